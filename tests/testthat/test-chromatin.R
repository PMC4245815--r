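mk_gene <- function(id, start, end, exon_bounds = NULL, chrom = "chr1") {
  if (is.null(exon_bounds)) exon_bounds <- cbind(start, end)
  gene_model(id, chrom, start, end, "+", exon_bounds)
}

test_that("peak count density uses half-open overlap on raw records", {
  g <- mk_gene("g", 0L, 10000L)
  tr <- peak_track(rep("chr1", 3), c(100L, 5000L, 9990L),
                   c(200L, 5100L, 10200L))
  expect_equal(peak_count_density(g, tr), 3e-4)
  # peak ending exactly at gene start does not overlap
  tr2 <- peak_track("chr1", 0L, 50L)
  g2 <- mk_gene("g2", 50L, 150L)
  expect_equal(peak_count_density(g2, tr2), 0)
  # nested/overlapping records each counted
  tr3 <- peak_track(c("chr1", "chr1"), c(10L, 20L), c(90L, 40L))
  expect_equal(peak_count_density(mk_gene("g3", 0L, 100L), tr3), 0.02)
})

test_that("coverage density merges overlapping peaks", {
  g <- mk_gene("g", 0L, 10000L)
  tr <- peak_track(c("chr1", "chr1"), c(0L, 250L), c(500L, 1000L))
  expect_equal(peak_coverage_density(g, tr), 0.1)
  expect_equal(peak_coverage_density(g, peak_track()), 0)
  whole <- peak_track("chr1", 0L, 20000L)
  expect_equal(peak_coverage_density(g, whole), 1)
})

test_that("overlap queries agree with the naive interval scan", {
  set.seed(17)
  for (rep in 1:10) {
    genes <- lapply(1:8, function(i) {
      s <- sample(0:5000, 1)
      mk_gene(paste0("g", i), s, s + sample(200:2000, 1))
    })
    st <- sample(0:6000, 40, replace = TRUE)
    tr <- peak_track(rep("chr1", 40), st, st + sample(50:500, 40,
                                                      replace = TRUE))
    for (g in genes) {
      expect_equal(peak_count_density(g, tr) * unspliced_length(g),
                   naive_peak_count(g, tr))
      expect_equal(peak_coverage_density(g, tr), naive_coverage(g, tr))
    }
  }
})

test_that("intron density counts gaps between exons per bp", {
  g <- mk_gene("g", 0L, 10000L,
               cbind(c(0L, 2000L, 4000L, 6000L, 8000L),
                     c(1000L, 3000L, 5000L, 7000L, 10000L)))
  expect_equal(intron_density(g), 4e-4)
  expect_equal(intron_density(g, per_kb = TRUE), 0.4)
  expect_equal(intron_density(mk_gene("s", 0L, 500L)), 0)
})

test_that("equal-mass binning follows the greedy trace", {
  lens <- c(6L, 4L, 3L, 3L, 2L, 2L)
  genes <- lapply(seq_along(lens), function(i)
    mk_gene(paste0("g", i), (i - 1L) * 100L, (i - 1L) * 100L + lens[i]))
  res <- equal_mass_bins(genes, peak_track(), n_bins = 2)
  expect_equal(res$total_bp, c(10, 10))
  expect_equal(res$n_genes, c(2L, 4L))
  asg <- attr(res, "assignment")
  expect_equal(asg[1:2], c(1L, 1L))  # lengths 6 and 4
  one <- equal_mass_bins(genes, peak_track(), n_bins = 1)
  expect_equal(one$total_bp, 20)
  expect_error(equal_mass_bins(genes[1:3], peak_track(), n_bins = 5),
               "fewer genes")
})

test_that("permutation p-values follow the (n+1)/(m+1) estimator", {
  res <- monte_carlo_label_test(rep(1, 6), rep(1, 6), n_iter = 200,
                                seed = 1)
  expect_equal(res$p_value, 1.0)
  set.seed(2)
  res2 <- monte_carlo_label_test(rnorm(10, 5), rnorm(10), n_iter = 499,
                                 seed = 3)
  expect_equal(res2$p_value, (res2$n_extreme + 1) / (res2$n_iter + 1))
  expect_gte(res2$p_value, 1 / 500)
  expect_error(monte_carlo_label_test(1:3, numeric(0)), "non-empty")
  expect_error(monte_carlo_label_test(1:3, 1:3, n_iter = 0), "n_iter")
})

test_that("flank window profiles respect window geometry and bounds", {
  g <- mk_gene("g", 100000L, 120000L)
  # one peak in the first upstream window, one 35 kb downstream
  tr <- peak_track(c("chr1", "chr1"), c(95000L, 152000L),
                   c(95500L, 152400L))
  prof <- flank_window_profile(list(g), tr, window = 10000, n_windows = 4)
  expect_equal(prof$density[prof$window == -1], 1e-4)
  expect_equal(prof$density[prof$window == 4], 1e-4)
  expect_equal(sum(prof$density > 0), 2)
  # gene near the chromosome start loses its far upstream windows
  g0 <- mk_gene("g0", 15000L, 20000L)
  prof0 <- flank_window_profile(list(g0), tr, window = 10000, n_windows = 4)
  expect_false(any(prof0$window %in% c(-4, -3)))
  # upper clipping by chromosome size
  profc <- flank_window_profile(list(g), tr, window = 10000, n_windows = 4,
                                chrom_sizes = c(chr1 = 130000))
  expect_false(any(profc$window > 1))
  # empty track: all densities zero
  prof_e <- flank_window_profile(list(g), peak_track(), window = 10000,
                                 n_windows = 2)
  expect_true(all(prof_e$density == 0))
})

test_that("flank average density averages both sides and flags clipping", {
  g <- mk_gene("g", 100000L, 110000L)
  tr <- peak_track(rep("chr1", 3), c(60000L, 70000L, 112000L),
                   c(60500L, 70500L, 112400L))
  res <- flank_average_density(g, tr, flank = 50000)
  expect_equal(res$density, mean(c(2, 1) / 50000))
  expect_false(res$clipped)
  edge <- mk_gene("e", 10000L, 20000L)
  res2 <- flank_average_density(edge, tr, flank = 50000)
  expect_true(res2$clipped)
  # only the right block [20k, 70k) counts: it holds the 60k peak, and the
  # 70k peak starts exactly at the half-open bound
  expect_equal(res2$density, 1 / 50000)
})

test_that("neighbour expression profile averages fractions, not zeros", {
  focal <- mk_gene("f", 100000L, 110000L)
  nb <- list(mk_gene("n1", 92000L, 94000L),   # window -1
             mk_gene("n2", 95000L, 99000L),   # window -1
             mk_gene("n3", 111000L, 112000L)) # window +1
  expressed <- c(n1 = TRUE, n2 = FALSE, n3 = TRUE)
  prof <- neighbor_expression_profile(list(focal), nb, expressed,
                                      window = 10000, n_windows = 2)
  expect_equal(prof$frac_expressed[prof$window == -1], 0.5)
  expect_equal(prof$frac_expressed[prof$window == 1], 1)
  expect_true(is.nan(prof$frac_expressed[prof$window == 2]))
  # all-expressed neighbours give 1 everywhere they occur
  prof2 <- neighbor_expression_profile(list(focal), nb,
                                       c(n1 = TRUE, n2 = TRUE, n3 = TRUE),
                                       window = 10000, n_windows = 1)
  expect_true(all(prof2$frac_expressed == 1))
})
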