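test_that("substitution counting classifies transitions and skips gaps/N", {
  ts <- toy_stitched("ACGT", "ACGA")
  cnt <- count_substitutions(ts$aln, "exon")
  expect_equal(cnt$n_sites, 4L)
  expect_equal(cnt$n_subs, 1L)
  expect_equal(cnt$n_transversions, 1L)  # T<->A
  expect_equal(cnt$n_transitions, 0L)

  same <- count_substitutions(toy_stitched("ACGT", "ACGT")$aln, "exon")
  expect_equal(same$n_subs, 0L)

  gapped <- count_substitutions(toy_stitched("AC-GTN", "ACCGTA")$aln, "exon")
  expect_equal(gapped$n_sites, 4L)  # gap and N columns excluded

  tr <- count_substitutions(toy_stitched("AG", "GA")$aln, "exon")
  expect_equal(tr$n_transitions, 2L)
})

test_that("p-distance is substitutions over sites", {
  cnt <- count_substitutions(toy_stitched("ACGT", "ACGA")$aln, "exon")
  expect_equal(p_distance(cnt), 0.25)
  expect_equal(p_distance(count_substitutions(
    toy_stitched("AAAA", "AAAA")$aln, "exon")), 0)
  empty <- count_substitutions(toy_stitched("----A", "AAAA-")$aln, "exon")
  expect_error(p_distance(empty), "no counted sites")
})

test_that("corrected distance reproduces its closed-form limiting cases", {
  mk <- function(P, Q, th1, th2) {
    list(n_sites = 1L, n_subs = P + Q, n_transitions = P,
         n_transversions = Q, gc_ref = th1, gc_other = th2)
  }
  # equal-GC 0.5 case: Kimura two-parameter closed form
  expect_equal(tk_distance(mk(0.1, 0.05, 0.5, 0.5)),
               -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  # no divergence
  expect_equal(tk_distance(mk(0, 0, 0.3, 0.7)), 0)
  # h arithmetic: th = (0.3, 0.5) gives h = 0.5, same K as (0.5, 0.5)
  expect_equal(tk_distance(mk(0.1, 0.05, 0.3, 0.5)),
               tk_distance(mk(0.1, 0.05, 0.5, 0.5)), tolerance = 1e-12)
  # saturation flagged, not -Inf
  sat <- tk_distance(mk(0.5, 0.3, 0.5, 0.5))
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
  # degenerate composition falls back with a warning
  expect_warning(k0 <- tk_distance(mk(0.1, 0.05, 0, 0)), "degenerate")
  expect_equal(k0, -0.5 * log(1 - 0.3), tolerance = 1e-12)
})

test_that("corrected distance increases with substitutions and bounds p", {
  mk <- function(P, Q) list(n_sites = 1L, n_subs = P + Q, n_transitions = P,
                            n_transversions = Q, gc_ref = 0.4,
                            gc_other = 0.45)
  ks <- vapply(seq(0.01, 0.2, by = 0.01),
               function(P) tk_distance(mk(P, 0.05)), numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks >= 0))
  # correction always at or above the raw proportion of differences
  for (P in c(0.02, 0.08, 0.15)) {
    expect_gte(tk_distance(mk(P, 0.05)), P + 0.05)
  }
})

test_that("pooled region counts equal the sum of per-gene counts", {
  set.seed(9)
  cfg <- sim_config(n_genes = 6)
  sim <- simulate_gene_models(cfg, seed = 21)
  al <- simulate_alignments(sim, seed = 22)
  parts <- lapply(seq_along(sim$genes), function(i)
    partition_regions(sim$genes[[i]], al$alignments[[i]]))
  tot <- list(n_sites = 0L, n_subs = 0L)
  for (i in seq_along(sim$genes)) {
    cnt <- count_substitutions(al$alignments[[i]], "exon",
                               parts[[i]]$flank_cols)
    tot$n_sites <- tot$n_sites + cnt$n_sites
    tot$n_subs <- tot$n_subs + cnt$n_subs
  }
  # concatenate-then-count route
  ref <- unlist(lapply(seq_along(sim$genes), function(i) {
    ch <- lincsel:::aln_chars(al$alignments[[i]], "exon")
    ch$ref[parts[[i]]$flank_cols]
  }))
  oth <- unlist(lapply(seq_along(sim$genes), function(i) {
    ch <- lincsel:::aln_chars(al$alignments[[i]], "exon")
    ch$oth[parts[[i]]$flank_cols]
  }))
  pooled <- lincsel:::count_subs_chars(ref, oth)
  expect_identical(pooled$n_sites, tot$n_sites)
  expect_identical(pooled$n_subs, tot$n_subs)
})

test_that("identical sequences give zero rates and undefined ratios", {
  ts <- toy_stitched(exon_ref = c(strrep("ACGT", 50), strrep("GTCA", 50)),
                     exon_oth = c(strrep("ACGT", 50), strrep("GTCA", 50)),
                     intron_ref = strrep("TTAC", 50),
                     intron_oth = strrep("TTAC", 50))
  p <- partition_regions(ts$gene, ts$aln)
  rr <- gene_region_rates(ts$gene, p, ts$aln)
  expect_equal(rr$K_exon, 0)
  expect_equal(rr$K_intron, 0)
  expect_true(is.na(rr$log_ke_ki))
  expect_true(is.na(rr$log_kef_kec))
})

test_that("positional rate profile is zero under zero divergence", {
  cfg <- sim_config(n_genes = 5, neutral_divergence = 0, indel_rate = 0)
  sim <- simulate_gene_models(cfg, seed = 31)
  al <- simulate_alignments(sim, seed = 32)
  masks <- lapply(al$alignments, annotate_alignment_ese,
                  hexamers = cfg$ese_hexamers)
  prof <- positional_rate_profile(sim$genes, al$alignments, masks)
  expect_true(all(prof$rate == 0))
  expect_true(all(prof$n_sites > 0))
})

test_that("composition-matched draws honour exact base counts", {
  # a pool where the substitution state is determined by the reference base:
  # every A column is substituted, everything else is not
  pool <- data.frame(ref = rep(c("A", "C", "G", "T"), each = 50),
                     oth = rep(c("G", "C", "G", "T"), each = 50),
                     stringsAsFactors = FALSE)
  pool$sub <- pool$ref != pool$oth
  comp <- c(A = 10L, C = 5L, G = 5L, T = 10L)
  res <- composition_matched_null(comp, pool, n_draws = 25, seed = 3)
  # with composition fixed, every draw contains exactly 10 substituted cols
  expect_true(all(res$draws == 10 / 30))
  expect_equal(res$sd, 0)
  res2 <- composition_matched_null(comp, pool, n_draws = 25, seed = 3)
  expect_identical(res$draws, res2$draws)
  expect_error(composition_matched_null(c(A = 200L, C = 0L, G = 0L,
                                          T = 0L), pool, 5, 1),
               "base A")
})

test_that("composition null is unbiased when the pool is homogeneous", {
  set.seed(41)
  n <- 4000
  pool <- data.frame(ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  pool$oth <- pool$ref
  flip <- runif(n) < 0.1
  pool$oth[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
  pool$sub <- pool$ref != pool$oth
  comp <- c(A = 100L, C = 80L, G = 90L, T = 110L)
  res <- composition_matched_null(comp, pool, n_draws = 400, seed = 5)
  # truth: expected rate equals the composition-weighted pool rate
  per_base <- tapply(pool$sub, pool$ref, mean)
  expected <- sum(per_base[names(comp)] * comp) / sum(comp)
  expect_lt(abs(res$rate - expected), 2 * res$sd / sqrt(400) + 1e-6)
})

test_that("expected exon/intron log ratio follows the constraint product", {
  expect_equal(expected_log_keki(0.27, 0.30, 0.15),
               log(1 - 0.27 * 0.30 * 0.15))
  expect_equal(expected_log_keki(0, 0.3, 0.15), 0)
  expect_warning(v <- expected_log_keki(1, 1, 1), "undefined")
  expect_true(is.na(v))
})
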