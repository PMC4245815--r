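test_that("hexamer scanning flags all covered positions", {
  expect_equal(scan_hexamers("GAAGAAT", hexamer_set("GAAGAA")),
               c(rep(TRUE, 6), FALSE))
  # overlapping matches union: starts 1 and 4 cover positions 1..9
  expect_equal(which(scan_hexamers("AAGAAGAAGAA", hexamer_set("AAGAAG"))),
               1:9)
  expect_equal(scan_hexamers("ACGTACGT", structure(character(0),
                                                   class = "hexamer_set")),
               rep(FALSE, 8))
  # N never matches
  expect_false(any(scan_hexamers("GANGAA", hexamer_set("GAAGAA"))))
})

test_that("hexamer scan agrees with the brute-force window oracle", {
  set.seed(11)
  hx <- default_ese_hexamers()
  for (rep in 1:25) {
    s <- random_seq(sample(6:120, 1))
    expect_equal(scan_hexamers(s, hx), naive_scan(s, hx))
  }
  # random small sets too
  for (rep in 1:10) {
    hset <- hexamer_set(vapply(1:3, function(i) random_seq(6), character(1)))
    s <- random_seq(80)
    expect_equal(scan_hexamers(s, hset), naive_scan(s, hset))
  }
})

test_that("gap removal and reinsertion preserves match positions", {
  ts <- toy_stitched("GA-AGAAT", "GACAGAAT")
  m <- annotate_alignment_ese(ts$aln, hexamer_set("GAAGAA"))
  expect_equal(which(as.logical(m)), c(1, 2, 4, 5, 6, 7))
  expect_equal(attr(m, "n_masked"), 6L)

  # gap columns are never flagged, even inside purine runs
  ts2 <- toy_stitched("GAAG--AA", "GAAGGGAA")
  m2 <- annotate_alignment_ese(ts2$aln, default_ese_hexamers())
  expect_false(any(m2[5:6]))
  expect_true(all(m2[c(1:4, 7:8)]))  # ungapped ref GAAGAA matches
  # mask never exceeds ungapped length
  expect_lte(sum(annotate_alignment_ese(ts$aln, default_ese_hexamers())),
             7L)
})

test_that("ESE density is masked bases over summed exon length", {
  ts <- toy_stitched("GAAGAATTTT", "GAAGAATTTT")
  m <- annotate_alignment_ese(ts$aln, hexamer_set("GAAGAA"))
  expect_equal(ese_density(ts$aln, m), 0.6)
  m0 <- annotate_alignment_ese(ts$aln, hexamer_set("CCCCCC"))
  expect_equal(ese_density(ts$aln, m0), 0)
})

test_that("junction distances follow the exon-half rule", {
  # internal exon of length 10 between two introns
  ts <- toy_stitched(exon_ref = c(strrep("A", 20), strrep("C", 10),
                                  strrep("G", 20)),
                     exon_oth = c(strrep("A", 20), strrep("C", 10),
                                  strrep("G", 20)),
                     intron_ref = c(strrep("T", 40), strrep("T", 40)),
                     intron_oth = c(strrep("T", 40), strrep("T", 40)))
  ann <- annotate_junction_distance(ts$gene, ts$aln)
  mid <- ann[21:30, ]  # the internal exon
  expect_equal(mid$distance[7], 4)       # position 7: 10 - 7 + 1
  expect_equal(mid$side[7], "3p")
  expect_equal(mid$distance[1:5], 1:5)   # 5' half
  expect_true(all(mid$valid))
  # first exon: only its 3' half valid
  first <- ann[1:20, ]
  expect_true(all(!first$valid[1:10]))
  expect_true(all(first$valid[11:20]))

  # odd length: ceiling split gives the 5' half the extra base
  ts2 <- toy_stitched(exon_ref = c(strrep("A", 12), strrep("C", 9),
                                   strrep("G", 12)),
                      exon_oth = c(strrep("A", 12), strrep("C", 9),
                                   strrep("G", 12)),
                      intron_ref = c(strrep("T", 40), strrep("T", 40)),
                      intron_oth = c(strrep("T", 40), strrep("T", 40)))
  ann2 <- annotate_junction_distance(ts2$gene, ts2$aln)
  expect_equal(ann2$distance[12 + 5], 5)
  expect_equal(ann2$side[12 + 5], "5p")

  single <- toy_stitched(strrep("A", 30), strrep("A", 30))
  expect_false(any(annotate_junction_distance(single$gene,
                                              single$aln)$valid))
})

test_that("assigned distance equals brute-force nearest-junction distance", {
  # internal exons: assigned distance must be min(p, L - p + 1)
  for (L in c(8, 9, 140, 141)) {
    ts <- toy_stitched(exon_ref = c(strrep("A", 10), strrep("C", L),
                                    strrep("G", 10)),
                       exon_oth = c(strrep("A", 10), strrep("C", L),
                                    strrep("G", 10)),
                       intron_ref = c(strrep("T", 50), strrep("T", 50)),
                       intron_oth = c(strrep("T", 50), strrep("T", 50)))
    ann <- annotate_junction_distance(ts$gene, ts$aln)
    got <- ann$distance[10 + seq_len(L)]
    expect_equal(got, pmin(seq_len(L), L - seq_len(L) + 1))
  }
})

test_that("region partition matches the worked flank/core arithmetic", {
  ts <- toy_stitched(exon_ref = c(strrep("A", 100), strrep("C", 200)),
                     exon_oth = c(strrep("A", 100), strrep("C", 200)),
                     intron_ref = strrep("T", 300),
                     intron_oth = strrep("T", 300))
  p <- partition_regions(ts$gene, ts$aln)
  expect_equal(p$L_flank, 140L)       # 70 + 70
  expect_equal(p$L_core, 160L)        # 30 + 130
  expect_equal(p$L_introncore, 260L)  # 300 - 2*20
  expect_true(p$passes_min_length)
  expect_equal(frac70(ts$gene, ts$aln), 140 / 300)

  # internal exon of length 100: midpoint caps flanks at 50 + 50
  ts2 <- toy_stitched(exon_ref = c(strrep("A", 200), strrep("C", 100),
                                   strrep("G", 200)),
                      exon_oth = c(strrep("A", 200), strrep("C", 100),
                                   strrep("G", 200)),
                      intron_ref = c(strrep("T", 150), strrep("T", 150)),
                      intron_oth = c(strrep("T", 150), strrep("T", 150)))
  p2 <- partition_regions(ts2$gene, ts2$aln)
  mid_cols <- which(ts2$aln$exon_block == 2L)
  expect_equal(sum(mid_cols %in% p2$flank_cols), 100L)
  expect_equal(sum(mid_cols %in% p2$core_cols), 0L)

  single <- toy_stitched(strrep("A", 500), strrep("A", 500))
  ps <- partition_regions(single$gene, single$aln)
  expect_equal(ps$L_flank, 0L)
  expect_false(ps$passes_min_length)
  expect_equal(frac70(single$gene, single$aln), 0)
})

test_that("partition is a disjoint cover of ungapped exon columns", {
  set.seed(5)
  cfg <- sim_config(n_genes = 8, mean_exons = 3)
  sim <- simulate_gene_models(cfg, seed = 3)
  al <- simulate_alignments(sim, seed = 4)
  for (i in seq_along(sim$genes)) {
    aln <- al$alignments[[i]]
    p <- partition_regions(sim$genes[[i]], aln)
    expect_length(intersect(p$flank_cols, p$core_cols), 0)
    ref <- strsplit(aln$exon_ref, "")[[1]]
    expect_setequal(c(p$flank_cols, p$core_cols), which(ref != "-"))
    # short internal exons (<= 2*flank_bp) are all flank
    expect_equal(p$L_flank + p$L_core, sum(ref != "-"))
  }
  # flank width 1.0: exons with junctions on both sides fully in flank
  ts <- toy_stitched(exon_ref = c(strrep("A", 100), strrep("C", 120)),
                     exon_oth = c(strrep("A", 100), strrep("C", 120)),
                     intron_ref = strrep("T", 200),
                     intron_oth = strrep("T", 200))
  expect_equal(frac70(ts$gene, ts$aln, flank_bp = 200), 1.0)
})

test_that("positional density profile pools genes and reports SEM", {
  ts <- toy_stitched(exon_ref = c(strrep("A", 30), strrep("A", 30)),
                     exon_oth = c(strrep("A", 30), strrep("A", 30)),
                     intron_ref = strrep("T", 50),
                     intron_oth = strrep("T", 50))
  m0 <- structure(rep(FALSE, 60), class = "ese_mask")
  prof <- positional_density_profile(list(ts$gene), list(ts$aln), list(m0),
                                     dmin = 6, dmax = 70)
  expect_true(all(prof$density == 0))
  expect_equal(max(prof$distance), 15)  # half-exon limit
  one <- positional_density_profile(list(ts$gene), list(ts$aln), list(m0),
                                    dmin = 6, dmax = 6)
  expect_equal(nrow(one), 1L)
})
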