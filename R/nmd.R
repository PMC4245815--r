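#' Extract ungapped per-exon reference sequences from a stitched alignment
#'
#' @param aln a [stitch_blocks()] result.
#' @return character vector, one ungapped reference sequence per exon in
#'   transcript order.
#' @export
exon_sequences <- function(aln) {
  ch <- aln_chars(aln, "exon")
  ok <- ch$ref != "-"
  if (!any(ok)) return(character(0))
  vapply(split(ch$ref[ok], aln$exon_block[ok]), paste, character(1),
         collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Count stop codons in one reading frame
#'
#' Non-overlapping codons starting at the frame offset; stops are
#' `TAA`, `TAG`, `TGA` (`U` accepted for `T`).
#'
#' @param seq sequence (character scalar).
#' @param frame frame offset in `0, 1, 2`.
#' @return integer count.
#' @export
count_stops <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  seq <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(seq)
  if (n - frame < 3L) return(0L)
  starts <- seq.int(1L + frame, n - 2L, by = 3L)
  sum(substring(seq, starts, starts + 2L) %in% STOP_CODONS)
}

# total stops over all three frames (internal)
stops_all_frames <- function(seq) {
  sum(vapply(0:2, function(f) count_stops(seq, f), integer(1)))
}

#' Paired stop-codon test on penultimate exons
#'
#' For genes whose penultimate exon (transcript order) exceeds `min_len` bp,
#' compares the stop-codon count (summed over all three frames) in the first
#' `window` bp of that exon against the last `window` bp — the window inside
#' the NMD shadow. Ties are dropped; the summary is an exact binomial test of
#' the proportion of genes with more stops in the 5' window against 0.5.
#'
#' @param exon_seqs list of per-gene exon sequence vectors (see
#'   [exon_sequences()]).
#' @param window window width in bp (default 50).
#' @param min_len minimum penultimate exon length (default 100, strict).
#' @return list with `per_gene` (data.frame `gene`, `stops_5p`, `stops_3p`)
#'   and `summary` (`n_informative`, `n_5p_higher`, `prop_5p_higher`,
#'   `p_value`); both empty/NA when no gene qualifies.
#' @export
penultimate_exon_paired_test <- function(exon_seqs, window = 50L,
                                         min_len = 100L) {
  rows <- lapply(seq_along(exon_seqs), function(i) {
    ex <- exon_seqs[[i]]
    if (length(ex) < 2L) return(NULL)
    pen <- ex[length(ex) - 1L]
    if (nchar(pen) <= min_len) return(NULL)
    w5 <- substr(pen, 1L, window)
    w3 <- substr(pen, nchar(pen) - window + 1L, nchar(pen))
    data.frame(gene = i, stops_5p = stops_all_frames(w5),
               stops_3p = stops_all_frames(w3))
  })
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene)) {
    return(list(per_gene = data.frame(gene = integer(0),
                                      stops_5p = integer(0),
                                      stops_3p = integer(0)),
                summary = list(n_informative = 0L, n_5p_higher = 0L,
                               prop_5p_higher = NA_real_,
                               p_value = NA_real_)))
  }
  diff <- per_gene$stops_5p - per_gene$stops_3p
  inf <- diff != 0L
  n5 <- sum(diff > 0L)
  p <- if (any(inf)) stats::binom.test(n5, sum(inf))$p.value else NA_real_
  list(per_gene = per_gene,
       summary = list(n_informative = sum(inf), n_5p_higher = n5,
                      prop_5p_higher = if (any(inf)) n5 / sum(inf)
                                       else NA_real_,
                      p_value = p))
}

#' Paired stop-codon test on the first exon of two-exon genes
#'
#' For genes with exactly two exons and a first exon of at least 100 bp,
#' compares stop counts (all frames) in the windows `[-100, -51]` and
#' `[-50, -1]` relative to the first exon's 3' junction — the latter being
#' the NMD shadow.
#'
#' @param exon_seqs list of per-gene exon sequence vectors.
#' @param shadow shadow width in bp (default 50).
#' @return as [penultimate_exon_paired_test()], with columns `stops_outer`
#'   (the `[-2*shadow, -shadow-1]` window) and `stops_shadow`.
#' @export
two_exon_window_test <- function(exon_seqs, shadow = 50L) {
  rows <- lapply(seq_along(exon_seqs), function(i) {
    ex <- exon_seqs[[i]]
    if (length(ex) != 2L) return(NULL)
    L <- nchar(ex[1L])
    if (L < 2L * shadow) return(NULL)
    outer_w <- substr(ex[1L], L - 2L * shadow + 1L, L - shadow)
    shadow_w <- substr(ex[1L], L - shadow + 1L, L)
    data.frame(gene = i, stops_outer = stops_all_frames(outer_w),
               stops_shadow = stops_all_frames(shadow_w))
  })
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene)) {
    return(list(per_gene = data.frame(gene = integer(0),
                                      stops_outer = integer(0),
                                      stops_shadow = integer(0)),
                summary = list(n_informative = 0L, n_outer_higher = 0L,
                               prop_outer_higher = NA_real_,
                               p_value = NA_real_)))
  }
  diff <- per_gene$stops_outer - per_gene$stops_shadow
  inf <- diff != 0L
  nh <- sum(diff > 0L)
  p <- if (any(inf)) stats::binom.test(nh, sum(inf))$p.value else NA_real_
  list(per_gene = per_gene,
       summary = list(n_informative = sum(inf), n_outer_higher = nh,
                      prop_outer_higher = if (any(inf)) nh / sum(inf)
                                          else NA_real_,
                      p_value = p))
}

#' Stop-free fractions of sequence windows
#'
#' Fraction of windows with zero stop codons in every frame, and fraction
#' with fewer than three stops. By default "fewer than three" counts the
#' total across the three frames; `mode = "per_frame"` instead reports the
#' fraction of windows with at least one entirely stop-free frame.
#'
#' @param windows character vector of sequences.
#' @param mode `"total"` or `"per_frame"` for the fewer-than-three statistic.
#' @return list: `frac_stop_free`, `frac_fewer_than_3`, exact binomial 95%
#'   CIs `ci_stop_free`/`ci_fewer_than_3`, `n`.
#' @export
stop_free_fraction <- function(windows, mode = c("total", "per_frame")) {
  mode <- match.arg(mode)
  per_frame <- t(vapply(windows, function(w)
    vapply(0:2, function(f) count_stops(w, f), integer(1)),
    integer(3)))
  total <- rowSums(per_frame)
  free <- total == 0L
  fewer3 <- if (mode == "total") total < 3L else
    apply(per_frame == 0L, 1L, any)
  ci <- function(k, n) if (n) as.numeric(
    stats::binom.test(k, n)$conf.int) else c(NA_real_, NA_real_)
  n <- length(windows)
  list(frac_stop_free = mean(free), frac_fewer_than_3 = mean(fewer3),
       ci_stop_free = ci(sum(free), n),
       ci_fewer_than_3 = ci(sum(fewer3), n), n = n)
}

#' Stop-free expectation under mononucleotide shuffling
#'
#' Shuffles each window preserving its exact base counts and reports the
#' expected stop-free fractions (see [stop_free_fraction()]) averaged over
#' shuffles.
#'
#' @param windows character vector of sequences.
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed integer seed.
#' @param mode passed to [stop_free_fraction()].
#' @return list: `frac_stop_free`, `frac_fewer_than_3` (means over shuffles),
#'   `n_shuffles`.
#' @export
randomized_stop_free_expectation <- function(windows, n_shuffles = 1000L,
                                             seed = 1L,
                                             mode = c("total", "per_frame")) {
  mode <- match.arg(mode)
  stopifnot(n_shuffles >= 1L)
  set.seed(seed)
  chars <- lapply(windows, function(w) strsplit(toupper(w), "")[[1L]])
  acc_free <- 0; acc_f3 <- 0
  for (s in seq_len(n_shuffles)) {
    shuf <- vapply(chars, function(ch) paste(sample(ch), collapse = ""),
                   character(1))
    res <- stop_free_fraction(shuf, mode = mode)
    acc_free <- acc_free + res$frac_stop_free
    acc_f3 <- acc_f3 + res$frac_fewer_than_3
  }
  list(frac_stop_free = acc_free / n_shuffles,
       frac_fewer_than_3 = acc_f3 / n_shuffles, n_shuffles = n_shuffles)
}

#' Stop-codon density versus first-exon length
#'
#' Spearman correlation of stops per bp (all frames) in the first exon with
#' first-exon length, over two-exon genes.
#'
#' @param exon_seqs list of per-gene exon sequence vectors.
#' @return list: `rho`, `p_value`, `n`.
#' @export
stop_density_vs_length <- function(exon_seqs) {
  two <- Filter(function(ex) length(ex) == 2L, exon_seqs)
  if (length(two) < 3L) stop("need at least 3 two-exon genes")
  len <- vapply(two, function(ex) nchar(ex[1L]), numeric(1))
  dens <- vapply(two, function(ex) stops_all_frames(ex[1L]), numeric(1)) / len
  ct <- suppressWarnings(stats::cor.test(dens, len, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(two))
}
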