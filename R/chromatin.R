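#' Peak count density of a gene
#'
#' Number of peak records with at least 1 bp of overlap with the unspliced
#' gene span `[start, end)`, divided by the gene length. Overlapping or
#' nested peak records each count once.
#'
#' @param gene a [gene_model()].
#' @param track a [peak_track()].
#' @return peaks per bp.
#' @export
peak_count_density <- function(gene, track) {
  len <- unspliced_length(gene)
  if (len <= 0L) stop("zero-length gene")
  r <- track_ranges(track, gene$chrom)
  q <- IRanges::IRanges(gene$start + 1L, gene$end)
  IRanges::countOverlaps(q, r) / len
}

#' Peak coverage density of a gene
#'
#' Length of the union of peak-gene intersections divided by the gene
#' length (merged coverage: overlapping peaks are not double counted).
#'
#' @param gene a [gene_model()].
#' @param track a [peak_track()].
#' @return fraction in `[0, 1]`.
#' @export
peak_coverage_density <- function(gene, track) {
  len <- unspliced_length(gene)
  if (len <= 0L) stop("zero-length gene")
  r <- track_ranges(track, gene$chrom)
  q <- IRanges::IRanges(gene$start + 1L, gene$end)
  inter <- IRanges::reduce(IRanges::restrict(r, IRanges::start(q),
                                             IRanges::end(q)))
  sum(IRanges::width(inter)) / len
}

#' Intron density of a gene
#'
#' Introns per bp of unspliced gene length: `(exon_count - 1) / (end - start)`.
#'
#' @param gene a [gene_model()].
#' @param per_kb report introns per kb instead of per bp.
#' @return density.
#' @export
intron_density <- function(gene, per_kb = FALSE) {
  d <- (n_exons(gene) - 1L) / unspliced_length(gene)
  if (per_kb) d * 1000 else d
}

#' Density table of genes against a peak track
#'
#' @param genes list of [gene_model()].
#' @param track a [peak_track()].
#' @param labels optional data.frame (`gene_id`, `cell_type`, `status`)
#'   restricted to one cell type, used to attach activity labels.
#' @return data.frame: `gene_id`, `peak_count_density`, `coverage_density`,
#'   `intron_density`, `length`, `status` (NA when unlabelled).
#' @export
density_table <- function(genes, track, labels = NULL) {
  df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    peak_count_density = vapply(genes, peak_count_density, numeric(1),
                                track = track),
    coverage_density = vapply(genes, peak_coverage_density, numeric(1),
                              track = track),
    intron_density = vapply(genes, intron_density, numeric(1)),
    length = vapply(genes, unspliced_length, numeric(1)),
    stringsAsFactors = FALSE)
  df$status <- if (!is.null(labels))
    labels$status[match(df$gene_id, labels$gene_id)] else NA_character_
  df
}

#' Peak density profile in independent flank windows
#'
#' Peak count per bp in `n_windows` non-overlapping windows of `window` bp on
#' each side of every gene (window -1/+1 abut the gene edges), averaged over
#' genes per activity class. Windows extending beyond the chromosome bounds
#' are excluded from that gene's contribution.
#'
#' @param genes list of [gene_model()].
#' @param track a [peak_track()].
#' @param labels activity labels (`gene_id`, `status`), or NULL to pool.
#' @param window window width in bp (default 10 kb).
#' @param n_windows windows per side (default 10).
#' @param chrom_sizes named vector of chromosome lengths (default: no upper
#'   clipping).
#' @return data.frame: `status`, `window` (-n..-1, 1..n), `density`
#'   (mean peaks/bp), `n_genes`.
#' @export
flank_window_profile <- function(genes, track, labels = NULL,
                                 window = 10000L, n_windows = 10L,
                                 chrom_sizes = NULL) {
  status <- if (!is.null(labels)) {
    labels$status[match(vapply(genes, `[[`, character(1), "gene_id"),
                        labels$gene_id)]
  } else rep("all", length(genes))
  widx <- c(-rev(seq_len(n_windows)), seq_len(n_windows))
  acc <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    r <- track_ranges(track, g$chrom)
    lim <- if (!is.null(chrom_sizes) && g$chrom %in% names(chrom_sizes))
      chrom_sizes[[g$chrom]] else Inf
    for (w in widx) {
      lo <- if (w < 0L) g$start + w * window else g$end + (w - 1L) * window
      hi <- lo + window
      if (lo < 0L || hi > lim) next
      cnt <- IRanges::countOverlaps(IRanges::IRanges(lo + 1L, hi), r)
      acc[[length(acc) + 1L]] <- data.frame(status = status[i], window = w,
                                            density = cnt / window)
    }
  }
  df <- do.call(rbind, acc)
  if (is.null(df)) {
    return(data.frame(status = character(0), window = integer(0),
                      density = numeric(0), n_genes = integer(0)))
  }
  agg <- stats::aggregate(density ~ status + window, data = df, FUN = mean)
  cnts <- stats::aggregate(density ~ status + window, data = df,
                           FUN = length)
  agg$n_genes <- cnts$density
  agg[order(agg$status, agg$window), , drop = FALSE]
}

#' Average peak density in the blocks flanking a gene
#'
#' Mean of the peak count densities of the `[start - flank, start)` and
#' `[end, end + flank)` blocks. Blocks extending beyond the chromosome are
#' dropped; when only one side remains the single-side mean is returned with
#' `clipped = TRUE`.
#'
#' @param gene a [gene_model()].
#' @param track a [peak_track()].
#' @param flank block width in bp (default 50 kb).
#' @param chrom_sizes optional named chromosome lengths.
#' @return list: `density` (peaks/bp), `clipped`.
#' @export
flank_average_density <- function(gene, track, flank = 50000L,
                                  chrom_sizes = NULL) {
  r <- track_ranges(track, gene$chrom)
  lim <- if (!is.null(chrom_sizes) && gene$chrom %in% names(chrom_sizes))
    chrom_sizes[[gene$chrom]] else Inf
  sides <- list(c(gene$start - flank, gene$start),
                c(gene$end, gene$end + flank))
  dens <- numeric(0)
  for (s in sides) {
    if (s[1L] < 0L || s[2L] > lim) next
    cnt <- IRanges::countOverlaps(IRanges::IRanges(s[1L] + 1L, s[2L]), r)
    dens <- c(dens, cnt / flank)
  }
  if (!length(dens)) return(list(density = NA_real_, clipped = TRUE))
  list(density = mean(dens), clipped = length(dens) < 2L)
}

#' Equal-total-length bins of genes
#'
#' Ranks genes by unspliced length (longest first) and greedily accumulates
#' them into bins, closing a bin once its cumulative length reaches
#' `total/n_bins`; each bin therefore holds a different number of genes but
#' about the same amount of sampled DNA. Reports introns/kb and peaks/kb per
#' bin.
#'
#' @param genes list of [gene_model()].
#' @param track a [peak_track()].
#' @param n_bins number of bins (default 10; must not exceed the gene count).
#' @return data.frame: `bin`, `n_genes`, `total_bp`, `introns_per_kb`,
#'   `peaks_per_kb`, plus attribute `assignment` (bin per sorted gene).
#' @export
equal_mass_bins <- function(genes, track, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  if (length(genes) < n_bins) stop("fewer genes than bins")
  len <- vapply(genes, unspliced_length, numeric(1))
  ord <- order(len, decreasing = TRUE)
  target <- sum(len) / n_bins
  bin <- integer(length(genes))
  b <- 1L; acc <- 0
  for (j in ord) {
    bin[j] <- b
    acc <- acc + len[j]
    if (acc >= target && b < n_bins) { b <- b + 1L; acc <- 0 }
  }
  nint <- vapply(genes, function(g) n_exons(g) - 1L, numeric(1))
  npk <- vapply(genes, function(g) peak_count_density(g, track) *
                  unspliced_length(g), numeric(1))
  out <- do.call(rbind, lapply(seq_len(n_bins), function(k) {
    sel <- bin == k
    data.frame(bin = k, n_genes = sum(sel), total_bp = sum(len[sel]),
               introns_per_kb = sum(nint[sel]) / sum(len[sel]) * 1000,
               peaks_per_kb = sum(npk[sel]) / sum(len[sel]) * 1000)
  }))
  attr(out, "assignment") <- bin
  out
}

#' Monte Carlo permutation test on a difference of group medians
#'
#' The observed statistic is `median(values_active) - median(values_inactive)`.
#' Group labels are permuted preserving group sizes; the unbiased p estimate
#' is `(n + 1) / (m + 1)` with `n` the number of permutations at least as
#' extreme as the observation (absolute value for the two-sided default) and
#' `m` the number of permutations.
#'
#' @param values_active,values_inactive numeric vectors (both non-empty).
#' @param n_iter number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (active median
#'   larger).
#' @return list: `p_value`, `observed`, `n_extreme`, `n_iter`.
#' @export
monte_carlo_label_test <- function(values_active, values_inactive,
                                   n_iter = 10000L, seed = 1L,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!length(values_active) || !length(values_inactive))
    stop("both groups must be non-empty")
  obs <- stats::median(values_active) - stats::median(values_inactive)
  pool <- c(values_active, values_inactive)
  na <- length(values_active); ntot <- length(pool)
  set.seed(seed)
  stat <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(ntot, na)
    stats::median(pool[idx]) - stats::median(pool[-idx])
  }, numeric(1))
  n_ext <- if (alternative == "two.sided") sum(abs(stat) >= abs(obs))
           else sum(stat >= obs)
  list(p_value = (n_ext + 1) / (n_iter + 1), observed = obs,
       n_extreme = n_ext, n_iter = n_iter)
}

#' Fraction of expressed neighbours in flank windows
#'
#' For every focal gene and every window (-n..-1, 1..n of `window` bp from
#' the gene edges), the fraction of neighbour genes overlapping the window
#' that are expressed, averaged over focal genes with at least one neighbour
#' in the window. Windows that never contain a neighbour are reported as
#' missing (`NaN`), not 0.
#'
#' @param genes list of focal [gene_model()].
#' @param neighbor_genes list of neighbour [gene_model()] (may be the same
#'   list; a gene is never its own neighbour).
#' @param expressed named logical vector (by neighbour gene id), e.g.
#'   `FPKM > 0` in the matching cell type.
#' @param window window width in bp (default 10 kb).
#' @param n_windows windows per side (default 10).
#' @return data.frame: `window`, `frac_expressed`, `n_focal`.
#' @export
neighbor_expression_profile <- function(genes, neighbor_genes, expressed,
                                        window = 10000L, n_windows = 10L) {
  nb_id <- vapply(neighbor_genes, `[[`, character(1), "gene_id")
  nb_chrom <- vapply(neighbor_genes, `[[`, character(1), "chrom")
  nb_start <- vapply(neighbor_genes, function(g) g$start, numeric(1))
  nb_end <- vapply(neighbor_genes, function(g) g$end, numeric(1))
  nb_expr <- as.logical(expressed[nb_id])
  widx <- c(-rev(seq_len(n_windows)), seq_len(n_windows))
  out <- lapply(widx, function(w) {
    fracs <- numeric(0)
    for (g in genes) {
      lo <- if (w < 0L) g$start + w * window else g$end + (w - 1L) * window
      hi <- lo + window
      if (lo < 0L) next
      sel <- nb_chrom == g$chrom & nb_start < hi & nb_end > lo &
        nb_id != g$gene_id
      if (!any(sel)) next
      fracs <- c(fracs, mean(nb_expr[sel], na.rm = TRUE))
    }
    data.frame(window = w,
               frac_expressed = if (length(fracs)) mean(fracs) else NaN,
               n_focal = length(fracs))
  })
  do.call(rbind, out)
}
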