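#' Count substitutions over a set of alignment columns
#'
#' Columns containing a gap or `N` in either row are skipped. Transitions are
#' `A<->G` and `C<->T`; every other mismatch is a transversion. GC fractions
#' of each row are computed over the counted columns, as inputs to the
#' lineage-heterogeneity-corrected distance.
#'
#' @param aln a [stitch_blocks()] result.
#' @param region `"exon"` or `"intron"` alignment.
#' @param columns integer vector of column indices (default: all columns of
#'   the chosen region).
#' @return list of class `"subst_counts"`: `n_sites`, `n_subs`,
#'   `n_transitions`, `n_transversions`, `gc_ref`, `gc_other`.
#' @export
count_substitutions <- function(aln, region = "exon", columns = NULL) {
  ch <- aln_chars(aln, region)
  if (is.null(columns)) columns <- seq_along(ch$ref)
  r <- ch$ref[columns]; o <- ch$oth[columns]
  count_subs_chars(r, o)
}

# core counter on character vectors (internal)
count_subs_chars <- function(r, o) {
  bases <- c("A", "C", "G", "T")
  ok <- r %in% bases & o %in% bases
  r <- r[ok]; o <- o[ok]
  n <- length(r)
  mm <- r != o
  ts <- mm & ((r == "A" & o == "G") | (r == "G" & o == "A") |
                (r == "C" & o == "T") | (r == "T" & o == "C"))
  structure(list(n_sites = n, n_subs = sum(mm), n_transitions = sum(ts),
                 n_transversions = sum(mm) - sum(ts),
                 gc_ref = if (n) mean(r %in% c("G", "C")) else NA_real_,
                 gc_other = if (n) mean(o %in% c("G", "C")) else NA_real_),
            class = "subst_counts")
}

#' Uncorrected p-distance
#'
#' Substitutions divided by sites. Errors when no sites were counted.
#'
#' @param counts a [count_substitutions()] result.
#' @return rate in `[0, 1]`.
#' @export
p_distance <- function(counts) {
  if (counts$n_sites == 0L) stop("p-distance undefined: no counted sites")
  counts$n_subs / counts$n_sites
}

#' Lineage-heterogeneity-corrected substitution distance
#'
#' Pairwise distance relaxing the assumption of a homogeneous substitution
#' pattern across the two lineages:
#' \deqn{K = -h \ln(1 - P/h - Q) - \tfrac{1}{2}(1 - h)\ln(1 - 2Q),}
#' with transition proportion `P`, transversion proportion `Q`, and
#' `h = theta1 + theta2 - 2*theta1*theta2` where `theta_i` is the GC fraction
#' of row `i` over the counted columns. With equal GC in both rows it reduces
#' to the Tamura (1992) single-lineage correction (`h = 2*theta*(1-theta)`),
#' and at `theta = 0.5` to the Kimura two-parameter distance.
#'
#' Saturated inputs (either logarithm argument non-positive) return `NA` with
#' attribute `saturated = TRUE` so callers can flag and exclude the gene. The
#' degenerate case `h = 0` (both rows entirely GC or entirely AT) falls back
#' to `-0.5 * ln(1 - 2P - 2Q)` with a warning.
#'
#' @param counts a [count_substitutions()] result.
#' @return numeric distance (substitutions per site), possibly `NA` with
#'   attribute `saturated`.
#' @export
tk_distance <- function(counts) {
  if (counts$n_sites == 0L) stop("distance undefined: no counted sites")
  P <- counts$n_transitions / counts$n_sites
  Q <- counts$n_transversions / counts$n_sites
  th1 <- counts$gc_ref; th2 <- counts$gc_other
  h <- th1 + th2 - 2 * th1 * th2
  if (h <= 0) {
    warning("degenerate base composition (h = 0); ",
            "falling back to -0.5*log(1 - 2P - 2Q)")
    arg <- 1 - 2 * P - 2 * Q
    if (arg <= 0) return(structure(NA_real_, saturated = TRUE))
    return(-0.5 * log(arg))
  }
  a1 <- 1 - P / h - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(structure(NA_real_, saturated = TRUE))
  -h * log(a1) - 0.5 * (1 - h) * log(a2)
}

#' Region-stratified substitution rates of one gene
#'
#' Applies [tk_distance()] to the concatenated column sets of the gene:
#' all exon columns (`K_exon`), all intron columns (`K_intron`), exon flanks
#' (`Kef`), exon cores (`Kec`) and intron cores (`Kic`), plus natural-log
#' ratios. Ratios are reported only when the partition passes its length
#' filter, both distances are defined (unsaturated) and the denominator rate
#' is positive; otherwise they are `NA`.
#'
#' @param gene a [gene_model()].
#' @param partition matching [partition_regions()] result.
#' @param aln matching [stitch_blocks()] result.
#' @return one-row data.frame: `gene_id`, `K_exon`, `K_intron`, `Kef`, `Kec`,
#'   `Kic`, `log_ke_ki`, `log_kef_kec`, `log_kec_kic`, `passes_filter`,
#'   `saturated`.
#' @export
gene_region_rates <- function(gene, partition, aln) {
  safe_k <- function(region, cols) {
    cnt <- count_substitutions(aln, region, cols)
    if (cnt$n_sites == 0L) return(structure(NA_real_, saturated = FALSE))
    k <- suppressWarnings(tk_distance(cnt))
    if (is.null(attr(k, "saturated"))) attr(k, "saturated") <- FALSE
    k
  }
  ke <- safe_k("exon", NULL)
  ki <- if (nchar(aln$intron_ref)) safe_k("intron", NULL)
        else structure(NA_real_, saturated = FALSE)
  kef <- safe_k("exon", partition$flank_cols)
  kec <- safe_k("exon", partition$core_cols)
  kic <- safe_k("intron", partition$introncore_cols)
  saturated <- any(vapply(list(ke, ki, kef, kec, kic),
                          function(k) isTRUE(attr(k, "saturated")),
                          logical(1)))
  ratio <- function(num, den) {
    if (!partition$passes_min_length) return(NA_real_)
    if (is.na(num) || is.na(den) || den <= 0 || num <= 0) return(NA_real_)
    log(num / den)
  }
  data.frame(gene_id = gene$gene_id,
             K_exon = as.numeric(ke), K_intron = as.numeric(ki),
             Kef = as.numeric(kef), Kec = as.numeric(kec),
             Kic = as.numeric(kic),
             log_ke_ki = ratio(as.numeric(ke), as.numeric(ki)),
             log_kef_kec = ratio(as.numeric(kef), as.numeric(kec)),
             log_kec_kic = ratio(as.numeric(kec), as.numeric(kic)),
             passes_filter = partition$passes_min_length,
             saturated = saturated,
             stringsAsFactors = FALSE)
}

#' Region rates for a collection of genes
#'
#' @param genes list of [gene_model()].
#' @param alns list of matching [stitch_blocks()] results.
#' @param flank_bp,intron_trim,min_concat passed to [partition_regions()].
#' @return data.frame, one row per gene (see [gene_region_rates()]).
#' @export
region_rates_table <- function(genes, alns, flank_bp = 70L, intron_trim = 20L,
                               min_concat = 100L) {
  rows <- lapply(seq_along(genes), function(i) {
    p <- partition_regions(genes[[i]], alns[[i]], flank_bp, intron_trim,
                           min_concat)
    gene_region_rates(genes[[i]], p, alns[[i]])
  })
  do.call(rbind, rows)
}

#' Positional substitution-rate profile, stratified by ESE status
#'
#' Pools exon alignment columns over genes per junction distance and ESE
#' class and reports the uncorrected p-distance of each pool with its
#' binomial SEM `sqrt(r*(1-r)/n_sites)`. Cells with no counted sites are
#' omitted.
#'
#' @param genes list of [gene_model()].
#' @param alns list of matching [stitch_blocks()] results.
#' @param masks list of matching [annotate_alignment_ese()] masks.
#' @param dmin,dmax distance range (defaults 1 and 70).
#' @return data.frame with `distance`, `class` (`"ESE"`/`"non-ESE"`),
#'   `n_sites`, `n_subs`, `rate`, `sem`.
#' @export
positional_rate_profile <- function(genes, alns, masks, dmin = 1L,
                                    dmax = 70L) {
  stopifnot(length(genes) == length(alns), length(alns) == length(masks))
  bases <- c("A", "C", "G", "T")
  per_gene <- lapply(seq_along(genes), function(i) {
    ann <- annotate_junction_distance(genes[[i]], alns[[i]])
    ch <- aln_chars(alns[[i]], "exon")
    sel <- ann$valid & !is.na(ann$distance) & ann$distance >= dmin &
      ann$distance <= dmax & ch$ref %in% bases & ch$oth %in% bases
    if (!any(sel)) return(NULL)
    data.frame(distance = ann$distance[sel],
               ese = as.logical(masks[[i]])[sel],
               sub = ch$ref[sel] != ch$oth[sel])
  })
  df <- do.call(rbind, per_gene)
  if (is.null(df)) {
    return(data.frame(distance = integer(0), class = character(0),
                      n_sites = integer(0), n_subs = integer(0),
                      rate = numeric(0), sem = numeric(0)))
  }
  agg <- stats::aggregate(sub ~ distance + ese, data = df,
                          FUN = function(x) c(n = length(x), s = sum(x)))
  n <- agg$sub[, "n"]; s <- agg$sub[, "s"]
  rate <- s / n
  out <- data.frame(distance = agg$distance,
                    class = ifelse(agg$ese, "ESE", "non-ESE"),
                    n_sites = n, n_subs = s, rate = rate,
                    sem = sqrt(rate * (1 - rate) / n),
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$class), , drop = FALSE]
}

#' Pool exon alignment columns over genes for null resampling
#'
#' @param alns list of [stitch_blocks()] results.
#' @return data.frame with one row per gap-free, N-free exon column: `ref`,
#'   `oth`, `sub`.
#' @export
exon_column_pool <- function(alns) {
  bases <- c("A", "C", "G", "T")
  per <- lapply(alns, function(a) {
    ch <- aln_chars(a, "exon")
    ok <- ch$ref %in% bases & ch$oth %in% bases
    data.frame(ref = ch$ref[ok], oth = ch$oth[ok],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per)
  df$sub <- df$ref != df$oth
  df
}

#' Composition-matched null substitution rate
#'
#' Draws random column samples from a pooled concatenated exon alignment with
#' the same reference-base composition (exact per-base counts) and total size
#' as a target cell, and reports the mean p-distance over draws. Sampling is
#' without replacement within a draw.
#'
#' @param cell_composition named integer vector with entries `A`, `C`, `G`,
#'   `T`: reference-base counts of the target cell.
#' @param pool an [exon_column_pool()] data.frame.
#' @param n_draws number of Monte Carlo draws.
#' @param seed integer seed.
#' @return list: `rate` (mean over draws), `sd` (SD of per-draw rates, the
#'   Monte Carlo SE of a single draw), `draws` (per-draw rates).
#' @export
composition_matched_null <- function(cell_composition, pool, n_draws = 1000L,
                                     seed = 1L) {
  bases <- c("A", "C", "G", "T")
  cell_composition <- cell_composition[bases]
  cell_composition[is.na(cell_composition)] <- 0L
  idx_by_base <- lapply(bases, function(b) which(pool$ref == b))
  names(idx_by_base) <- bases
  for (b in bases) {
    if (cell_composition[[b]] > length(idx_by_base[[b]]))
      stop("pool too small for base ", b, ": need ", cell_composition[[b]],
           ", have ", length(idx_by_base[[b]]))
  }
  total <- sum(cell_composition)
  if (total == 0L) stop("empty cell composition")
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    subs <- 0L
    for (b in bases) {
      k <- cell_composition[[b]]
      if (k > 0L) {
        take <- idx_by_base[[b]][sample.int(length(idx_by_base[[b]]), k)]
        subs <- subs + sum(pool$sub[take])
      }
    }
    subs / total
  }, numeric(1))
  list(rate = mean(draws), sd = stats::sd(draws), draws = draws)
}

#' Predicted exon/intron log rate ratio from ESE constraint alone
#'
#' `log(1 - frac_flank * ese_density * slowdown)`: the exon/intron log rate
#' ratio expected if the only exonic constraint is a proportional rate
#' reduction on ESE bases within exon flanks, with non-ESE exonic sequence
#' evolving at the intronic rate.
#'
#' @param frac_flank fraction of exonic sequence in flank windows.
#' @param ese_density fraction of flank bases inside ESE motifs.
#' @param slowdown proportional rate reduction on ESE bases.
#' @return natural-log rate ratio (`NA` with a warning when the product
#'   reaches 1, where the ratio is undefined).
#' @export
expected_log_keki <- function(frac_flank, ese_density, slowdown) {
  x <- frac_flank * ese_density * slowdown
  if (x >= 1) {
    warning("constraint product >= 1: expected log ratio undefined")
    return(NA_real_)
  }
  log(1 - x)
}
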