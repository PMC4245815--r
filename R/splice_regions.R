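#' Create a validated hexamer set
#'
#' @param x character vector of 6-mers over `A,C,G,T` (case-insensitive).
#' @return unique uppercase character vector of class `"hexamer_set"`.
#' @export
hexamer_set <- function(x) {
  x <- toupper(as.character(x))
  if (any(nchar(x) != 6L)) stop("all hexamers must have length 6")
  if (any(grepl("[^ACGT]", x))) stop("hexamers must be over A,C,G,T")
  structure(unique(x), class = "hexamer_set")
}

#' Read a hexamer list (one 6-mer per line)
#' @param path plain-text file, one hexamer per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return a [hexamer_set()].
#' @export
read_hexamers <- function(path) {
  x <- trimws(readLines(path))
  hexamer_set(x[nzchar(x) & !startsWith(x, "#")])
}

#' Synthetic purine-rich ESE hexamer set
#'
#' A stand-in for an experimentally derived exonic-splice-enhancer hexamer
#' list: all 64 hexamers over `{A, G}`. ESEs are purine-rich, so a purine-only
#' family reproduces their compositional signature (and their enrichment
#' behaviour) while remaining fully synthetic. Use [read_hexamers()] to supply
#' a real, experimentally confirmed set instead.
#'
#' @return a [hexamer_set()] of 64 purine hexamers.
#' @export
default_ese_hexamers <- function() {
  grid <- expand.grid(rep(list(c("A", "G")), 6L), stringsAsFactors = FALSE)
  hexamer_set(apply(as.matrix(grid), 1L, paste, collapse = ""))
}

#' Scan an ungapped sequence for hexamer matches
#'
#' Position `i` is flagged when some hexamer of the set matches at a start
#' `s` with `s <= i <= s + 5`; overlapping matches union. `N` never matches.
#'
#' @param seq ungapped sequence over `A,C,G,T,N` (character scalar).
#' @param hexamers a [hexamer_set()] (may be empty).
#' @return logical vector, one flag per sequence position.
#' @export
scan_hexamers <- function(seq, hexamers) {
  seq <- toupper(seq)
  n <- nchar(seq)
  mask <- logical(n)
  if (n < 6L || length(hexamers) == 0L) return(mask)
  windows <- substring(seq, 1:(n - 5L), 6:n)
  starts <- which(windows %in% hexamers)
  if (length(starts)) {
    idx <- unique(as.vector(outer(starts, 0:5, `+`)))
    mask[idx] <- TRUE
  }
  mask
}

#' Annotate ESE matches on a stitched exon alignment
#'
#' Gaps are removed from the reference row, the ungapped sequence is scanned
#' with [scan_hexamers()], and flags are re-projected onto alignment columns.
#' Gap columns are never flagged; only the reference row is scanned.
#'
#' @param aln a [stitch_blocks()] result.
#' @param hexamers a [hexamer_set()].
#' @param scan_both also scan the other row and union the flags (off by
#'   default: the hexamer set defines reference-species enhancers).
#' @return logical mask over exon alignment columns (class `"ese_mask"`),
#'   with attribute `n_masked` = number of flagged reference nucleotides.
#' @export
annotate_alignment_ese <- function(aln, hexamers, scan_both = FALSE) {
  ch <- aln_chars(aln, "exon")
  mask <- logical(length(ch$ref))
  nongap <- which(ch$ref != "-")
  if (length(nongap))
    mask[nongap] <- scan_hexamers(paste(ch$ref[nongap], collapse = ""),
                                  hexamers)
  if (scan_both) {
    nongap2 <- which(ch$oth != "-")
    if (length(nongap2)) {
      m2 <- logical(length(ch$ref))
      m2[nongap2] <- scan_hexamers(paste(ch$oth[nongap2], collapse = ""),
                                   hexamers)
      mask <- mask | (m2 & ch$ref != "-")
    }
  }
  structure(mask, n_masked = sum(mask), class = "ese_mask")
}

#' ESE density of a gene
#'
#' Number of reference nucleotides lying inside at least one hexamer match,
#' divided by the summed ungapped exon length.
#'
#' @param aln a [stitch_blocks()] result.
#' @param mask matching [annotate_alignment_ese()] mask.
#' @return fraction in `[0, 1]`.
#' @export
ese_density <- function(aln, mask) {
  ch <- aln_chars(aln, "exon")
  L <- sum(ch$ref != "-")
  if (L == 0L) stop("gene '", aln$gene_id, "': zero exon length")
  sum(mask) / L
}

# Per-exon-column helper: ungapped reference position within its exon block
# and the block's ungapped length (internal). Gap columns get position NA.
exon_column_positions <- function(aln) {
  ch <- aln_chars(aln, "exon")
  nongap <- ch$ref != "-"
  pos <- rep(NA_integer_, length(nongap))
  blk <- aln$exon_block
  # position = running count of non-gap columns within each block
  pos[nongap] <- stats::ave(rep(1L, sum(nongap)), blk[nongap], FUN = cumsum)
  L <- integer(max(blk, 0L))
  if (length(blk)) {
    tab <- tapply(nongap, blk, sum)
    L[as.integer(names(tab))] <- as.integer(tab)
  }
  list(pos = pos, block = blk, block_len = L, nongap = nongap)
}

#' Junction distances of exon alignment columns
#'
#' Every exon is split in half on its ungapped reference length `L`
#' (the 5' half takes the extra base for odd `L`): the first `ceiling(L/2)`
#' positions are assigned their distance (1-based) to the 5' splice junction,
#' the rest their distance to the 3' junction. Halves abutting transcript ends
#' (the 5' half of the first exon, the 3' half of the last) are marked
#' invalid, as are gap columns; single-exon genes have no valid positions.
#' Distances are on ungapped reference coordinates, not alignment columns.
#'
#' @param gene a [gene_model()].
#' @param aln matching [stitch_blocks()] result.
#' @return data.frame over exon alignment columns: `distance`, `side`
#'   (`"5p"`/`"3p"`), `valid`.
#' @export
annotate_junction_distance <- function(gene, aln) {
  cp <- exon_column_positions(aln)
  ne <- n_exons(gene)
  n <- length(cp$block)
  dist <- rep(NA_integer_, n); side <- rep(NA_character_, n)
  valid <- logical(n)
  ok <- cp$nongap
  L <- cp$block_len[cp$block]
  half <- ceiling(L / 2)
  five <- ok & cp$pos <= half
  three <- ok & cp$pos > half
  dist[five] <- cp$pos[five]
  dist[three] <- L[three] - cp$pos[three] + 1L
  side[five] <- "5p"; side[three] <- "3p"
  valid[five] <- cp$block[five] > 1L
  valid[three] <- cp$block[three] < ne
  data.frame(distance = dist, side = side, valid = valid,
             stringsAsFactors = FALSE)
}

#' Partition a gene into exon flanks, exon cores and intron cores
#'
#' Each junction-adjacent exon end claims up to `flank_bp` ungapped reference
#' bases. Internal exons (junctions at both ends) never let a flank cross the
#' exon midpoint (the 5' half takes the extra base for odd lengths); a
#' terminal exon's single junction may claim up to the whole exon. Exon
#' columns not in a flank are core. Intron cores are the introns minus
#' `intron_trim` bases at each end (empty when the intron is shorter than
#' `2 * intron_trim`). The partition passes the length filter when the
#' concatenated flank, core and intron-core lengths are each at least
#' `min_concat`.
#'
#' @param gene a [gene_model()].
#' @param aln matching [stitch_blocks()] result.
#' @param flank_bp flank width per junction-adjacent exon end (default 70).
#' @param intron_trim bases trimmed from each intron end (default 20).
#' @param min_concat minimum concatenated length per region class (default 100).
#' @return list of class `"region_partition"`: integer column-index vectors
#'   `flank_cols`, `core_cols` (into the exon alignment), `introncore_cols`
#'   (into the intron alignment), ungapped lengths `L_flank`, `L_core`,
#'   `L_introncore`, and `passes_min_length`.
#' @export
partition_regions <- function(gene, aln, flank_bp = 70L, intron_trim = 20L,
                              min_concat = 100L) {
  cp <- exon_column_positions(aln)
  ne <- n_exons(gene)
  n <- length(cp$block)
  is_flank <- logical(n)
  if (n) {
    L <- cp$block_len[cp$block]
    has5 <- cp$block > 1L
    has3 <- cp$block < ne
    f5 <- ifelse(has5 & has3, pmin(flank_bp, ceiling(L / 2)),
                 ifelse(has5, pmin(flank_bp, L), 0L))
    f3 <- ifelse(has5 & has3, pmin(flank_bp, floor(L / 2)),
                 ifelse(has3, pmin(flank_bp, L), 0L))
    ok <- cp$nongap
    is_flank[ok] <- (cp$pos[ok] <= f5[ok]) | (cp$pos[ok] > L[ok] - f3[ok])
  }
  is_core <- cp$nongap & !is_flank
  # intron cores on the intron alignment
  ich <- aln_chars(aln, "intron")
  inongap <- ich$ref != "-"
  ipos <- rep(NA_integer_, length(inongap))
  if (length(inongap) && any(inongap))
    ipos[inongap] <- stats::ave(rep(1L, sum(inongap)),
                                aln$intron_block[inongap], FUN = cumsum)
  iL <- integer(0)
  if (length(aln$intron_block)) {
    tab <- tapply(inongap, aln$intron_block, sum)
    iL <- integer(max(aln$intron_block))
    iL[as.integer(names(tab))] <- as.integer(tab)
  }
  is_icore <- logical(length(inongap))
  if (length(inongap) && any(inongap)) {
    Li <- iL[aln$intron_block]
    is_icore <- inongap & !is.na(ipos) & ipos > intron_trim &
      ipos <= Li - intron_trim
  }
  out <- list(flank_cols = which(is_flank), core_cols = which(is_core),
              introncore_cols = which(is_icore),
              L_flank = sum(is_flank), L_core = sum(is_core),
              L_introncore = sum(is_icore))
  out$passes_min_length <- out$L_flank >= min_concat &&
    out$L_core >= min_concat && out$L_introncore >= min_concat
  class(out) <- "region_partition"
  out
}

#' Fraction of exonic sequence within flank windows of splice junctions
#'
#' `frac70 = L_flank / (L_flank + L_core)` on ungapped reference bases, using
#' the [partition_regions()] flank definition. Single-exon genes score 0.
#'
#' @param gene a [gene_model()].
#' @param aln matching [stitch_blocks()] result.
#' @param flank_bp flank width (default 70).
#' @return fraction in `[0, 1]`.
#' @export
frac70 <- function(gene, aln, flank_bp = 70L) {
  p <- partition_regions(gene, aln, flank_bp = flank_bp)
  tot <- p$L_flank + p$L_core
  if (tot == 0L) return(0)
  p$L_flank / tot
}

#' Positional ESE density profile
#'
#' For each junction distance `d` in `[dmin, dmax]`, the fraction of valid
#' exon positions at that distance whose reference base is ESE-flagged,
#' pooled over genes, with the SEM of the per-gene fractions.
#'
#' @param genes list of [gene_model()].
#' @param alns list of matching [stitch_blocks()] results.
#' @param masks list of matching [annotate_alignment_ese()] masks.
#' @param dmin,dmax distance range (defaults 6 and 70).
#' @return data.frame with `distance`, `density`, `sem`, `n_sites`,
#'   `n_genes`; distances with no valid positions are omitted.
#' @export
positional_density_profile <- function(genes, alns, masks,
                                       dmin = 6L, dmax = 70L) {
  stopifnot(length(genes) == length(alns), length(alns) == length(masks))
  per_gene <- lapply(seq_along(genes), function(i) {
    ann <- annotate_junction_distance(genes[[i]], alns[[i]])
    sel <- ann$valid & !is.na(ann$distance) &
      ann$distance >= dmin & ann$distance <= dmax
    if (!any(sel)) return(NULL)
    data.frame(gene = i, distance = ann$distance[sel],
               ese = as.logical(masks[[i]])[sel])
  })
  df <- do.call(rbind, per_gene)
  if (is.null(df)) {
    return(data.frame(distance = integer(0), density = numeric(0),
                      sem = numeric(0), n_sites = integer(0),
                      n_genes = integer(0)))
  }
  out <- lapply(sort(unique(df$distance)), function(d) {
    sub <- df[df$distance == d, , drop = FALSE]
    gfrac <- tapply(sub$ese, sub$gene, mean)
    data.frame(distance = d, density = mean(sub$ese),
               sem = if (length(gfrac) > 1L)
                 stats::sd(gfrac) / sqrt(length(gfrac)) else NA_real_,
               n_sites = nrow(sub), n_genes = length(gfrac))
  })
  do.call(rbind, out)
}
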