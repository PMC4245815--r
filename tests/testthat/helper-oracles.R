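# Independent oracles and small constructors used across the suite.

# Build a gene model plus stitched alignment from explicit gapped block
# strings (transcript order). Genomic coordinates are laid out left to right
# from `start` using the ungapped reference lengths.
toy_stitched <- function(exon_ref, exon_oth, intron_ref = character(0),
                         intron_oth = character(0), gene_id = "toy",
                         chrom = "chrT", start = 0L, strand = "+") {
  ug <- function(s) nchar(gsub("-", "", s, fixed = TRUE))
  ex_len <- vapply(exon_ref, ug, integer(1), USE.NAMES = FALSE)
  in_len <- vapply(intron_ref, ug, integer(1), USE.NAMES = FALSE)
  ne <- length(ex_len)
  # transcript order -> genomic order
  g_ex <- if (strand == "+") ex_len else rev(ex_len)
  g_in <- if (strand == "+") in_len else rev(in_len)
  starts <- integer(ne); ends <- integer(ne); pos <- start
  for (k in seq_len(ne)) {
    starts[k] <- pos; ends[k] <- pos + g_ex[k]
    pos <- ends[k] + if (k < ne) g_in[k] else 0L
  }
  gene <- gene_model(gene_id, chrom, start, ends[ne], strand,
                     cbind(starts, ends))
  blocks <- c(
    lapply(seq_len(ne), function(k)
      alignment_block(gene_id, "exon", k, exon_ref[k], exon_oth[k])),
    lapply(seq_along(intron_ref), function(k)
      alignment_block(gene_id, "intron", k, intron_ref[k], intron_oth[k])))
  list(gene = gene, aln = stitch_blocks(blocks, gene))
}

# Brute-force hexamer scan: test every window of every hexamer.
naive_scan <- function(seq, hexamers) {
  n <- nchar(seq)
  mask <- logical(n)
  if (n < 6L) return(mask)
  for (s in 1:(n - 5L)) {
    if (substr(seq, s, s + 5L) %in% hexamers) mask[s:(s + 5L)] <- TRUE
  }
  mask
}

# Exhaustive enumeration of nested structures: maximum pair count.
# Recurses over all placements of pairs; independent of the DP in src/.
enum_max_pairs <- function(chars, min_loop = 3L,
                           allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  chars <- chartr("T", "U", toupper(chars))
  ok_pair <- function(a, b) paste0(a, b) %in% allowed
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)                       # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (ok_pair(chars[i], chars[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(chars))
}

# Naive stop-codon count via explicit codon extraction.
naive_stops <- function(seq, frame) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  cnt <- 0L
  s <- 1L + frame
  while (s + 2L <= n) {
    if (substr(seq, s, s + 2L) %in% c("TAA", "TAG", "TGA")) cnt <- cnt + 1L
    s <- s + 3L
  }
  cnt
}

# Naive interval overlap count / merged coverage on half-open intervals.
naive_peak_count <- function(gene, track) {
  sel <- track$chrom == gene$chrom
  sum(track$start[sel] < gene$end & track$end[sel] > gene$start)
}
naive_coverage <- function(gene, track) {
  sel <- track$chrom == gene$chrom & track$start < gene$end &
    track$end > gene$start
  if (!any(sel)) return(0)
  covered <- logical(gene$end - gene$start)
  for (i in which(sel)) {
    lo <- max(track$start[i], gene$start) - gene$start + 1L
    hi <- min(track$end[i], gene$end) - gene$start
    covered[lo:hi] <- TRUE
  }
  mean(covered)
}

# First-order recursive partial correlation (single control).
recursive_partial <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%+%` <- function(a, b) paste0(a, b)
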