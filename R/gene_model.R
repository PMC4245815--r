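#' Construct a gene model
#'
#' A gene model is a transcript on a chromosome with an ordered set of exon
#' blocks. All coordinates are 0-based half-open (BED convention); introns are
#' the gaps between consecutive exons. Exon blocks are stored in genomic
#' order; for minus-strand genes [exon_order()] exposes transcript (5'->3')
#' order.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param start,end genomic span, 0-based half-open; `end > start`.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (start, end) of exon blocks in
#'   genomic order, non-overlapping, within `[start, end)`.
#' @param biotype `"lincRNA"` or `"coding"`.
#' @param activity optional named character vector mapping cell type to
#'   `"active"`/`"inactive"`.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = "+",
                       exons, biotype = "lincRNA", activity = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            biotype %in% c("lincRNA", "coding"))
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("gene '", gene_id, "': end must exceed start")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene '", gene_id, "': at least one exon required")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene '", gene_id, "': exon with non-positive length")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L)
    stop("gene '", gene_id, "': exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene '", gene_id, "': overlapping exons")
  if (exons[1L, 1L] < start || exons[nrow(exons), 2L] > end)
    stop("gene '", gene_id, "': exons outside gene span")
  structure(list(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand, exons = exons, biotype = biotype,
                 activity = activity),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %s, %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$biotype,
              nrow(x$exons)))
  invisible(x)
}

#' Number of exons of a gene model
#' @param gene a [gene_model()].
#' @return integer scalar.
#' @export
n_exons <- function(gene) nrow(gene$exons)

#' Intron blocks of a gene model
#'
#' @param gene a [gene_model()].
#' @return two-column matrix of intron `[start, end)` blocks in genomic order
#'   (zero rows for single-exon genes).
#' @export
introns <- function(gene) {
  ne <- n_exons(gene)
  if (ne < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = gene$exons[-ne, 2L], end = gene$exons[-1L, 1L])
}

#' Transcript-order index of exon (or intron) blocks
#'
#' Genomic-order block `exon_order(gene)[k]` is the k-th block in transcript
#' (5'->3') orientation: identity on plus-strand genes, reversed on minus.
#'
#' @param gene a [gene_model()].
#' @param n number of blocks (defaults to exon count).
#' @return integer vector of genomic-order indices in transcript order.
#' @export
exon_order <- function(gene, n = n_exons(gene)) {
  if (n == 0L) return(integer(0))
  if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
}

#' Unspliced gene length in bp
#' @param gene a [gene_model()].
#' @return integer, `end - start`.
#' @export
unspliced_length <- function(gene) gene$end - gene$start

#' Read gene models from a BED12 file
#'
#' Exon blocks are reconstructed from `blockStarts`/`blockSizes` relative to
#' `chromStart`. Malformed lines (block count inconsistent with the size or
#' start lists, zero-size blocks, fewer than 12 columns) raise an error naming
#' the offending line.
#'
#' @param path path to a 12-column BED file (whitespace separated).
#' @param biotype biotype assigned to all records.
#' @return list of [gene_model()] objects.
#' @export
read_bed12 <- function(path, biotype = "lincRNA") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
    if (length(f) < 12L)
      stop("BED12 parse error at line ", i, ": expected 12 columns, got ",
           length(f))
    nblk <- suppressWarnings(as.integer(f[10L]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    offs <- suppressWarnings(as.integer(strsplit(f[12L], ",")[[1L]]))
    if (is.na(nblk) || length(sizes) != nblk || length(offs) != nblk)
      stop("BED12 parse error at line ", i,
           ": blockCount disagrees with blockSizes/blockStarts")
    if (any(is.na(sizes)) || any(sizes <= 0L))
      stop("BED12 parse error at line ", i, ": blockSizes must be positive")
    cs <- as.integer(f[2L])
    gene_model(gene_id = f[4L], chrom = f[1L], start = cs,
               end = as.integer(f[3L]),
               strand = if (f[6L] %in% c("+", "-")) f[6L] else "+",
               exons = cbind(cs + offs, cs + offs + sizes),
               biotype = biotype)
  })
}

#' Write gene models to a BED12 file
#'
#' Inverse of [read_bed12()] on canonical records.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    offs <- g$exons[, 1L] - g$start
    sizes <- g$exons[, 2L] - g$exons[, 1L]
    paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand, g$start, g$end,
          "0", nrow(g$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
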