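#' Construct an alignment block
#'
#' One gapped pairwise alignment covering a single exon or intron of a gene,
#' with both rows in transcript (5'->3') orientation. The reference row's
#' ungapped length must equal the block's genomic length when stitched against
#' a gene model.
#'
#' @param gene_id gene identifier.
#' @param region_kind `"exon"` or `"intron"`.
#' @param ordinal 1-based index of the block in transcript orientation.
#' @param seq_ref,seq_other gapped sequences over `A,C,G,T,N,-`, equal length.
#' @return object of class `"aln_block"`.
#' @export
alignment_block <- function(gene_id, region_kind, ordinal, seq_ref, seq_other) {
  region_kind <- match.arg(region_kind, c("exon", "intron"))
  if (nchar(seq_ref) != nchar(seq_other))
    stop("block ", gene_id, "|", region_kind, "|", ordinal,
         ": rows differ in length (", nchar(seq_ref), " vs ",
         nchar(seq_other), ")")
  structure(list(gene_id = gene_id, region_kind = region_kind,
                 ordinal = as.integer(ordinal),
                 seq_ref = toupper(seq_ref), seq_other = toupper(seq_other)),
            class = "aln_block")
}

#' Read paired gapped FASTA alignment blocks
#'
#' The interchange format for per-block pairwise alignments is a pair of
#' FASTA files with matching headers `geneid|exon|k` / `geneid|intron|k`
#' (k = 1-based block index in transcript orientation): one file holds the
#' reference (e.g. human) rows, the other the second species.
#'
#' @param ref_path,other_path FASTA paths for reference and other species.
#' @return list of [alignment_block()] objects.
#' @export
read_alignment_fasta <- function(ref_path, other_path) {
  ref <- Biostrings::readBStringSet(ref_path)
  oth <- Biostrings::readBStringSet(other_path)
  if (!setequal(names(ref), names(oth)))
    stop("reference and other FASTA headers do not match")
  oth <- oth[names(ref)]
  lapply(seq_along(ref), function(i) {
    parts <- strsplit(names(ref)[i], "|", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("malformed alignment header '", names(ref)[i],
           "': expected geneid|kind|ordinal")
    alignment_block(parts[1L], parts[2L], as.integer(parts[3L]),
                    as.character(ref[[i]]), as.character(oth[[i]]))
  })
}

#' Write alignment blocks as paired gapped FASTA
#' @param blocks list of [alignment_block()] objects.
#' @param ref_path,other_path output FASTA paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_alignment_fasta <- function(blocks, ref_path, other_path) {
  nm <- vapply(blocks, function(b)
    paste(b$gene_id, b$region_kind, b$ordinal, sep = "|"), character(1))
  ref <- Biostrings::BStringSet(vapply(blocks, `[[`, character(1), "seq_ref"))
  oth <- Biostrings::BStringSet(vapply(blocks, `[[`, character(1), "seq_other"))
  names(ref) <- names(oth) <- nm
  Biostrings::writeXStringSet(ref, ref_path, width = 80L)
  Biostrings::writeXStringSet(oth, other_path, width = 80L)
  invisible(c(ref_path, other_path))
}

#' Stitch per-block alignments into concatenated exon and intron alignments
#'
#' Concatenates the gene's exon blocks (and separately intron blocks) in
#' transcript orientation, recording for every alignment column its source
#' block and within-block column offset. Blocks must be supplied complete:
#' one per exon and one per intron of the gene model.
#'
#' @param blocks list of [alignment_block()] for one gene.
#' @param gene the matching [gene_model()].
#' @return object of class `"stitched_alignment"`: a list with `gene_id`,
#'   character scalars `exon_ref`, `exon_other`, `intron_ref`, `intron_other`,
#'   and integer vectors `exon_block`, `exon_offset`, `intron_block`,
#'   `intron_offset` giving per-column provenance.
#' @export
stitch_blocks <- function(blocks, gene) {
  blocks <- Filter(function(b) b$gene_id == gene$gene_id, blocks)
  stitch_one <- function(kind, n_expected, genomic_len_transcript_order) {
    bl <- Filter(function(b) b$region_kind == kind, blocks)
    ords <- vapply(bl, `[[`, integer(1), "ordinal")
    missing <- setdiff(seq_len(n_expected), ords)
    if (length(missing))
      stop("gene '", gene$gene_id, "': missing ", kind, " block(s) ",
           paste(missing, collapse = ", "))
    if (anyDuplicated(ords))
      stop("gene '", gene$gene_id, "': duplicated ", kind, " block ordinal")
    bl <- bl[order(ords)]
    for (k in seq_len(n_expected)) {
      ug <- nchar(gsub("-", "", bl[[k]]$seq_ref, fixed = TRUE))
      if (ug != genomic_len_transcript_order[k])
        stop("gene '", gene$gene_id, "': ", kind, " block ", k,
             " ungapped reference length ", ug,
             " does not match genomic length ",
             genomic_len_transcript_order[k])
    }
    widths <- vapply(bl, function(b) nchar(b$seq_ref), integer(1))
    list(ref = paste(vapply(bl, `[[`, character(1), "seq_ref"), collapse = ""),
         other = paste(vapply(bl, `[[`, character(1), "seq_other"),
                       collapse = ""),
         block = rep(seq_len(n_expected), widths),
         offset = unlist(lapply(widths, seq_len), use.names = FALSE))
  }
  ne <- n_exons(gene)
  exon_len <- (gene$exons[, 2L] - gene$exons[, 1L])[exon_order(gene)]
  ex <- stitch_one("exon", ne, exon_len)
  intr <- introns(gene)
  if (nrow(intr) > 0L) {
    intron_len <- (intr[, 2L] - intr[, 1L])[exon_order(gene, nrow(intr))]
    int <- stitch_one("intron", nrow(intr), intron_len)
  } else {
    int <- list(ref = "", other = "", block = integer(0), offset = integer(0))
  }
  structure(list(gene_id = gene$gene_id,
                 exon_ref = ex$ref, exon_other = ex$other,
                 exon_block = ex$block, exon_offset = ex$offset,
                 intron_ref = int$ref, intron_other = int$other,
                 intron_block = int$block, intron_offset = int$offset),
            class = "stitched_alignment")
}

#' @export
print.stitched_alignment <- function(x, ...) {
  cat(sprintf("<stitched_alignment> %s: exon %d cols, intron %d cols\n",
              x$gene_id, nchar(x$exon_ref), nchar(x$intron_ref)))
  invisible(x)
}

# split a stitched alignment's rows into character vectors (internal)
aln_chars <- function(aln, region = c("exon", "intron")) {
  region <- match.arg(region)
  if (region == "exon")
    list(ref = strsplit(aln$exon_ref, "", fixed = TRUE)[[1L]],
         oth = strsplit(aln$exon_other, "", fixed = TRUE)[[1L]])
  else
    list(ref = strsplit(aln$intron_ref, "", fixed = TRUE)[[1L]],
         oth = strsplit(aln$intron_other, "", fixed = TRUE)[[1L]])
}

#' Indel fraction of a stitched alignment
#'
#' Fraction of alignment columns (exon and intron columns pooled) carrying a
#' gap in either row. Each column counts once even if both rows are gapped.
#'
#' @param aln a [stitch_blocks()] result.
#' @return fraction in `[0, 1]`.
#' @export
gap_fraction <- function(aln) {
  ex <- aln_chars(aln, "exon"); int <- aln_chars(aln, "intron")
  ref <- c(ex$ref, int$ref); oth <- c(ex$oth, int$oth)
  if (length(ref) == 0L)
    stop("gene '", aln$gene_id, "': zero-length alignment")
  mean(ref == "-" | oth == "-")
}

#' Discard genes whose alignments exceed an indel-fraction threshold
#'
#' Genes with pooled [gap_fraction()] strictly greater than `threshold` are
#' removed (a fraction exactly at the threshold is kept).
#'
#' @param genes list of [gene_model()].
#' @param alignments list of matching [stitch_blocks()] results (same order).
#' @param threshold maximum tolerated indel fraction (default 0.15).
#' @return list with `genes`, `alignments` (retained subsets) and `report`,
#'   a data.frame of all gene ids, gap fractions and kept flags.
#' @export
filter_by_gap <- function(genes, alignments, threshold = 0.15) {
  stopifnot(length(genes) == length(alignments))
  gf <- vapply(alignments, gap_fraction, numeric(1))
  keep <- gf <= threshold
  list(genes = genes[keep], alignments = alignments[keep],
       report = data.frame(
         gene_id = vapply(genes, `[[`, character(1), "gene_id"),
         gap_fraction = gf, kept = keep, stringsAsFactors = FALSE))
}
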