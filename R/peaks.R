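#' Construct a peak track
#'
#' A peak track is a set of `[start, end)` intervals per chromosome, sorted by
#' start within chromosome, with an optional score. Overlapping records are
#' retained as-is; merging is performed only inside coverage queries.
#'
#' @param chrom,start,end parallel vectors of interval coordinates.
#' @param score optional numeric score per interval.
#' @return data.frame of class `"peak_track"` with columns
#'   `chrom`, `start`, `end`, `score`, sorted by (chrom, start, end).
#' @export
peak_track <- function(chrom = character(0), start = integer(0),
                       end = integer(0), score = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("peak with start >= end")
  if (is.null(score)) score <- rep(NA_real_, length(start))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_track", "data.frame")
  df
}

#' Read a BED3+/broadPeak file into a peak track
#'
#' Accepts any tab/space separated file whose first three columns are
#' chrom, start, end. For broadPeak input (9 columns) the 7th column
#' (signalValue) is kept as the score; otherwise a numeric 5th column is used
#' when present. Empty files yield a valid empty track.
#'
#' @param path input path.
#' @return a [peak_track()].
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(peak_track())
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("peak parse error at line ", which(ncols < 3L)[1L],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("peak parse error at line ", bad[1L], ": start must be < end")
  score <- rep(NA_real_, length(lines))
  has7 <- ncols >= 9L
  score[has7] <- suppressWarnings(
    as.numeric(vapply(fields[has7], `[[`, character(1), 7L)))
  has5 <- !has7 & ncols >= 5L
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, character(1), 5L)))
  peak_track(chrom, start, end, score)
}

#' Write a peak track as BED
#' @param track a [peak_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(track, path) {
  df <- as.data.frame(track)
  sc <- ifelse(is.na(df$score), 0, df$score)
  writeLines(paste(df$chrom, df$start, df$end, ".", sc, ".", sep = "\t"), path)
  invisible(path)
}

# IRanges view of the intervals on one chromosome (internal).
track_ranges <- function(track, chrom) {
  sel <- track$chrom == chrom
  # half-open [start, end) -> closed 1-based [start+1, end]
  IRanges::IRanges(start = track$start[sel] + 1L, end = track$end[sel])
}
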