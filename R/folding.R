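#' Maximum-base-pairing secondary structure
#'
#' Nussinov-style dynamic program maximizing the number of nested base pairs
#' subject to a minimum loop size (`j - i > min_loop`), used as a proxy for
#' minimum-free-energy folding: the fraction of paired nucleotides is the
#' stability statistic of interest, not the structure itself. `T` is read as
#' `U`; characters outside `A,C,G,U` never pair. Traceback ties are broken
#' deterministically (pairing preferred, then the smaller partner index).
#'
#' @param seq RNA/DNA sequence (character scalar, length >= 1).
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param allowed_pairs character vector of allowed pair types; default
#'   Watson-Crick plus GU wobble.
#' @return list of class `"fold_result"`: `length`, `n_paired`,
#'   `paired_fraction`, and `pairs` (2-column matrix of 1-based indices).
#' @export
fold_maxpair <- function(seq, min_loop = 3L,
                         allowed_pairs = c("AU", "UA", "GC", "CG",
                                           "GU", "UG")) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  n <- nchar(seq)
  if (n == 0L) stop("cannot fold a zero-length sequence")
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
                c("A", "C", "G", "U")) - 1L
  code[is.na(code)] <- -1L
  can <- matrix(FALSE, 4L, 4L, dimnames = list(c("A", "C", "G", "U"),
                                               c("A", "C", "G", "U")))
  for (p in toupper(allowed_pairs)) {
    can[substr(p, 1L, 1L), substr(p, 2L, 2L)] <- TRUE
  }
  pairs <- .nussinov_pairs(code, as.integer(min_loop), can)
  structure(list(length = n, n_paired = 2L * nrow(pairs),
                 paired_fraction = 2 * nrow(pairs) / n,
                 pairs = pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d nt, %d paired (%.3f)\n",
              x$length, x$n_paired, x$paired_fraction))
  invisible(x)
}

#' Parse a dot-bracket structure string into a fold result
#'
#' Adapter half of the plug-in contract for external folding tools: any
#' program that emits a dot-bracket line (e.g. RNAfold) can stand in for the
#' built-in folder.
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return a `"fold_result"` (see [fold_maxpair()]).
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  plist <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      plist[[length(plist) + 1L]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    } else if (ch[i] != ".") stop("invalid dot-bracket character '",
                                  ch[i], "'")
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  if (length(plist)) pairs <- do.call(rbind, plist)
  structure(list(length = length(ch), n_paired = 2L * nrow(pairs),
                 paired_fraction = if (length(ch))
                   2 * nrow(pairs) / length(ch) else 0,
                 pairs = pairs),
            class = "fold_result")
}

#' Parse a .ct (connectivity table) structure file
#'
#' @param path path to a `.ct` file (first line: length + title; then one row
#'   per base with the pairing partner in column 5, 0 = unpaired).
#' @return a `"fold_result"` (see [fold_maxpair()]).
#' @export
parse_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]][1L])
  body <- lines[seq.int(2L, length.out = n)]
  f <- lapply(strsplit(trimws(body), "[ \t]+"), as.character)
  i <- as.integer(vapply(f, `[[`, character(1), 1L))
  j <- as.integer(vapply(f, `[[`, character(1), 5L))
  sel <- j > 0L & i < j
  pairs <- cbind(i[sel], j[sel])
  structure(list(length = n, n_paired = 2L * nrow(pairs),
                 paired_fraction = if (n) 2 * nrow(pairs) / n else 0,
                 pairs = pairs),
            class = "fold_result")
}

#' Fold with an external command-line tool
#'
#' Runs a dot-bracket-emitting folder (default: ViennaRNA's `RNAfold`) on one
#' sequence and parses its output, satisfying the same contract as
#' [fold_maxpair()]. Requires the tool on `PATH`.
#'
#' @param seq sequence to fold.
#' @param cmd command to run; must read FASTA on stdin and print a
#'   dot-bracket line.
#' @param args extra arguments.
#' @return a `"fold_result"`.
#' @export
fold_external <- function(seq, cmd = "RNAfold", args = "--noPS") {
  out <- system2(cmd, args, input = c(">q", seq), stdout = TRUE)
  db_line <- grep("^[.()]+", out, value = TRUE)
  if (!length(db_line)) stop("no dot-bracket line in output of ", cmd)
  parse_dot_bracket(sub("^([.()]+).*$", "\\1", db_line[1L]))
}

#' Folding stability of a gene's transcript
#'
#' Applies a folder to the spliced transcript (exon-concatenated ungapped
#' reference sequence, transcript orientation) and returns the fraction of
#' paired nucleotides. A 5' window cap keeps the cubic-time folder tractable
#' on long transcripts; `max_len = Inf` folds the full sequence.
#'
#' @param aln a [stitch_blocks()] result.
#' @param folder folding function taking a sequence and returning a
#'   `"fold_result"` (default [fold_maxpair()]).
#' @param max_len fold at most this many nucleotides from the 5' end
#'   (default 1000).
#' @return paired fraction in `[0, 1]`.
#' @export
folding_stability <- function(aln, folder = fold_maxpair, max_len = 1000L) {
  ch <- aln_chars(aln, "exon")
  seq <- paste(ch$ref[ch$ref != "-"], collapse = "")
  if (is.finite(max_len) && nchar(seq) > max_len)
    seq <- substr(seq, 1L, max_len)
  folder(seq)$paired_fraction
}
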