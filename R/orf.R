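#' Coding sequence container
#'
#' A light container for a nucleotide sequence with a declared identity and
#' reading-frame status. When `is_cds` is `TRUE` the sequence is taken to
#' start at codon 1 of an open reading frame and must be at least 6 bp.
#'
#' @param id single identifier string.
#' @param seq nucleotide string over A/C/G/T (lower case is upper-cased).
#' @param is_cds does the sequence start at codon 1 of an ORF?
#' @return an object of class `coding_sequence` (a named list with elements
#'   `id`, `seq`, `is_cds`, `length`).
#' @export
coding_sequence <- function(id, seq, is_cds = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  .check_nt(seq)
  if (isTRUE(is_cds) && nchar(seq) < 6L)
    stop("a CDS must be at least 6 bp")
  structure(list(id = id, seq = seq, is_cds = isTRUE(is_cds),
                 length = nchar(seq)),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", x$length, " bp",
      if (x$is_cds) " (CDS)", "\n", sep = "")
  invisible(x)
}

#' Is an ORF still intact?
#'
#' An ORF is intact relative to its starting state when (a) its length equals
#' `original_length`, (b) it begins with ATG (optional, see
#' `require_start`), and (c) no complete codon strictly before the final
#' codon is a stop (TAA/TAG/TGA). For sequences whose length is not a
#' multiple of 3 the trailing partial codon is the final codon and can never
#' contain a stop, so every complete codon is checked; for codon-multiple
#' sequences the last complete codon is the final codon and may be a stop.
#'
#' @param seq nucleotide string (A/C/G/T only; anything else is an error).
#' @param original_length length (bp) of the starting ORF.
#' @param require_start must the first codon be ATG?
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_orf_intact("ATGAAATAA", 9)  # TRUE
#' is_orf_intact("ATGTAATAA", 9)  # FALSE: internal stop
#' is_orf_intact("ATGAATAA", 9)   # FALSE: length changed
#' @export
is_orf_intact <- function(seq, original_length, require_start = TRUE) {
  .check_nt(seq)
  stopifnot(is.numeric(original_length), original_length > 0)
  cpp_orf_intact(seq, as.integer(original_length), isTRUE(require_start))
}

#' Longest open reading frame of a sequence
#'
#' Scans all three reading frames (and, for `strand_mode = "both"`, the
#' reverse complement) for ATG-to-stop ORFs and returns the longest; if an
#' ATG has no downstream in-frame stop the ORF runs to the last complete
#' codon (open 3' end). Ties are broken in favour of the 5'-most start on
#' the forward strand. Coordinates are 1-based inclusive on the input
#' (forward) sequence; the interval includes the stop codon when present but
#' `n_codons` excludes it.
#'
#' @param seq nucleotide string.
#' @param strand_mode `"forward"` or `"both"`.
#' @return list with `start`, `end`, `n_codons`, `strand`, `has_stop`;
#'   `n_codons = 0` and `NA` coordinates when no ATG exists.
#' @export
longest_orf <- function(seq, strand_mode = c("forward", "both")) {
  strand_mode <- match.arg(strand_mode)
  seq <- toupper(seq)
  .check_nt(seq)
  best <- list(start = NA_integer_, end = NA_integer_, n_codons = 0L,
               strand = "+", has_stop = FALSE)
  scan_strand <- function(s, strand) {
    L <- nchar(s)
    res <- best
    for (frame in 0:2) {
      n <- (L - frame) %/% 3L
      if (n < 1L) next
      starts <- seq.int(frame + 1L, by = 3L, length.out = n)
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      if (!length(atg)) next
      stops <- which(codons %in% STOP_CODONS)
      for (a in atg) {
        nxt <- stops[stops > a]
        if (length(nxt)) {
          end_codon <- nxt[1L]
          nc <- end_codon - a
          has_stop <- TRUE
        } else {
          end_codon <- n
          nc <- n - a + 1L
          has_stop <- FALSE
        }
        if (nc > res$n_codons ||
            (nc == res$n_codons && nc > 0L && !is.na(res$start) &&
             starts[a] < res$start)) {
          res <- list(start = starts[a], end = starts[end_codon] + 2L,
                      n_codons = nc, strand = strand, has_stop = has_stop)
        }
      }
    }
    res
  }
  fwd <- scan_strand(seq, "+")
  if (fwd$n_codons > best$n_codons) best <- fwd
  if (strand_mode == "both") {
    rev <- scan_strand(revcomp(seq), "-")
    if (rev$n_codons > best$n_codons) {
      # map back to forward coordinates
      L <- nchar(seq)
      best <- list(start = L - rev$end + 1L, end = L - rev$start + 1L,
                   n_codons = rev$n_codons, strand = "-",
                   has_stop = rev$has_stop)
    }
  }
  best
}
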