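#' Scoring parameters for the frameshift-tolerant codon alignment
#'
#' Substitution scores are BLOSUM62 at codon granularity (the retrocopy
#' codon is translated and scored against the parent residue, including
#' the `*` row so stop codons score like stops). Gaps are affine at codon
#' granularity: a first inserted/deleted codon costs
#' `gap_open + 3 * gap_extend`, each further contiguous codon
#' `3 * gap_extend`. A +/-1-nt frameshift transition (a 4-nt or 2-nt
#' "codon") costs `frameshift`.
#'
#' @param gap_open,gap_extend nucleotide-scale gap penalties (defaults
#'   11 and 1).
#' @param frameshift frameshift penalty (default 15).
#' @param min_score alignments scoring below this are reported
#'   `"unalignable"` (default 100, far above the ~40 expected for the
#'   best chance local block of unrelated sequences at this scale and
#'   far below the score of any genuine retrocopy).
#' @return list of class `frameshift_scoring`.
#' @export
frameshift_scoring <- function(gap_open = 11, gap_extend = 1,
                               frameshift = 15, min_score = 100) {
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 frameshift = frameshift, min_score = min_score),
            class = "frameshift_scoring")
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# codon index (16*a + 4*b + c with A=0,C=1,G=2,T=3) -> BLOSUM62 row index
.codon_rows <- local({
  cache <- NULL
  function(submat) {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                                paste0))
      # outer order: first index varies fastest; rebuild explicitly
      codons <- character(64)
      k <- 1L
      for (a in bases) for (b in bases) for (c in bases) {
        codons[k] <- paste0(a, b, c)
        k <- k + 1L
      }
      aas <- Biostrings::GENETIC_CODE[codons]
      cache <<- match(aas, rownames(submat)) - 1L
    }
    cache
  }
})

#' Map inactivating mutations in a retrocopy
#'
#' Aligns the retrocopy nucleotide sequence to the parent protein
#' (terminal stop included as `*`) with a three-state dynamic programme
#' that tolerates +/-1-nt frameshifts (see [frameshift_scoring()]).
#' The alignment is local (one best block): parent codons and retrocopy
#' bases outside the block are free, so 5'-truncated copies and
#' unalignable UTR overhangs align without penalty, and events are
#' reported within the aligned block only. Reported events, in parent
#' codon coordinates (1-based):
#' * `premature_stop` - an aligned retrocopy codon translating to a stop
#'   before the parent's terminal stop codon;
#' * `frameshift_ins` / `frameshift_del` - a 1-nt insertion or deletion
#'   relative to the parent reading frame.
#' Ties are resolved deterministically (match > frameshift > gap, then
#' leftmost).
#'
#' @param retro_seq retrocopy nucleotide sequence (the locus sequence in
#'   mRNA orientation).
#' @param parent a [parent_gene], or a plain amino-acid string (parent
#'   protein without terminal stop).
#' @param scoring a [frameshift_scoring] object.
#' @return list of class `mutation_map` with `status` (`"aligned"` or
#'   `"unalignable"`), `score`, `events` (data frame `type`,
#'   `parent_codon`), `parent_start`, `parent_end`.
#' @export
map_inactivating_mutations <- function(retro_seq, parent,
                                       scoring = frameshift_scoring()) {
  retro_seq <- toupper(retro_seq)
  .check_nt(retro_seq, "retro_seq")
  prot <- if (inherits(parent, "parent_gene")) parent$protein_seq
          else toupper(parent)
  prot <- paste0(sub("\\*$", "", prot), "*")
  sm <- .blosum62()
  prot_col <- match(strsplit(prot, "")[[1L]], colnames(sm)) - 1L
  if (anyNA(prot_col)) stop("parent protein contains unknown residues")
  res <- cpp_align_frameshift(
    retro_seq, prot, .codon_rows(sm), prot_col, sm,
    scoring$gap_open + 3 * scoring$gap_extend, 3 * scoring$gap_extend,
    scoring$frameshift)
  empty <- data.frame(type = character(0), parent_codon = integer(0))
  if (!isTRUE(res$aligned) || res$score < scoring$min_score) {
    return(structure(list(status = "unalignable",
                          score = if (isTRUE(res$aligned)) res$score
                                  else NA_real_,
                          events = empty, parent_start = NA_integer_,
                          parent_end = NA_integer_),
                     class = "mutation_map"))
  }
  types <- c("premature_stop", "frameshift_ins", "frameshift_del")
  ev <- if (length(res$event_type)) {
    df <- data.frame(type = types[res$event_type],
                     parent_codon = res$parent_codon)
    df[order(df$parent_codon), , drop = FALSE]
  } else empty
  rownames(ev) <- NULL
  structure(list(status = "aligned", score = res$score, events = ev,
                 parent_start = res$parent_start,
                 parent_end = res$parent_end),
            class = "mutation_map")
}

#' @export
print.mutation_map <- function(x, ...) {
  cat(sprintf("<mutation_map> %s (score %.1f), %d inactivating event(s)\n",
              x$status, x$score, nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
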