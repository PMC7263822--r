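#' Scan a protein for cytidine-deaminase HxE-CxxC motifs
#'
#' A3-family deaminase domains coordinate zinc with an H-x-E motif
#' followed, after a spacer, by C-x-x-C. The scan reports every H-x-E
#' whose downstream C-x-x-C starts within `spacer` residues of the end of
#' the H-x-E (default 20-40, bracketing the ~25-30-residue spacer of real
#' A3 domains) as a full domain hit, ordered N- to C-terminal; C-x-x-C
#' motifs not claimed by any H-x-E are reported as partial hits. Each
#' C-x-x-C is claimed by at most one (the nearest upstream) H-x-E.
#'
#' @param protein_seq amino-acid string.
#' @param spacer two-element numeric: allowed gap (residues) between the
#'   end of H-x-E and the start of C-x-x-C.
#' @return data frame with columns `domain` (`"domain1"`, `"domain2"`, ...
#'   for full hits; `"partial"` for unpaired C-x-x-C), `start`, `end`
#'   (1-based inclusive interval from the H of H-x-E to the final C of
#'   C-x-x-C, or the C-x-x-C alone for partials) and `complete`.
#' @examples
#' detect_deaminase_motifs(
#'   paste0("MAHAEKLLKKKKKKKKKKKKKKKKKKKKKKKKKKCAACW"))
#' @export
detect_deaminase_motifs <- function(protein_seq, spacer = c(20, 40)) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  protein_seq <- toupper(protein_seq)
  if (grepl("[^A-Z*]", protein_seq))
    stop("protein_seq must be an amino-acid string")
  hxe <- .find_overlapping(protein_seq, "(?=H.E)")
  cxxc <- .find_overlapping(protein_seq, "(?=C..C)")
  used_c <- logical(length(cxxc))
  full <- list()
  for (h in hxe) {
    gap <- cxxc - (h + 3L)   # residues between end of HxE and start of CxxC
    ok <- which(!used_c & gap >= spacer[1L] & gap <= spacer[2L])
    if (!length(ok)) next
    k <- ok[1L]
    used_c[k] <- TRUE
    full[[length(full) + 1L]] <- c(start = h, end = cxxc[k] + 3L)
  }
  out <- data.frame(domain = character(0), start = integer(0),
                    end = integer(0), complete = logical(0))
  if (length(full)) {
    m <- do.call(rbind, full)
    out <- data.frame(domain = paste0("domain", seq_len(nrow(m))),
                      start = m[, "start"], end = m[, "end"],
                      complete = TRUE)
  }
  if (any(!used_c)) {
    part <- data.frame(domain = "partial", start = cxxc[!used_c],
                       end = cxxc[!used_c] + 3L, complete = FALSE)
    out <- rbind(out, part)
  }
  rownames(out) <- NULL
  out
}

.find_overlapping <- function(s, pattern) {
  m <- gregexpr(pattern, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Flank-gene synteny support for a retrocopy locus
#'
#' Compares the gene names flanking a retrocopy in two species (within
#' the conventionally 1-Mbp window on either side). Orthologous insertion
#' loci share flanking genes; `both_sides` is the strongest support,
#' `one_side` weaker (orthologous retrocopy clusters can show a shared
#' gene on only one flank), `none` no support.
#'
#' @param flanks_a,flanks_b lists with character vectors `up` and `down`
#'   of flank gene names, ordered away from the locus.
#' @param window documented flank window size in bp (not enforced; the
#'   caller extracts the flank lists).
#' @return object of class `synteny_support`: list with `category`
#'   (`"both_sides"`, `"one_side"`, `"none"`), `shared_upstream`,
#'   `shared_downstream`, `window`.
#' @export
synteny_support <- function(flanks_a, flanks_b, window = 1e6) {
  stopifnot(is.list(flanks_a), is.list(flanks_b),
            all(c("up", "down") %in% names(flanks_a)),
            all(c("up", "down") %in% names(flanks_b)))
  if (!length(c(flanks_a$up, flanks_a$down)) ||
      !length(c(flanks_b$up, flanks_b$down)))
    warning("empty flank list: synteny category is 'none'")
  up <- intersect(flanks_a$up, flanks_b$up)
  down <- intersect(flanks_a$down, flanks_b$down)
  category <- if (length(up) && length(down)) "both_sides"
              else if (length(up) || length(down)) "one_side"
              else "none"
  structure(list(category = category, shared_upstream = up,
                 shared_downstream = down, window = window),
            class = "synteny_support")
}

#' @export
print.synteny_support <- function(x, ...) {
  cat(sprintf("<synteny_support> %s (up: %s; down: %s)\n", x$category,
              paste(x$shared_upstream, collapse = ","),
              paste(x$shared_downstream, collapse = ",")))
  invisible(x)
}
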