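# Brute-force / independent reference implementations used to verify the
# package's operations. Each oracle is written directly from the
# definition of the operation, in plain R, independent of the code path
# it checks.

# -- intactness, written from the definition -------------------------------
oracle_intact <- function(s, L0, require_start = TRUE) {
  if (nchar(s) != L0 || nchar(s) < 3) return(FALSE)
  if (require_start && substr(s, 1, 3) != "ATG") return(FALSE)
  n_complete <- nchar(s) %/% 3
  final_codon <- ceiling(nchar(s) / 3)
  n_check <- min(n_complete, final_codon - 1)
  if (n_check < 1) return(TRUE)
  for (c in seq_len(n_check)) {
    if (substr(s, 3 * c - 2, 3 * c) %in% c("TAA", "TAG", "TGA"))
      return(FALSE)
  }
  TRUE
}

# fraction of all 3L single substitutions that break the ORF
oracle_f_stop <- function(orf) {
  L <- nchar(orf)
  bases <- c("A", "C", "G", "T")
  broken <- 0L
  for (pos in seq_len(L)) {
    cur <- substr(orf, pos, pos)
    for (b in setdiff(bases, cur)) {
      s <- orf
      substr(s, pos, pos) <- b
      if (!oracle_intact(s, L)) broken <- broken + 1L
    }
  }
  broken / (3 * L)
}

# -- longest ORF: enumerate every ATG, scan codons to the next stop --------
oracle_longest_orf <- function(seq, strand_mode = "forward") {
  stops <- c("TAA", "TAG", "TGA")
  scan <- function(s) {
    L <- nchar(s)
    best <- list(start = NA, end = NA, n_codons = 0, has_stop = FALSE)
    for (start in seq_len(max(L - 2, 0))) {
      if (substr(s, start, start + 2) != "ATG") next
      nc <- 0
      has_stop <- FALSE
      end <- start + 2
      pos <- start
      while (pos + 2 <= L) {
        codon <- substr(s, pos, pos + 2)
        if (pos > start && codon %in% stops) {
          has_stop <- TRUE
          end <- pos + 2
          break
        }
        nc <- nc + 1
        end <- pos + 2
        pos <- pos + 3
      }
      if (nc > best$n_codons) {
        best <- list(start = start, end = end, n_codons = nc,
                     has_stop = has_stop)
      }
    }
    best
  }
  fwd <- scan(seq)
  fwd$strand <- "+"
  if (strand_mode == "both") {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
    bwd <- scan(rc)
    if (bwd$n_codons > fwd$n_codons) {
      L <- nchar(seq)
      return(list(start = L - bwd$end + 1, end = L - bwd$start + 1,
                  n_codons = bwd$n_codons, strand = "-",
                  has_stop = bwd$has_stop))
    }
  }
  fwd
}

# -- percentile crossing: naive linear scan --------------------------------
oracle_percentiles <- function(fracs, times, percentiles) {
  vapply(percentiles, function(p) {
    for (i in seq_along(fracs)) if (fracs[i] <= p) return(times[i])
    NA_real_
  }, numeric(1))
}

# -- read assignment: substring scan over all references and strands -------
oracle_assign <- function(read, refs) {
  if (grepl("[^ACGT]", read) || !nzchar(read)) return("none")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(read, "")[[1]]),
                                     collapse = ""))
  hit <- vapply(refs, function(r) {
    grepl(read, r, fixed = TRUE) || grepl(rc, r, fixed = TRUE)
  }, logical(1))
  n <- sum(hit)
  if (n == 0) "none" else if (n > 1) "multi" else names(refs)[hit]
}

# -- motif scan: position-by-position pattern match ------------------------
oracle_motifs <- function(protein, spacer = c(20, 40)) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  hxe <- integer(0)
  cxxc <- integer(0)
  for (i in seq_len(max(n - 2, 0)))
    if (aa[i] == "H" && aa[i + 2] == "E") hxe <- c(hxe, i)
  for (i in seq_len(max(n - 3, 0)))
    if (aa[i] == "C" && aa[i + 3] == "C") cxxc <- c(cxxc, i)
  used <- logical(length(cxxc))
  full <- NULL
  for (h in hxe) {
    for (k in seq_along(cxxc)) {
      gap <- cxxc[k] - (h + 3)
      if (!used[k] && gap >= spacer[1] && gap <= spacer[2]) {
        used[k] <- TRUE
        full <- rbind(full, c(start = h, end = cxxc[k] + 3))
        break
      }
    }
  }
  list(full = full, partial = cxxc[!used])
}

# -- frameshift alignment: independent local DP over the same move set -----
oracle_align_score <- function(nt, prot, gap_open = 11, gap_extend = 1,
                               fs = 15) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  prot <- paste0(sub("\\*$", "", prot), "*")
  paa <- strsplit(prot, "")[[1]]
  n <- nchar(nt)
  m <- length(paa)
  open3 <- gap_open + 3 * gap_extend
  ext3 <- 3 * gap_extend
  tr <- function(i) {  # aa of codon formed by nt[i-2..i]
    Biostrings::GENETIC_CODE[[substr(nt, i - 2, i)]]
  }
  S <- function(i, j) sm[tr(i), paa[j]]
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  pmax3 <- function(i, j) max(M[i + 1, j + 1], X[i + 1, j + 1],
                              Y[i + 1, j + 1])
  for (i in 1:n) {
    for (j in 0:m) {
      if (j >= 1) {
        cand <- -Inf
        if (i >= 3) cand <- max(cand, S(i, j),
                                pmax3(i - 3, j - 1) + S(i, j))
        if (i >= 4) cand <- max(cand, pmax3(i - 4, j - 1) + S(i, j) - fs)
        if (i >= 2) cand <- max(cand, pmax3(i - 2, j - 1) - fs)
        M[i + 1, j + 1] <- cand
      }
      if (i >= 3)
        X[i + 1, j + 1] <- max(M[i - 3 + 1, j + 1] - open3,
                               X[i - 3 + 1, j + 1] - ext3)
      if (j >= 1)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - open3, Y[i + 1, j] - ext3)
    }
  }
  max(M)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random ORF: ATG + stop-free codons + terminal stop
random_orf <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  safe <- names(gc)[gc != "*" & names(gc) != "ATG"]
  paste(c("ATG", sample(safe, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}
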