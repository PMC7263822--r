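# Annotation of candidate retrocopy loci. Coordinates are 1-based
# inclusive; query (q_*) coordinates are on the parent mRNA and always
# ascend; subject (s_*) coordinates are on the genomic contig and always
# ascend, with orientation carried by `strand`.

#' Parent gene container
#'
#' @param id gene identifier.
#' @param mrna_seq spliced mRNA sequence.
#' @param cds_start,cds_end 1-based inclusive CDS interval on the mRNA
#'   (including the stop codon).
#' @param exons data frame of genomic exon intervals (`seqid`, `start`,
#'   `end`, `strand`), ordered, non-overlapping.
#' @param protein_seq translation of the CDS without the terminal stop;
#'   recomputed (and checked, if supplied) from the mRNA.
#' @return object of class `parent_gene`.
#' @export
parent_gene <- function(id, mrna_seq, cds_start, cds_end, exons,
                        protein_seq = NULL) {
  mrna_seq <- toupper(mrna_seq)
  .check_nt(mrna_seq, "mrna_seq")
  stopifnot(cds_start >= 1, cds_end <= nchar(mrna_seq), cds_start < cds_end)
  stopifnot(is.data.frame(exons),
            all(c("seqid", "start", "end", "strand") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  widths <- exons$end - exons$start + 1L
  if (sum(widths) != nchar(mrna_seq))
    stop("exon widths must sum to the mRNA length")
  cds <- substr(mrna_seq, cds_start, cds_end)
  prot <- translate_nt(cds)
  prot <- sub("\\*$", "", prot)
  if (!is.null(protein_seq) && !identical(prot, protein_seq))
    stop("translate(CDS) does not match the supplied protein_seq")
  structure(list(id = id, mrna_seq = mrna_seq, cds_start = cds_start,
                 cds_end = cds_end, exons = exons, protein_seq = prot),
            class = "parent_gene")
}

#' @export
print.parent_gene <- function(x, ...) {
  cat(sprintf("<parent_gene> %s: %d bp mRNA, CDS %d-%d, %d exons\n",
              x$id, nchar(x$mrna_seq), x$cds_start, x$cds_end,
              nrow(x$exons)))
  invisible(x)
}

# mRNA positions of the last base of each exon but the final one
# (exon-exon junctions on the mRNA)
mrna_junctions <- function(parent) {
  w <- parent$exons$end - parent$exons$start + 1L
  if (length(w) < 2L) return(integer(0))
  cumsum(w)[-length(w)]
}

#' Naive seed-and-extend search of a query against genome contigs
#'
#' Exact k-mer seeds of the query are located in each contig (both
#' strands), grouped by diagonal, extended ungapped while bases match
#' exactly, and reported as ungapped hit segments with their percent
#' identity; segments below `min_identity` are dropped. This matcher is
#' intended for the package's synthetic genomes; genome-scale sensitive
#' homology search is out of scope and standard 12-column tabular hits
#' from an external search tool can be supplied instead.
#'
#' @param query named single-sequence character vector (parent mRNA).
#' @param genome named character vector of contig sequences.
#' @param seed_length exact seed length (default 15).
#' @param min_identity minimum percent identity of a segment (default 80).
#' @return hit data frame in the [read_blast_tabular()] layout.
#' @export
find_hits <- function(query, genome, seed_length = 15L,
                      min_identity = 80) {
  stopifnot(length(query) == 1L, !is.null(names(query)))
  qid <- names(query)
  qseq <- toupper(query[[1L]])
  L <- nchar(qseq)
  if (L < seed_length) return(empty_hits())
  starts <- seq_len(L - seed_length + 1L)
  kmers <- substring(qseq, starts, starts + seed_length - 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  out <- list()
  for (contig in names(genome)) {
    cseq <- toupper(genome[[contig]])
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") cseq else revcomp(cseq)
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
      sp <- Biostrings::startIndex(mi)
      nhit <- lengths(sp)
      if (!sum(nhit)) next
      qpos <- rep.int(starts, nhit)
      spos <- unlist(sp[nhit > 0L], use.names = FALSE)
      diag <- spos - qpos
      for (d in unique(diag)) {
        qs <- sort(qpos[diag == d])
        # split seed runs separated by more than one seed length
        brk <- c(0L, which(diff(qs) > seed_length * 2L), length(qs))
        for (b in seq_len(length(brk) - 1L)) {
          run <- qs[(brk[b] + 1L):brk[b + 1L]]
          q1 <- min(run); q2 <- max(run) + seed_length - 1L
          s1 <- q1 + d; s2 <- q2 + d
          # ungapped exact extension
          while (q1 > 1L && s1 > 1L &&
                 substr(qseq, q1 - 1L, q1 - 1L) ==
                 substr(subject, s1 - 1L, s1 - 1L)) {
            q1 <- q1 - 1L; s1 <- s1 - 1L
          }
          slen <- nchar(subject)
          while (q2 < L && s2 < slen &&
                 substr(qseq, q2 + 1L, q2 + 1L) ==
                 substr(subject, s2 + 1L, s2 + 1L)) {
            q2 <- q2 + 1L; s2 <- s2 + 1L
          }
          qsub <- strsplit(substr(qseq, q1, q2), "")[[1L]]
          ssub <- strsplit(substr(subject, s1, s2), "")[[1L]]
          pid <- 100 * mean(qsub == ssub)
          if (pid < min_identity) next
          # map minus-strand coordinates back to the forward contig
          if (strand == "-") {
            t1 <- clen - s2 + 1L; t2 <- clen - s1 + 1L
            s1 <- t1; s2 <- t2
          }
          out[[length(out) + 1L]] <- data.frame(
            query_id = qid, subject_id = contig, percent_identity = pid,
            alignment_length = q2 - q1 + 1L, q_start = q1, q_end = q2,
            s_start = s1, s_end = s2, strand = strand)
        }
      }
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$subject_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Merge collinear candidate hits into loci
#'
#' Hits on the same contig and strand whose genomic gaps are at most
#' `max_gap` and whose mRNA coordinates progress collinearly (ascending
#' with the genome on `+`, descending on `-`) are chained into a single
#' locus. Hits on different strands are never merged.
#'
#' @param hits hit data frame ([read_blast_tabular()] layout).
#' @param max_gap largest genomic gap (bp) bridged within one locus.
#' @return data frame of loci (`locus_id`, `subject_id`, `strand`,
#'   `s_start`, `s_end`, `q_start`, `q_end`, `n_hits`) with the member
#'   hits attached as a list column `hits`, sorted by genomic start.
#' @export
merge_hits <- function(hits, max_gap = 50L) {
  if (!nrow(hits)) {
    out <- data.frame(locus_id = character(0), subject_id = character(0),
                      strand = character(0), s_start = integer(0),
                      s_end = integer(0), q_start = integer(0),
                      q_end = integer(0), n_hits = integer(0))
    out$hits <- list()
    return(out)
  }
  loci <- list()
  for (key in unique(paste(hits$subject_id, hits$strand))) {
    grp <- hits[paste(hits$subject_id, hits$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$s_start), , drop = FALSE]
    minus <- grp$strand[1L] == "-"
    cur <- grp[1L, , drop = FALSE]
    flush <- function(cur) {
      loci[[length(loci) + 1L]] <<- list(
        subject_id = cur$subject_id[1L], strand = cur$strand[1L],
        s_start = min(cur$s_start), s_end = max(cur$s_end),
        q_start = min(cur$q_start), q_end = max(cur$q_end),
        hits = cur)
    }
    if (nrow(grp) > 1L) for (i in 2:nrow(grp)) {
      prev <- cur[nrow(cur), ]
      gap <- grp$s_start[i] - prev$s_end - 1L
      collinear <- if (minus) {
        grp$q_end[i] <= prev$q_start + 30L
      } else {
        grp$q_start[i] >= prev$q_end - 30L
      }
      if (gap <= max_gap && collinear) {
        cur <- rbind(cur, grp[i, , drop = FALSE])
      } else {
        flush(cur)
        cur <- grp[i, , drop = FALSE]
      }
    }
    flush(cur)
  }
  ord <- order(vapply(loci, function(l) l$subject_id, ""),
               vapply(loci, function(l) l$s_start, 1L))
  loci <- loci[ord]
  out <- data.frame(
    locus_id = sprintf("locus_%02d", seq_along(loci)),
    subject_id = vapply(loci, function(l) l$subject_id, ""),
    strand = vapply(loci, function(l) l$strand, ""),
    s_start = as.integer(vapply(loci, function(l) l$s_start, 1)),
    s_end = as.integer(vapply(loci, function(l) l$s_end, 1)),
    q_start = as.integer(vapply(loci, function(l) l$q_start, 1)),
    q_end = as.integer(vapply(loci, function(l) l$q_end, 1)),
    n_hits = vapply(loci, function(l) nrow(l$hits), 1L))
  out$hits <- lapply(loci, function(l) l$hits)
  out
}

#' Classify a merged locus as intronless
#'
#' For each parent exon-exon junction covered by the locus (with at least
#' `margin` bp of aligned parent mRNA on each side, so a chance 1-2 bp
#' extension past a junction is not mistaken for coverage), the genomic
#' alignment either bridges the junction contiguously (one hit spans it
#' with margin, or the excess genomic gap across it is at most `max_gap`)
#' or shows an intron-scale excess gap (at least `min_intron`). A locus
#' is intronless (`TRUE`) when at least `min_exons_bridged - 1` junctions
#' are bridged and none shows an intron; any intron-scale gap classifies
#' the locus `FALSE` (the parental gene itself); a locus covering no
#' junction is indeterminate (`NA`): single-exon evidence cannot
#' distinguish a retrocopy from a parental fragment.
#'
#' @param locus one row of [merge_hits()] output.
#' @param parent a [parent_gene].
#' @param min_exons_bridged minimum exons that must be bridged (default 2).
#' @param max_gap contiguity tolerance (bp).
#' @param min_intron smallest excess genomic gap treated as an intron.
#' @param margin minimum aligned bases required on each side of a
#'   junction before it counts as covered or bridged.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
classify_intronless <- function(locus, parent, min_exons_bridged = 2L,
                                max_gap = 50L, min_intron = 200L,
                                margin = 8L) {
  junctions <- mrna_junctions(parent)
  hits <- locus$hits[[1L]]
  hits <- hits[order(hits$q_start), , drop = FALSE]
  n_bridged <- 0L
  n_intron <- 0L
  for (J in junctions) {
    if (J - locus$q_start + 1L < margin ||
        locus$q_end - J < margin) next  # not covered with margin
    # nearest aligned blocks reaching the junction from each side
    li <- which(hits$q_start <= J - margin + 1L & hits$q_end >= J)
    ri <- which(hits$q_end >= J + margin & hits$q_start <= J + 1L)
    l <- if (length(li)) li[which.max(hits$q_end[li])] else {
      cand <- which(hits$q_start <= J - margin + 1L)
      if (length(cand)) cand[which.max(hits$q_end[cand])] else NA_integer_
    }
    r <- if (length(ri)) ri[which.min(hits$q_start[ri])] else {
      cand <- which(hits$q_end >= J + margin)
      if (length(cand)) cand[which.min(hits$q_start[cand])] else NA_integer_
    }
    if (is.na(l) || is.na(r)) next
    if (l == r) {  # one hit spans the junction with margin
      n_bridged <- n_bridged + 1L
      next
    }
    q_gap <- hits$q_start[r] - hits$q_end[l] - 1L
    s_gap <- if (locus$strand == "-")
      hits$s_start[l] - hits$s_end[r] - 1L
    else hits$s_start[r] - hits$s_end[l] - 1L
    excess <- s_gap - q_gap
    if (excess <= max_gap) n_bridged <- n_bridged + 1L
    else if (excess >= min_intron) n_intron <- n_intron + 1L
  }
  if (n_intron > 0L) return(FALSE)
  if (n_bridged >= min_exons_bridged - 1L) return(TRUE)
  NA
}

# Group contiguity-merged loci into candidate regions: loci on the same
# contig and strand, separated by at most cluster_gap bp of genome and
# collinear in parent-mRNA coordinates, belong to one candidate (seed
# islands of a diverged retrocopy; the exons of the parental gene).
cluster_loci <- function(loci, cluster_gap = 5000L) {
  if (nrow(loci) <= 1L) return(loci)
  groups <- list()
  for (key in unique(paste(loci$subject_id, loci$strand))) {
    grp <- loci[paste(loci$subject_id, loci$strand) == key, ,
                drop = FALSE]
    grp <- grp[order(grp$s_start), , drop = FALSE]
    minus <- grp$strand[1L] == "-"
    idx <- list(1L)
    if (nrow(grp) > 1L) for (i in 2:nrow(grp)) {
      members <- idx[[length(idx)]]
      prev <- members[length(members)]
      gap <- grp$s_start[i] - grp$s_end[prev] - 1L
      collinear <- if (minus) grp$q_end[i] <= grp$q_start[prev] + 30L
                   else grp$q_start[i] >= grp$q_end[prev] - 30L
      if (gap <= cluster_gap && collinear)
        idx[[length(idx)]] <- c(members, i)
      else idx[[length(idx) + 1L]] <- i
    }
    for (members in idx) {
      sub <- grp[members, , drop = FALSE]
      groups[[length(groups) + 1L]] <- list(
        subject_id = sub$subject_id[1L], strand = sub$strand[1L],
        s_start = min(sub$s_start), s_end = max(sub$s_end),
        q_start = min(sub$q_start), q_end = max(sub$q_end),
        hits = do.call(rbind, sub$hits))
    }
  }
  ord <- order(vapply(groups, function(l) l$subject_id, ""),
               vapply(groups, function(l) l$s_start, 1L))
  groups <- groups[ord]
  out <- data.frame(
    locus_id = sprintf("locus_%02d", seq_along(groups)),
    subject_id = vapply(groups, function(l) l$subject_id, ""),
    strand = vapply(groups, function(l) l$strand, ""),
    s_start = as.integer(vapply(groups, function(l) l$s_start, 1)),
    s_end = as.integer(vapply(groups, function(l) l$s_end, 1)),
    q_start = as.integer(vapply(groups, function(l) l$q_start, 1)),
    q_end = as.integer(vapply(groups, function(l) l$q_end, 1)),
    n_hits = vapply(groups, function(l) nrow(l$hits), 1L))
  out$hits <- lapply(groups, function(l) l$hits)
  out
}

#' 5' truncation and covered span of a locus
#'
#' @param locus one row of [merge_hits()] output.
#' @param parent a [parent_gene].
#' @return list with `truncation_5p` (bases of parent mRNA missing at the
#'   5' end; 0 for full-length copies) and `covered_span`.
#' @export
measure_truncation <- function(locus, parent) {
  list(truncation_5p = locus$q_start - 1L,
       covered_span = locus$q_end - locus$q_start + 1L)
}

#' Annotate candidate retrocopy loci
#'
#' Runs the full annotation chain on a set of candidate hits (from
#' [read_blast_tabular()] or [find_hits()]): merging into loci, intronless
#' classification, 5'-truncation measurement, longest-ORF scan on the
#' extracted locus sequence, frameshift-tolerant mapping of inactivating
#' mutations against the parent protein, and deaminase-motif scan of the
#' longest-ORF translation.
#'
#' @param hits candidate hit data frame.
#' @param parent a [parent_gene].
#' @param genome named character vector of contig sequences.
#' @param max_gap,min_intron see [classify_intronless()].
#' @param cluster_gap collinear loci separated by at most this much
#'   genome are treated as one candidate region (seed islands of a
#'   diverged copy; the exon hits of the parental gene across its
#'   introns).
#' @param scoring see [map_inactivating_mutations()].
#' @return object of class `retrocopy_calls`: the locus data frame with
#'   columns `is_intronless`, `truncation_5p`, `covered_span`,
#'   `orf_codons`, `orf_start`, `orf_end` and list columns `mutations`
#'   (data frames of `type`, `parent_codon`) and `motifs`.
#' @export
annotate_retrocopies <- function(hits, parent, genome, max_gap = 50L,
                                 min_intron = 200L, cluster_gap = 5000L,
                                 scoring = frameshift_scoring()) {
  loci <- merge_hits(hits, max_gap = max_gap)
  loci <- cluster_loci(loci, cluster_gap = cluster_gap)
  n <- nrow(loci)
  loci$is_intronless <- rep(NA, n)
  loci$truncation_5p <- rep(NA_integer_, n)
  loci$covered_span <- rep(NA_integer_, n)
  loci$orf_codons <- rep(NA_integer_, n)
  loci$orf_start <- rep(NA_integer_, n)
  loci$orf_end <- rep(NA_integer_, n)
  loci$mutations <- vector("list", n)
  loci$motifs <- vector("list", n)
  for (i in seq_len(n)) {
    locus <- loci[i, , drop = FALSE]
    loci$is_intronless[i] <- classify_intronless(
      locus, parent, max_gap = max_gap, min_intron = min_intron)
    tr <- measure_truncation(locus, parent)
    loci$truncation_5p[i] <- tr$truncation_5p
    loci$covered_span[i] <- tr$covered_span
    seq <- substr(genome[[locus$subject_id]], locus$s_start, locus$s_end)
    if (locus$strand == "-") seq <- revcomp(seq)
    orf <- longest_orf(seq, strand_mode = "forward")
    loci$orf_codons[i] <- orf$n_codons
    loci$orf_start[i] <- orf$start
    loci$orf_end[i] <- orf$end
    aln <- map_inactivating_mutations(seq, parent, scoring = scoring)
    loci$mutations[[i]] <- aln$events
    if (orf$n_codons > 0L) {
      pep <- translate_nt(substr(seq, orf$start, orf$end))
      pep <- sub("\\*$", "", pep)
      loci$motifs[[i]] <- detect_deaminase_motifs(pep)
    } else {
      loci$motifs[[i]] <- detect_deaminase_motifs("A")
    }
  }
  class(loci) <- c("retrocopy_calls", class(loci))
  loci
}

#' Write retrocopy calls as GFF3
#'
#' 1-based inclusive coordinates (the GFF3 standard); the `attributes`
#' column carries `ID`, `intronless`, `truncation_5p` and
#' `longest_orf_codons`.
#'
#' @param calls a `retrocopy_calls` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_gff3 <- function(calls, path) {
  df <- data.frame(
    seqid = calls$subject_id, type = "retrocopy",
    start = calls$s_start, end = calls$s_end, strand = calls$strand,
    attributes = sprintf(
      "ID=%s;intronless=%s;truncation_5p=%d;longest_orf_codons=%d",
      calls$locus_id, ifelse(is.na(calls$is_intronless), "indeterminate",
                             tolower(calls$is_intronless)),
      calls$truncation_5p, calls$orf_codons))
  write_gff3(df, path)
}
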