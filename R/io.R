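# Shared I/O. File formats: FASTA/FASTQ via Biostrings, GFF3 read via
# rtracklayer, GFF3 written by a small 9-column writer (1-based inclusive
# coordinates, the GFF3 standard), 12-column BLAST tabular, plain TSV.
# Internal coordinates everywhere in this package are 1-based inclusive.

#' Read a FASTA file
#'
#' Duplicate record ids are an error; lower-case bases are upper-cased with
#' a warning; an empty file yields an empty set with a warning.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (any(grepl("[a-z]", seqs))) {
    warning("lower-case bases upper-cased in ", path)
    seqs <- toupper(seqs)
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (reads only)
#'
#' @param path FASTQ file, optionally gzipped.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record ",
         n_lines %/% 4L + 1L)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads),
                   function(n) paste(rep("I", n), collapse = ""), "")
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Parse 12-column BLAST tabular output
#'
#' Standard `outfmt 6` columns: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Input coordinates
#' are 1-based inclusive; minus-strand hits (sstart > send) are normalised
#' to ascending subject coordinates with `strand = "-"`.
#'
#' @param path tab-separated hit file (no header).
#' @return data frame of candidate hits with columns `query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1L],
         " at line ", which(nf != 12L)[1L])
  m <- do.call(rbind, fields)
  num <- function(i) as.numeric(m[, i])
  s1 <- num(9); s2 <- num(10)
  minus <- s1 > s2
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3), alignment_length = as.integer(num(4)),
    q_start = as.integer(num(7)), q_end = as.integer(num(8)),
    s_start = as.integer(ifelse(minus, s2, s1)),
    s_end = as.integer(ifelse(minus, s1, s2)),
    strand = ifelse(minus, "-", "+"))
  if (any(hits$q_start > hits$q_end))
    stop("query coordinates must ascend (qstart <= qend)")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0))
}

#' Write hits in 12-column BLAST tabular format
#'
#' Inverse of [read_blast_tabular()]: minus-strand hits are emitted with
#' descending subject coordinates.
#'
#' @param hits data frame as returned by [read_blast_tabular()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  s1 <- ifelse(hits$strand == "-", hits$s_end, hits$s_start)
  s2 <- ifelse(hits$strand == "-", hits$s_start, hits$s_end)
  df <- data.frame(hits$query_id, hits$subject_id,
                   hits$percent_identity, hits$alignment_length,
                   0L, 0L, hits$q_start, hits$q_end, s1, s2, 0, 0)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read exon annotations from GFF3
#'
#' @param path GFF3 file; rows with `type == "exon"` are used.
#' @return data frame with `seqid`, `start`, `end`, `strand` (1-based
#'   inclusive), ordered by genomic start.
#' @export
read_exons_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  data.frame(seqid = as.character(df$seqnames), start = df$start,
             end = df$end, strand = as.character(df$strand))
}

# Minimal GFF3 writer; 1-based inclusive coordinates per the standard.
write_gff3 <- function(df, path, source = "retrofossil") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    attrs <- df$attributes
    writeLines(paste(df$seqid, source, df$type, df$start, df$end, ".",
                     df$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
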