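# Exact-match unique-assignment expression counting: a read counts for a
# reference only when it is a perfect full-length substring of exactly one
# reference (forward or reverse-complement); reads matching several
# references are "multi", reads matching none (or containing N) are
# "none". This is the filter that fully determines the published
# search-then-filter scheme, so only the filter is implemented.

#' Build a reference set for read assignment
#'
#' @param seqs named character vector (parent mRNA/CDS plus every
#'   retrocopy sequence); ids must be unique, sequences non-empty.
#' @return named character vector of class `reference_set`.
#' @export
reference_set <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs))) stop("reference ids must be unique")
  if (any(!nzchar(seqs))) stop("reference sequences must be non-empty")
  structure(toupper(seqs), class = "reference_set")
}

#' Assign one read to a unique reference
#'
#' @param read nucleotide string; any non-ACGT character (e.g. N) makes
#'   the read unassignable.
#' @param refs a [reference_set] (or named character vector).
#' @param both_strands also match the reverse complement of the read?
#' @return a reference id, `"multi"` or `"none"`.
#' @export
assign_read <- function(read, refs, both_strands = TRUE) {
  assign_reads(read, refs, both_strands = both_strands)[[1L]]
}

#' Vectorised exact-match unique assignment
#'
#' @param reads character vector of read sequences.
#' @param refs a [reference_set].
#' @param both_strands also match reverse complements?
#' @return character vector: reference id, `"multi"` or `"none"` per read.
#' @export
assign_reads <- function(reads, refs, both_strands = TRUE) {
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  ref_set <- Biostrings::DNAStringSet(unclass(refs))
  out <- character(length(reads))
  reads <- toupper(reads)
  bad <- grepl("[^ACGT]", reads) | !nzchar(reads)
  out[bad] <- "none"
  for (i in which(!bad)) {
    hit <- Biostrings::vcountPattern(reads[i], ref_set) > 0L
    if (both_strands)
      hit <- hit | Biostrings::vcountPattern(revcomp(reads[i]),
                                             ref_set) > 0L
    n <- sum(hit)
    out[i] <- if (n == 0L) "none" else if (n > 1L) "multi"
              else names(refs)[hit]
  }
  out
}

#' Dataset metadata table
#'
#' @param dataset_id,species,tissue character vectors (recycled to equal
#'   length); `dataset_id` must be unique.
#' @param tissue_class one of `"germline"`, `"brain"`, `"blood"`,
#'   `"other"` per dataset; missing/unknown classes fall back to
#'   `"other"` with a warning.
#' @return data frame of class `dataset_meta`.
#' @export
dataset_meta <- function(dataset_id, species, tissue, tissue_class) {
  df <- data.frame(dataset_id = dataset_id, species = species,
                   tissue = tissue, tissue_class = tissue_class)
  if (anyDuplicated(df$dataset_id)) stop("dataset ids must be unique")
  known <- c("germline", "brain", "blood", "other")
  bad <- !(df$tissue_class %in% known)
  if (any(bad)) {
    warning("unknown tissue class(es) set to 'other': ",
            paste(unique(df$tissue_class[bad]), collapse = ", "))
    df$tissue_class[bad] <- "other"
  }
  class(df) <- c("dataset_meta", class(df))
  df
}

#' Read a dataset metadata TSV
#'
#' Expects columns `dataset_id`, `species`, `tissue`, `tissue_class`.
#'
#' @param path tab-separated file with a header row.
#' @return a [dataset_meta] data frame.
#' @export
read_dataset_meta <- function(path) {
  df <- read_tsv(path)
  need <- c("dataset_id", "species", "tissue", "tissue_class")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  dataset_meta(df$dataset_id, df$species, df$tissue, df$tissue_class)
}

#' Count uniquely assigned reads per dataset
#'
#' @param fastq_files character vector of FASTQ paths, one per dataset,
#'   in the row order of `meta`.
#' @param refs a [reference_set].
#' @param meta a [dataset_meta] with one row per file.
#' @param both_strands see [assign_reads()].
#' @return object of class `read_count_table`: list with `counts` (matrix
#'   dataset x reference), `qc` (data frame `dataset_id`, `multi`,
#'   `none`, `total`) and `meta`.
#' @export
count_reads <- function(fastq_files, refs, meta, both_strands = TRUE) {
  stopifnot(length(fastq_files) == nrow(meta))
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  counts <- matrix(0L, nrow = nrow(meta), ncol = length(refs),
                   dimnames = list(meta$dataset_id, names(refs)))
  qc <- data.frame(dataset_id = meta$dataset_id, multi = 0L, none = 0L,
                   total = 0L)
  for (i in seq_along(fastq_files)) {
    reads <- read_fastq(fastq_files[i])
    qc$total[i] <- length(reads)
    if (!length(reads)) next
    asg <- assign_reads(reads, refs, both_strands = both_strands)
    tab <- table(factor(asg, levels = c(names(refs), "multi", "none")))
    counts[i, ] <- as.integer(tab[names(refs)])
    qc$multi[i] <- as.integer(tab[["multi"]])
    qc$none[i] <- as.integer(tab[["none"]])
  }
  structure(list(counts = counts, qc = qc, meta = meta),
            class = "read_count_table")
}

#' Tissue-averaged expression matrix
#'
#' Cells are mean read counts over all datasets of one (species, tissue)
#' pair; the log view is `log10(count + 1)`. Row order follows the
#' reference order; columns are grouped by tissue class in the order
#' germline, brain, blood, other (then order of first appearance).
#'
#' @param counts a [count_reads()] result.
#' @param meta optional [dataset_meta] (defaults to the one stored in
#'   `counts`).
#' @return object of class `expression_matrix`: list with `raw` and
#'   `log10` matrices (reference x "species:tissue") and `columns`
#'   metadata.
#' @export
build_matrix <- function(counts, meta = NULL) {
  stopifnot(inherits(counts, "read_count_table"))
  if (is.null(meta)) meta <- counts$meta
  stopifnot(nrow(meta) >= 1L)
  key <- paste(meta$species, meta$tissue, sep = ":")
  class_rank <- match(meta$tissue_class,
                      c("germline", "brain", "blood", "other"))
  ord <- order(class_rank, match(key, unique(key)))
  cols <- unique(key[ord])
  raw <- sapply(cols, function(k) {
    rows <- which(key == k)
    if (length(rows) == 1L) as.numeric(counts$counts[rows, ])
    else colMeans(counts$counts[rows, , drop = FALSE])
  })
  raw <- matrix(raw, nrow = ncol(counts$counts),
                dimnames = list(colnames(counts$counts), cols))
  col_meta <- data.frame(column = cols,
                         species = sub(":.*$", "", cols),
                         tissue = sub("^[^:]*:", "", cols),
                         tissue_class = meta$tissue_class[
                           match(cols, key)])
  structure(list(raw = raw, log10 = log10(raw + 1), columns = col_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d references x %d (species, tissue)\n",
              nrow(x$raw), ncol(x$raw)))
  print(round(x$log10, 3))
  invisible(x)
}

#' @method as.matrix expression_matrix
#' @export
as.matrix.expression_matrix <- function(x, ...) x$raw
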