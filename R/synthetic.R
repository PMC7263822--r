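# Fully labelled synthetic data: an A3G-like parent gene, a genome with
# planted retrocopies of known age/truncation/selection status, and
# error-free reads. Background sequence is i.i.d. uniform nucleotides --
# adequate for exact-match and alignment testing at desk scale, with no
# repeat structure.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study system: a 384-residue A3G-like parent
#' protein with two HxE...CxxC deaminase motifs, four coding exons,
#' retrocopies born continually over the ~25 My history of the New World
#' monkey radiation with a marked 3' bias (full-length with probability
#' `p_full`, else a geometric 5' truncation), evolving under the
#' `"nwm-like"` mutation preset either neutrally or with rejection of
#' ORF-breaking events (`orf_constrained`), and error-free uniform reads
#' at a configurable per-copy expression.
#'
#' @param seed integer seed (the generator is deterministic under it).
#' @param n_codons parent protein length in residues (excluding the stop).
#' @param exon_count number of coding exons.
#' @param intron_length two-element range of intron lengths (bp).
#' @param utr5,utr3 UTR lengths on the mRNA (bp).
#' @param n_retrocopies number of planted copies.
#' @param ages optional vector of copy ages in years (recycled); default
#'   uniform on 0-25 My.
#' @param selection optional character vector `"neutral"` /
#'   `"orf_constrained"` per copy; default one in four constrained.
#' @param p_full probability a copy is full-length.
#' @param trunc_mean mean of the geometric 5'-truncation (bp).
#' @param params [mutation_params] driving copy divergence.
#' @param expression reads per reference per dataset (recycled over
#'   parent + copies).
#' @param read_length read length (bp).
#' @param flank background flank around planted features (bp).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = NULL, n_codons = 384L,
                             exon_count = 4L,
                             intron_length = c(300L, 3000L),
                             utr5 = 60L, utr3 = 90L,
                             n_retrocopies = 8L, ages = NULL,
                             selection = NULL, p_full = 0.6,
                             trunc_mean = 300,
                             params = mutation_preset("nwm-like"),
                             expression = 50L, read_length = 100L,
                             flank = 6000L) {
  stopifnot(n_codons >= 60L, exon_count >= 1L, p_full >= 0, p_full <= 1)
  if (!is.null(ages) && any(ages > 5e7))
    stop("copy ages must be at most 50 My")
  structure(list(seed = seed, n_codons = as.integer(n_codons),
                 exon_count = as.integer(exon_count),
                 intron_length = intron_length, utr5 = as.integer(utr5),
                 utr3 = as.integer(utr3),
                 n_retrocopies = as.integer(n_retrocopies), ages = ages,
                 selection = selection, p_full = p_full,
                 trunc_mean = trunc_mean, params = params,
                 expression = expression,
                 read_length = as.integer(read_length),
                 flank = as.integer(flank)),
            class = "generator_config")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# amino acid -> synonymous codons under the standard code
.aa_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- split(names(Biostrings::GENETIC_CODE),
                      Biostrings::GENETIC_CODE)
    cache
  }
})

reverse_translate <- function(protein) {
  tab <- .aa_codons()
  aas <- strsplit(protein, "")[[1L]]
  paste(vapply(aas, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

#' Generate the synthetic A3G-like parent gene
#'
#' Builds a random protein of `n_codons` residues starting with M and
#' carrying two planted HxE...CxxC deaminase domains (N-terminal around
#' residue 65, C-terminal around residue 255, 28-residue spacers),
#' resampling until the motif scan reports exactly the two planted
#' domains; reverse-translates it with uniformly chosen synonymous
#' codons, appends a stop, adds UTRs, splits the mRNA into exons and
#' embeds the exon/intron locus in background sequence on its own contig.
#'
#' @param config a [generator_config].
#' @return list with `parent` (a [parent_gene]), `contig` (named
#'   character: the parental genomic contig), `locus` (1-based interval
#'   of the gene on the contig), `motifs` (planted motif intervals on the
#'   protein), `cds` (the CDS string).
#' @export
generate_parent <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_codons
  aas <- setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")
  h1 <- 65L
  h2 <- min(255L, n - 40L)
  spacer <- 28L
  planted <- data.frame(start = c(h1, h2),
                        end = c(h1 + 3L + spacer + 3L,
                                h2 + 3L + spacer + 3L))
  repeat {
    prot <- c("M", sample(aas, n - 1L, replace = TRUE))
    for (h in c(h1, h2)) {
      prot[h] <- "H"; prot[h + 2L] <- "E"
      cs <- h + 3L + spacer
      prot[cs] <- "C"; prot[cs + 3L] <- "C"
      prot[cs + 1L] <- "A"; prot[cs + 2L] <- "A"
    }
    prot <- paste(prot, collapse = "")
    hits <- detect_deaminase_motifs(prot)
    full <- hits[hits$complete, , drop = FALSE]
    if (nrow(full) == 2L && nrow(hits) == 2L &&
        all(full$start == planted$start) && all(full$end == planted$end))
      break
  }
  cds <- paste0(reverse_translate(prot),
                sample(STOP_CODONS, 1L))
  mrna <- paste0(random_nt(config$utr5), cds, random_nt(config$utr3))
  # exonise: junctions keep every exon at least 50 bp
  L <- nchar(mrna)
  k <- config$exon_count
  repeat {
    cuts <- sort(sample(seq.int(50L, L - 50L), k - 1L))
    if (k == 1L || all(diff(c(0L, cuts, L)) >= 50L)) break
  }
  widths <- diff(c(0L, cuts, L))
  introns <- vapply(seq_len(max(k - 1L, 0L)), function(i)
    random_nt(sample(seq(config$intron_length[1L],
                         config$intron_length[2L]), 1L)), "")
  pieces <- character(0)
  exon_start <- integer(k)
  pos <- config$flank + 1L
  genomic <- random_nt(config$flank)
  offs <- c(0L, cumsum(widths))
  for (i in seq_len(k)) {
    exon_start[i] <- nchar(genomic) + 1L
    genomic <- paste0(genomic,
                      substr(mrna, offs[i] + 1L, offs[i + 1L]))
    if (i < k) genomic <- paste0(genomic, introns[i])
  }
  locus <- c(start = exon_start[1L],
             end = exon_start[k] + widths[k] - 1L)
  genomic <- paste0(genomic, random_nt(config$flank))
  exons <- data.frame(seqid = "chr_parent", start = exon_start,
                      end = exon_start + widths - 1L, strand = "+")
  parent <- parent_gene("A3G_parent", mrna, config$utr5 + 1L,
                        config$utr5 + nchar(cds), exons)
  list(parent = parent, contig = c(chr_parent = genomic),
       locus = locus, motifs = planted, cds = cds)
}

#' Plant retrocopies of the parent into a synthetic genome
#'
#' Each copy is the parent mRNA, optionally 5'-truncated (geometric
#' model; `orf_constrained` copies are forced full-length so the
#' retained-ORF phenotype is well defined), evolved for its age with
#' [evolve_sequence()] (neutrally, or rejecting ORF-breaking events),
#' inserted intronless in random orientation between background spacers
#' on a dedicated contig.
#'
#' @param parent_obj the result of [generate_parent()].
#' @param config a [generator_config].
#' @return list with `genome` (named character: parental contig +
#'   retrocopy contig), `truth` (data frame: `copy_id`, `contig`,
#'   `start`, `end`, `strand`, `age_years`, `truncation_5p`, `selection`,
#'   `expected_intact`, `n_events`), `retro_seqs` (copies in mRNA
#'   orientation), `events` (list of per-copy event logs).
#' @export
plant_retrocopies <- function(parent_obj, config = generator_config()) {
  parent <- parent_obj$parent
  mrna <- parent$mrna_seq
  L <- nchar(mrna)
  cds_len <- parent$cds_end - parent$cds_start + 1L
  n <- config$n_retrocopies
  ages <- if (is.null(config$ages)) runif(n, 0, 2.5e7)
          else rep_len(config$ages, n)
  selection <- if (is.null(config$selection))
    ifelse(seq_len(n) %% 4L == 0L, "orf_constrained", "neutral")
  else rep_len(config$selection, n)
  contig <- random_nt(config$flank)
  truth <- vector("list", n)
  seqs <- character(n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    constrained <- selection[i] == "orf_constrained"
    repeat {
      trunc <- if (constrained || runif(1) < config$p_full) 0L
               else rgeom(1L, 1 / config$trunc_mean)
      if (L - trunc >= 50L) break
    }
    copy <- substr(mrna, trunc + 1L, L)
    has_cds <- trunc < parent$cds_start
    cds_start <- if (has_cds) parent$cds_start - trunc else NA_integer_
    ev <- evolve_sequence(copy, config$params, ages[i],
                          constrained = constrained,
                          cds_start = cds_start,
                          cds_length = if (has_cds) cds_len
                                       else NA_integer_)
    seqs[i] <- ev$seq
    events[[i]] <- ev$events
    intact <- has_cds && !is.na(ev$cds_start) &&
      ev$cds_length == cds_len &&
      is_orf_intact(substr(ev$seq, ev$cds_start,
                           ev$cds_start + ev$cds_length - 1L), cds_len)
    strand <- sample(c("+", "-"), 1L)
    inserted <- if (strand == "+") ev$seq else revcomp(ev$seq)
    start <- nchar(contig) + 1L
    contig <- paste0(contig, inserted, random_nt(config$flank))
    truth[[i]] <- data.frame(
      copy_id = sprintf("retro_%02d", i), contig = "chr_retro",
      start = start, end = start + nchar(inserted) - 1L,
      strand = strand, age_years = ages[i], truncation_5p = trunc,
      selection = selection[i], expected_intact = intact,
      n_events = ev$n_events)
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$copy_id
  names(events) <- truth$copy_id
  list(genome = c(parent_obj$contig, chr_retro = contig), truth = truth,
       retro_seqs = seqs, events = events)
}

#' Simulate error-free RNA-seq reads
#'
#' Reads are drawn uniformly along each expressed reference on the
#' forward (transcript) strand, with no sequencing errors; per-reference
#' truth counts are recorded.
#'
#' @param refs named character vector of reference sequences.
#' @param expression integer reads per reference (recycled).
#' @param read_length read length (bp); must not exceed any expressed
#'   reference's length.
#' @param seed optional seed.
#' @return list with `reads` (named character vector; names encode the
#'   source reference) and `truth` (named integer counts).
#' @export
simulate_reads <- function(refs, expression, read_length = 100L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expression <- rep_len(as.integer(expression), length(refs))
  stopifnot(all(expression >= 0L))
  lens <- nchar(refs)
  expressed <- expression > 0L
  if (any(expressed & lens < read_length))
    stop("read_length exceeds the length of an expressed reference")
  reads <- character(0)
  for (i in which(expressed)) {
    pos <- sample.int(lens[i] - read_length + 1L, expression[i],
                      replace = TRUE)
    r <- substring(refs[[i]], pos, pos + read_length - 1L)
    names(r) <- sprintf("%s|read%d|pos%d", names(refs)[i],
                        seq_along(r), pos)
    reads <- c(reads, r)
  }
  list(reads = reads, truth = setNames(expression, names(refs)))
}

#' Generate and write a complete labelled synthetic dataset
#'
#' Runs [generate_parent()], [plant_retrocopies()] and
#' [simulate_reads()] and writes: `genome.fasta`, `parent_mrna.fasta`,
#' `parent_exons.gff3`, `retrocopies.fasta`, one FASTQ per dataset,
#' `datasets.tsv` and `ground_truth.json`.
#'
#' @param config a [generator_config].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `parent_obj`, `planted`, `meta`,
#'   `reads`, `files`.
#' @export
make_synthetic <- function(config = generator_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg2 <- config
  cfg2$seed <- NULL  # one seed governs the whole run
  parent_obj <- generate_parent(cfg2)
  planted <- plant_retrocopies(parent_obj, cfg2)
  refs <- c(setNames(parent_obj$parent$mrna_seq, parent_obj$parent$id),
            planted$retro_seqs)
  meta <- dataset_meta(
    dataset_id = c("ds_testis", "ds_cortex", "ds_blood"),
    species = "synthetic_nwm",
    tissue = c("testis", "cortex", "whole_blood"),
    tissue_class = c("germline", "brain", "blood"))
  files <- list(
    genome = file.path(out_dir, "genome.fasta"),
    parent_mrna = file.path(out_dir, "parent_mrna.fasta"),
    parent_exons = file.path(out_dir, "parent_exons.gff3"),
    retrocopies = file.path(out_dir, "retrocopies.fasta"),
    meta = file.path(out_dir, "datasets.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_fasta(planted$genome, files$genome)
  write_fasta(setNames(parent_obj$parent$mrna_seq,
                       parent_obj$parent$id), files$parent_mrna)
  ex <- parent_obj$parent$exons
  write_gff3(data.frame(seqid = ex$seqid, type = "exon",
                        start = ex$start, end = ex$end,
                        strand = ex$strand,
                        attributes = sprintf("ID=exon%d;Parent=%s",
                                             seq_len(nrow(ex)),
                                             parent_obj$parent$id)),
             files$parent_exons)
  write_fasta(planted$retro_seqs, files$retrocopies)
  reads <- list()
  for (i in seq_len(nrow(meta))) {
    sim <- simulate_reads(refs, config$expression, config$read_length)
    fq <- file.path(out_dir, paste0(meta$dataset_id[i], ".fastq"))
    write_fastq(sim$reads, fq)
    files[[meta$dataset_id[i]]] <- fq
    reads[[meta$dataset_id[i]]] <- sim
  }
  write_tsv(meta, files$meta)
  jsonlite::write_json(
    list(seed = config$seed,
         parent = list(id = parent_obj$parent$id,
                       locus = parent_obj$locus,
                       motifs = parent_obj$motifs),
         copies = planted$truth),
    files$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(parent_obj = parent_obj, planted = planted, meta = meta,
                 reads = reads, files = files))
}
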