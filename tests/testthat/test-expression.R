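make_refs <- function() {
  set.seed(601)
  reference_set(c(parent = random_dna(600), retroA = random_dna(500),
                  retroB = random_dna(400)))
}

test_that("reads assign to the unique containing reference", {
  refs <- make_refs()
  r <- substr(refs[["retroA"]], 101, 200)
  expect_equal(assign_read(r, refs), "retroA")
  # reverse-complement reads match unless disabled
  rc <- revcomp(r)
  expect_equal(assign_read(rc, refs), "retroA")
  expect_equal(assign_read(rc, refs, both_strands = FALSE), "none")
  # shared substring -> multi
  shared <- substr(refs[["parent"]], 1, 80)
  refs2 <- reference_set(c(unclass(refs),
                           chimera = paste0(shared, "ACGT")))
  expect_equal(assign_read(shared, refs2), "multi")
  # N or mismatch -> none
  expect_equal(assign_read("NNNNACGT", refs), "none")
  expect_equal(assign_read(paste0(substr(r, 1, 99), "N"), refs), "none")
})

test_that("assignment agrees with the substring-scan oracle", {
  refs <- make_refs()
  set.seed(602)
  reads <- character(400)
  for (i in seq_along(reads)) {
    kind <- sample(3, 1)
    reads[i] <- if (kind == 1) {          # genuine read
      src <- sample(names(refs), 1)
      pos <- sample(nchar(refs[[src]]) - 59, 1)
      substring(refs[[src]], pos, pos + 59)
    } else if (kind == 2) {               # revcomp or mutated read
      src <- sample(names(refs), 1)
      pos <- sample(nchar(refs[[src]]) - 59, 1)
      r <- substring(refs[[src]], pos, pos + 59)
      if (runif(1) < 0.5) revcomp(r) else mutate_once(r, "sub",
                                                      sample(60, 1))
    } else random_dna(60)                 # random
  }
  got <- assign_reads(reads, refs)
  want <- vapply(reads, oracle_assign, "", refs = unclass(refs),
                 USE.NAMES = FALSE)
  expect_identical(got, want)
  # order independence with respect to reference listing
  perm <- rev(seq_along(refs))
  got2 <- assign_reads(reads, reference_set(unclass(refs)[perm]))
  expect_identical(got2, want)
})

test_that("counting conserves reads and an empty FASTQ counts zero", {
  refs <- make_refs()
  set.seed(603)
  meta <- dataset_meta(c("d1", "d2"), "sp", c("testis", "brain"),
                       c("germline", "brain"))
  sim <- simulate_reads(unclass(refs), c(40, 25, 0), read_length = 60)
  f1 <- tempfile(fileext = ".fastq")
  write_fastq(c(sim$reads, noise = random_dna(60),
                withn = paste0(random_dna(59), "N")), f1)
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(character(0), f2)
  ct <- count_reads(c(f1, f2), refs, meta)
  expect_equal(unname(rowSums(ct$counts) + ct$qc$multi + ct$qc$none),
               ct$qc$total)
  expect_equal(ct$qc$total, c(67L, 0L))
  expect_true(all(ct$counts["d2", ] == 0))
  expect_equal(unname(ct$counts["d1", "retroB"]), 0L)
  # planted counts minus verbatim-shared (multi) reads
  truth_assign <- vapply(sim$reads, oracle_assign, "",
                         refs = unclass(refs), USE.NAMES = FALSE)
  for (id in names(refs))
    expect_equal(unname(ct$counts["d1", id]), sum(truth_assign == id))
})

test_that("the expression matrix averages within tissue and log-transforms", {
  refs <- reference_set(c(a = strrep("ACGT", 30)))
  meta <- dataset_meta(c("d1", "d2", "d3"), "sp",
                       c("testis", "testis", "cortex"),
                       c("germline", "germline", "brain"))
  ct <- structure(list(
    counts = matrix(c(10L, 30L, 0L), nrow = 3,
                    dimnames = list(c("d1", "d2", "d3"), "a")),
    qc = data.frame(dataset_id = c("d1", "d2", "d3"), multi = 0L,
                    none = 0L, total = c(10L, 30L, 0L)),
    meta = meta), class = "read_count_table")
  em <- build_matrix(ct)
  expect_equal(unname(em$raw["a", "sp:testis"]), 20)
  expect_equal(unname(em$log10["a", "sp:testis"]), log10(21))
  expect_equal(unname(em$log10["a", "sp:cortex"]), 0)
  # germline column sorts before brain
  expect_equal(colnames(em$raw), c("sp:testis", "sp:cortex"))
})

test_that("matrix cells equal a group-by mean oracle on random tables", {
  set.seed(604)
  for (rep in 1:20) {
    nd <- sample(3:6, 1)
    nr <- sample(2:5, 1)
    classes <- c("germline", "brain", "blood", "other")
    meta <- dataset_meta(sprintf("d%d", seq_len(nd)), "sp",
                         sample(c("t1", "t2", "t3"), nd, replace = TRUE),
                         sample(classes, nd, replace = TRUE))
    # a tissue must have one class; make class a function of tissue
    meta$tissue_class <- classes[match(meta$tissue,
                                       c("t1", "t2", "t3"))]
    cm <- matrix(rpois(nd * nr, 20), nrow = nd,
                 dimnames = list(meta$dataset_id,
                                 sprintf("r%d", seq_len(nr))))
    ct <- structure(list(counts = cm,
                         qc = data.frame(dataset_id = meta$dataset_id,
                                         multi = 0L, none = 0L,
                                         total = rowSums(cm)),
                         meta = meta), class = "read_count_table")
    em <- build_matrix(ct)
    agg <- aggregate(cm, by = list(key = paste(meta$species,
                                               meta$tissue,
                                               sep = ":")), FUN = mean)
    for (k in agg$key)
      expect_equal(unname(em$raw[, k]),
                   as.numeric(agg[agg$key == k, -1]))
    expect_equal(em$log10, log10(em$raw + 1))
  }
})

test_that("unknown tissue classes fall back to other with a warning", {
  expect_warning(m <- dataset_meta("d1", "sp", "liver", "viscera"),
                 "other")
  expect_equal(m$tissue_class, "other")
  expect_error(dataset_meta(c("d1", "d1"), "sp", "t", "other"),
               "unique")
})
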