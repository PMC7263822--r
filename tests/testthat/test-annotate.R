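test_that("collinear nearby hits merge; distant or opposite hits do not", {
  base <- data.frame(query_id = "q", subject_id = "chr1",
                     percent_identity = 100, alignment_length = 100L,
                     strand = "+")
  two <- rbind(cbind(base, q_start = 1L, q_end = 100L, s_start = 1001L,
                     s_end = 1100L),
               cbind(base, q_start = 101L, q_end = 200L,
                     s_start = 1111L, s_end = 1210L))
  m <- merge_hits(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$s_start, 1001)
  expect_equal(m$s_end, 1210)
  expect_equal(m$n_hits, 2)

  far <- two
  far$s_start[2] <- 11111L
  far$s_end[2] <- 11210L
  expect_equal(nrow(merge_hits(far)), 2)

  mixed <- two
  mixed$strand[2] <- "-"
  expect_equal(nrow(merge_hits(mixed)), 2)  # strands kept separate

  # non-collinear mRNA coordinates refuse to merge even when adjacent
  back <- two
  back$q_start[2] <- 1L
  back$q_end[2] <- 100L
  expect_equal(nrow(merge_hits(back)), 2)
})

test_that("planted copies merge into single loci recovering the span", {
  fx <- annotation_fixture()
  truth <- fx$planted$truth
  idx <- match_calls_to_truth(fx$calls, truth)
  expect_false(anyNA(idx))  # every planted copy -> exactly one locus
  # age-0 copies are recovered at their exact genomic span
  young <- which(truth$age_years == 0)
  for (i in young) {
    expect_equal(fx$calls$s_start[idx[i]], truth$start[i])
    expect_equal(fx$calls$s_end[idx[i]], truth$end[i])
    expect_equal(fx$calls$strand[idx[i]], truth$strand[i])
  }
})

test_that("intronless labels: copies TRUE, parental locus FALSE", {
  fx <- annotation_fixture()
  truth <- fx$planted$truth
  idx <- match_calls_to_truth(fx$calls, truth)
  for (i in seq_len(nrow(truth))) {
    lab <- fx$calls$is_intronless[idx[i]]
    # heavily truncated copies may cover no junction (indeterminate)
    if (!is.na(lab)) expect_true(lab)
  }
  parent_call <- which(fx$calls$subject_id == "chr_parent")
  expect_equal(length(parent_call), 1L)
  expect_false(fx$calls$is_intronless[parent_call])
})

test_that("single-junction evidence requirement yields indeterminate", {
  fx <- annotation_fixture()
  parent <- fx$parent_obj$parent
  # a hit inside exon 1 only: covers no junction
  w1 <- parent$exons$end[1] - parent$exons$start[1] + 1
  hit <- data.frame(query_id = parent$id, subject_id = "chr_parent",
                    percent_identity = 100,
                    alignment_length = w1 - 10L, q_start = 1L,
                    q_end = w1 - 10L, s_start = parent$exons$start[1],
                    s_end = parent$exons$start[1] + w1 - 11L,
                    strand = "+")
  locus <- merge_hits(hit)
  expect_true(is.na(classify_intronless(locus[1, ], parent)))
})

test_that("truncation is exact for age-0 copies and unbiased in cohorts", {
  fx <- annotation_fixture()
  truth <- fx$planted$truth
  idx <- match_calls_to_truth(fx$calls, truth)
  young <- which(truth$age_years == 0)
  for (i in young)
    expect_equal(fx$calls$truncation_5p[idx[i]], truth$truncation_5p[i])
  # cohort: generator truncations follow the configured geometric model
  set.seed(77)
  cfg <- generator_config(seed = 77, n_retrocopies = 400, ages = 0,
                          p_full = 0, trunc_mean = 300,
                          selection = "neutral")
  po <- generate_parent(cfg)
  pl <- plant_retrocopies(po, cfg)
  tr <- pl$truth$truncation_5p
  # E[geometric, mean parameter 300] ~ 299 (support starts at 0),
  # conditioned on leaving >= 50 bp of copy
  keep_max <- nchar(po$parent$mrna_seq) - 50
  mu <- 1 / 300
  expected <- (1 - mu) / mu  # unconditional mean; truncation cap is rare
  se <- sqrt(((1 - mu) / mu^2) / length(tr))
  expect_lt(abs(mean(tr) - expected), 3 * se)
  expect_true(all(tr <= keep_max))
})

test_that("mutation mapping recovers planted stops and indels exactly", {
  set.seed(501)
  for (rep in 1:6) {
    n_cod <- sample(60:90, 1)
    cds <- random_orf(n_cod)
    exons <- data.frame(seqid = "c", start = 1, end = nchar(cds),
                        strand = "+")
    parent <- parent_gene("p", cds, 1, nchar(cds), exons)
    k <- sample(0:3, 1)  # stops
    j <- sample(0:3, 1)  # 1-bp deletions
    # well-separated events: a stop immediately abutting a frameshift is
    # genuinely unidentifiable (the aligner may absorb it into the shift)
    repeat {
      positions <- sort(sample(5:(n_cod - 5), k + j))
      if (length(positions) < 2 || all(diff(positions) >= 5)) break
    }
    stop_at <- positions[seq_len(k)]
    del_at <- if (j) positions[k + seq_len(j)] else integer(0)
    retro <- cds
    for (cp in stop_at) substr(retro, 3 * cp - 2, 3 * cp) <- "TAA"
    for (cp in rev(del_at)) {  # right-to-left keeps codon coordinates
      nt <- 3 * cp - 1
      retro <- paste0(substr(retro, 1, nt - 1),
                      substr(retro, nt + 1, nchar(retro)))
    }
    mm <- map_inactivating_mutations(retro, parent)
    expect_equal(mm$status, "aligned")
    got_stops <- mm$events$parent_codon[mm$events$type ==
                                          "premature_stop"]
    got_dels <- mm$events$parent_codon[grepl("frameshift",
                                             mm$events$type)]
    expect_equal(sort(got_stops), sort(stop_at))
    # a lone 1-bp deletion is identifiable only to within one codon: the
    # alignment may realign the shift boundary to the neighbouring codon
    # when that scores equally
    expect_equal(length(got_dels), j)
    if (j) expect_true(all(abs(sort(got_dels) - sort(del_at)) <= 1))
    expect_equal(nrow(mm$events), k + j)  # no extra calls
  }
})

test_that("identical retrocopy has no events; random sequence unalignable", {
  fx <- annotation_fixture()
  parent <- fx$parent_obj$parent
  mm <- map_inactivating_mutations(fx$parent_obj$cds, parent)
  expect_equal(mm$status, "aligned")
  expect_equal(nrow(mm$events), 0)
  set.seed(502)
  rnd <- map_inactivating_mutations(random_dna(900), parent)
  expect_equal(rnd$status, "unalignable")
})

test_that("alignment score equals the independent DP oracle on toys", {
  set.seed(503)
  for (rep in 1:8) {
    n_cod <- sample(10:25, 1)
    cds <- random_orf(n_cod)
    prot <- sub("\\*$", "", translate_nt(cds))
    # perturb: substitutions and possibly a 1-bp indel
    retro <- cds
    for (s in sample(nchar(retro), sample(0:4, 1)))
      retro <- mutate_once(retro, "sub", s)
    if (runif(1) < 0.5)
      retro <- mutate_once(retro, sample(c("ins", "del"), 1),
                           sample(nchar(retro), 1))
    mm <- map_inactivating_mutations(
      retro, prot, frameshift_scoring(min_score = -Inf))
    expect_equal(mm$score, oracle_align_score(retro, prot))
  }
})

test_that("deaminase motif scan matches examples and the pattern oracle", {
  hit <- detect_deaminase_motifs(
    "MAHAEKLLKKKKKKKKKKKKKKKKKKKKKKKKKKCAACW")
  expect_equal(nrow(hit), 1)
  expect_true(hit$complete)
  expect_equal(hit$start, 3)
  expect_equal(hit$end, 38)
  none <- detect_deaminase_motifs(strrep("A", 80))
  expect_equal(nrow(none), 0)
  set.seed(504)
  aas <- c("A", "C", "D", "E", "H", "K", "L", "S")
  for (rep in 1:300) {
    prot <- paste(sample(aas, sample(40:120, 1), replace = TRUE),
                  collapse = "")
    got <- detect_deaminase_motifs(prot)
    want <- oracle_motifs(prot)
    full_got <- got[got$complete, , drop = FALSE]
    if (is.null(want$full)) {
      expect_equal(nrow(full_got), 0)
    } else {
      expect_equal(nrow(full_got), nrow(want$full))
      expect_equal(full_got$start, unname(want$full[, "start"]))
      expect_equal(full_got$end, unname(want$full[, "end"]))
    }
    expect_equal(got$start[!got$complete], want$partial)
  }
})

test_that("synteny support categories follow shared flank genes", {
  a <- list(up = c("g1", "g2"), down = c("g3", "g4"))
  expect_equal(synteny_support(a, a)$category, "both_sides")
  b <- list(up = c("g9"), down = c("g3"))
  expect_equal(synteny_support(a, b)$category, "one_side")
  c0 <- list(up = "x1", down = "x2")
  expect_equal(synteny_support(a, c0)$category, "none")
  expect_warning(
    out <- synteny_support(a, list(up = character(0),
                                   down = character(0))),
    "empty")
  expect_equal(out$category, "none")
  set.seed(505)
  pool <- sprintf("gene%02d", 1:40)
  for (rep in 1:100) {
    fa <- list(up = sample(pool, 6), down = sample(pool, 6))
    fb <- list(up = sample(pool, 6), down = sample(pool, 6))
    got <- synteny_support(fa, fb)
    up <- length(intersect(fa$up, fb$up)) > 0
    down <- length(intersect(fa$down, fb$down)) > 0
    want <- if (up && down) "both_sides"
            else if (up || down) "one_side" else "none"
    expect_equal(got$category, want)
  }
})
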