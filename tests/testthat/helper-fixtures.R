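# Shared synthetic fixtures, built once per test run.

.fixture_env <- new.env()

# small labelled genome: two age-0 copies (one truncated), one mid-age
# neutral, one old neutral, one old constrained copy
annotation_fixture <- function() {
  if (!is.null(.fixture_env$annot)) return(.fixture_env$annot)
  cfg <- generator_config(
    seed = 4242, n_retrocopies = 5,
    ages = c(0, 0, 5e6, 2e7, 2e7),
    selection = c("neutral", "neutral", "neutral", "neutral",
                  "orf_constrained"),
    p_full = 0.5)
  set.seed(cfg$seed)
  parent_obj <- generate_parent(cfg)
  planted <- plant_retrocopies(parent_obj, cfg)
  hits <- find_hits(setNames(parent_obj$parent$mrna_seq,
                             parent_obj$parent$id), planted$genome)
  calls <- annotate_retrocopies(hits, parent_obj$parent, planted$genome)
  .fixture_env$annot <- list(cfg = cfg, parent_obj = parent_obj,
                             planted = planted, hits = hits,
                             calls = calls)
  .fixture_env$annot
}

# match annotated calls to planted copies by genomic overlap
match_calls_to_truth <- function(calls, truth) {
  idx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    on_contig <- calls$subject_id == truth$contig[i]
    ov <- on_contig & calls$s_start <= truth$end[i] &
      calls$s_end >= truth$start[i]
    j <- which(ov)
    if (length(j) == 1L) idx[i] <- j
  }
  idx
}
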