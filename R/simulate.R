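#' Simulation configuration for neutral ORF decay
#'
#' @param horizon_years total simulated time (default 50 My).
#' @param census_interval_years census spacing (default 50,000 y); must
#'   divide the horizon.
#' @param n_replicates number of independent replicate ORFs (default
#'   10,000).
#' @param seed optional integer seed; when given, [simulate_decay()] is
#'   bit-reproducible.
#' @param require_start_codon count loss of the ATG as loss of the ORF?
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(horizon_years = 5e7,
                              census_interval_years = 5e4,
                              n_replicates = 10000L, seed = NULL,
                              require_start_codon = TRUE) {
  stopifnot(horizon_years > 0, census_interval_years > 0, n_replicates >= 1)
  n_int <- horizon_years / census_interval_years
  if (abs(n_int - round(n_int)) > 1e-8)
    stop("horizon_years must be divisible by census_interval_years")
  structure(list(horizon_years = horizon_years,
                 census_interval_years = census_interval_years,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 require_start_codon = isTRUE(require_start_codon)),
            class = "simulation_config")
}

#' Simulate neutral decay of an ORF
#'
#' Runs `n_replicates` independent copies of the starting ORF forward in
#' time. Within each census interval the number of substitutions,
#' insertions and deletions are independent Poisson draws with mean
#' `rate * current_length * generations_per_interval`; events are applied
#' in random order at uniform positions (substitutions pick one of the
#' three alternative bases uniformly; indels are 1 bp). Intactness (see
#' [is_orf_intact()]) is re-evaluated on the current sequence at every
#' census, so back-mutation can in principle restore an ORF; a sequence
#' that reaches length zero is counted not-intact from then on.
#'
#' @param orf a [coding_sequence] (with `is_cds = TRUE`) or a plain
#'   nucleotide string.
#' @param params a [mutation_params] object.
#' @param config a [simulation_config] object.
#' @return an object of class `decay_trajectory`: list with `census_times`
#'   (years, starting at 0), `intact_counts`, `intact_fraction`,
#'   `n_replicates`, `params`, `orf_length`.
#' @export
simulate_decay <- function(orf, params, config = simulation_config()) {
  if (inherits(orf, "coding_sequence")) {
    if (!orf$is_cds) stop("orf must be a CDS (is_cds = TRUE)")
    seq <- orf$seq
  } else {
    seq <- toupper(orf)
    .check_nt(seq, "orf")
  }
  stopifnot(inherits(params, "mutation_params"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_int <- as.integer(round(config$horizon_years /
                              config$census_interval_years))
  gens <- config$census_interval_years / params$generation_time
  counts <- cpp_simulate_decay(seq, n_int, gens, params$sub_rate,
                               params$ins_rate, params$del_rate,
                               config$n_replicates,
                               config$require_start_codon)
  structure(list(
    census_times = seq.int(0L, n_int) * config$census_interval_years,
    intact_counts = counts,
    intact_fraction = counts / config$n_replicates,
    n_replicates = config$n_replicates,
    params = params, orf_length = nchar(seq), config = config),
    class = "decay_trajectory")
}

#' @export
print.decay_trajectory <- function(x, ...) {
  cat(sprintf(
    "<decay_trajectory> %d bp ORF, %s params, %d replicates, %d censuses\n",
    x$orf_length, x$params$label, x$n_replicates, length(x$census_times)))
  last <- length(x$intact_fraction)
  cat(sprintf("  intact fraction at %.3g My: %.4f\n",
              x$census_times[last] / 1e6, x$intact_fraction[last]))
  invisible(x)
}

#' @method as.data.frame decay_trajectory
#' @export
as.data.frame.decay_trajectory <- function(x, ...) {
  data.frame(time_years = x$census_times, intact_count = x$intact_counts,
             intact_fraction = x$intact_fraction)
}

#' First census times at which the intact fraction crosses percentiles
#'
#' @param traj a [decay_trajectory].
#' @param percentiles proportions in (0, 1] (defaults: 1% and 5%).
#' @return data frame with columns `percentile`, `time_years` (`NA` when
#'   the trajectory never falls to the percentile) and `reached`.
#' @export
retention_percentiles <- function(traj, percentiles = c(0.01, 0.05)) {
  stopifnot(inherits(traj, "decay_trajectory"))
  if (any(percentiles <= 0 | percentiles > 1))
    stop("percentiles must lie in (0, 1]")
  time_years <- vapply(percentiles, function(p) {
    i <- which(traj$intact_fraction <= p)
    if (length(i)) traj$census_times[i[1L]] else NA_real_
  }, numeric(1))
  data.frame(percentile = percentiles, time_years = time_years,
             reached = !is.na(time_years))
}

#' Write a decay trajectory as TSV
#'
#' Columns `time_years`, `intact_count`, `intact_fraction`.
#'
#' @param traj a [decay_trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  write_tsv(as.data.frame(traj), path)
}

#' Read a simulation parameter configuration (YAML or JSON)
#'
#' Recognised keys: `preset` (one of the [mutation_preset()] names) or
#' explicit `sub_rate`/`ins_rate`/`del_rate`/`generation_time` (explicit
#' rates override the preset), plus `horizon_years`,
#' `census_interval_years`, `n_replicates`, `seed`,
#' `require_start_codon`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return list with `params` ([mutation_params]) and `config`
#'   ([simulation_config]).
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(cfg$preset)) mutation_preset(cfg$preset)
            else mutation_params(cfg$sub_rate, cfg$ins_rate,
                                 cfg$del_rate, cfg$generation_time)
  for (k in c("sub_rate", "ins_rate", "del_rate", "generation_time"))
    if (!is.null(cfg[[k]])) params[[k]] <- as.numeric(cfg[[k]])
  defaults <- simulation_config()
  pick <- function(k, coerce = as.numeric) {
    if (!is.null(cfg[[k]])) coerce(cfg[[k]]) else defaults[[k]]
  }
  config <- simulation_config(
    horizon_years = pick("horizon_years"),
    census_interval_years = pick("census_interval_years"),
    n_replicates = pick("n_replicates"), seed = cfg$seed,
    require_start_codon = pick("require_start_codon", as.logical))
  list(params = params, config = config)
}

#' Neutral retention test for an observed intact retrocopy
#'
#' Simulates the neutral null for an ORF of the given length and asks how
#' probable it is that the ORF is still intact at `age_years`. An observed
#' intact retrocopy of that age is flagged `"candidate selected"` when the
#' neutral probability falls below `threshold` (default the 5th
#' percentile).
#'
#' @param age_years age of the observed retrocopy (<= the config horizon;
#'   rounded to the nearest census).
#' @param orf the starting ORF ([coding_sequence] or string).
#' @param params a [mutation_params].
#' @param config a [simulation_config].
#' @param threshold flagging threshold on the neutral intact probability.
#' @param observed_intact is the observed copy's ORF actually intact? A
#'   broken copy is never flagged.
#' @param traj optional precomputed [decay_trajectory] for the same
#'   ORF/params (avoids re-simulation when testing many copies).
#' @return object of class `retention_result`: list with `age_years`,
#'   `intact_fraction`, `flagged`, `threshold`, `percentile_calls`.
#' @export
retention_test <- function(age_years, orf, params,
                           config = simulation_config(), threshold = 0.05,
                           observed_intact = TRUE, traj = NULL) {
  if (is.null(traj)) {
    if (age_years > config$horizon_years)
      stop("age_years exceeds the simulation horizon")
    traj <- simulate_decay(orf, params, config)
  }
  if (age_years > max(traj$census_times))
    stop("age_years exceeds the simulated horizon")
  i <- which.min(abs(traj$census_times - age_years))
  frac <- traj$intact_fraction[i]
  structure(list(age_years = age_years, intact_fraction = frac,
                 threshold = threshold,
                 flagged = isTRUE(observed_intact) && frac < threshold,
                 percentile_calls = retention_percentiles(traj),
                 trajectory = traj),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf(
    "<retention_result> age %.3g My: neutral intact fraction %.4g -> %s\n",
    x$age_years / 1e6, x$intact_fraction,
    if (x$flagged) "candidate selected" else "not flagged"))
  invisible(x)
}
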