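#' Per-generation mutation parameters
#'
#' Bundles per-site per-generation rates of substitution and 1-bp
#' insertion/deletion together with a generation time in years. Three named
#' presets are provided (see [mutation_preset()]): `"human-like"`
#' (1.16e-8 / 2e-10 / 5.5e-10, 25 y), `"mouse-like"`
#' (5.4e-9 / 1.55e-10 / 1.55e-10, 0.3 y) and `"nwm-like"` (night-monkey
#' substitution rate 8.1e-9 with mouse-like indel rates and a 1-year
#' generation time, the short end of the 1-9 y maturation range reported
#' for New World monkeys).
#'
#' @param sub_rate substitutions per site per generation (>= 0).
#' @param ins_rate 1-bp insertions per site per generation (>= 0).
#' @param del_rate 1-bp deletions per site per generation (>= 0).
#' @param generation_time years per generation (> 0).
#' @param label free-text label.
#' @return an object of class `mutation_params`.
#' @export
mutation_params <- function(sub_rate, ins_rate, del_rate, generation_time,
                            label = "custom") {
  vals <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("mutation rates must be finite and >= 0")
  if (!is.finite(generation_time) || generation_time <= 0)
    stop("generation_time must be > 0")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, generation_time = generation_time,
                 label = label),
            class = "mutation_params")
}

#' @export
print.mutation_params <- function(x, ...) {
  cat(sprintf(
    "<mutation_params> %s: sub %.3g, ins %.3g, del %.3g /site/gen; g = %g y\n",
    x$label, x$sub_rate, x$ins_rate, x$del_rate, x$generation_time))
  invisible(x)
}

#' @rdname mutation_params
#' @param preset one of `"human-like"`, `"mouse-like"`, `"nwm-like"`.
#' @export
mutation_preset <- function(preset = c("nwm-like", "human-like",
                                       "mouse-like")) {
  preset <- match.arg(preset)
  switch(preset,
    "human-like" = mutation_params(1.16e-8, 2e-10, 5.5e-10, 25,
                                   "human-like"),
    "mouse-like" = mutation_params(5.4e-9, 1.55e-10, 1.55e-10, 0.3,
                                   "mouse-like"),
    "nwm-like"   = mutation_params(8.1e-9, 1.55e-10, 1.55e-10, 1,
                                   "nwm-like"))
}

#' Apply a single mutation event
#'
#' Substitutions replace the base at `position` with one of the three
#' alternatives (uniformly, unless `base` forces the replacement);
#' insertions add one random (or forced) base immediately after `position`;
#' deletions remove the base at `position`. Positions are 1-based.
#'
#' @param seq nucleotide string.
#' @param kind `"sub"`, `"ins"` or `"del"`.
#' @param position 1-based site index within the current sequence.
#' @param base optional forced base for `sub`/`ins`.
#' @return the mutated sequence.
#' @export
mutate_once <- function(seq, kind = c("sub", "ins", "del"), position,
                        base = NULL) {
  kind <- match.arg(kind)
  .check_nt(seq)
  L <- nchar(seq)
  if (position < 1L || position > L)
    stop("position ", position, " out of range 1..", L)
  bases <- c("A", "C", "G", "T")
  if (kind == "sub") {
    cur <- substr(seq, position, position)
    if (is.null(base)) base <- sample(setdiff(bases, cur), 1L)
    if (base == cur) stop("substitution must change the base")
    substr(seq, position, position) <- base
    seq
  } else if (kind == "ins") {
    if (is.null(base)) base <- sample(bases, 1L)
    paste0(substr(seq, 1L, position), base,
           if (position < L) substr(seq, position + 1L, L) else "")
  } else {
    paste0(substr(seq, 1L, position - 1L),
           if (position < L) substr(seq, position + 1L, L) else "")
  }
}

# Evolve a sequence for a span of years under a mutation_params set.
# Pure-R event loop used by the synthetic-data generator (and deliberately
# independent of the C++ replicate engine so cross-module consistency tests
# compare two implementations). When `constrained = TRUE` and the full CDS
# is present, events that would break the ORF are rejected: indels inside
# the CDS always, substitutions inside the CDS when they create a premature
# stop or destroy the ATG. Indels outside the CDS are accepted and shift
# the tracked CDS coordinates.

#' Evolve a sequence neutrally or under ORF constraint
#'
#' @param seq nucleotide string (e.g. a planted retrocopy).
#' @param params a [mutation_params] object.
#' @param age_years span of time to simulate.
#' @param census_interval_years interval for Poisson event draws.
#' @param constrained reject ORF-breaking events?
#' @param cds_start,cds_length 1-based start and length of the tracked CDS
#'   within `seq` (`NA` when the copy does not carry a full CDS).
#' @return list with `seq`, tracked `cds_start`/`cds_length`, `n_events`,
#'   `n_rejected`, and an `events` data frame (`type`, `position` at
#'   application time).
#' @export
evolve_sequence <- function(seq, params, age_years,
                            census_interval_years = 5e4,
                            constrained = FALSE,
                            cds_start = NA_integer_,
                            cds_length = NA_integer_) {
  .check_nt(seq)
  stopifnot(inherits(params, "mutation_params"), age_years >= 0)
  if (constrained && (is.na(cds_start) || is.na(cds_length)))
    stop("constrained evolution needs cds_start and cds_length")
  L0_cds <- cds_length
  track <- !is.na(cds_start) && !is.na(cds_length)
  ev_type <- character(0)
  ev_pos <- integer(0)
  n_rejected <- 0L
  remaining <- age_years
  cds_ok <- track  # full CDS still at original length
  while (remaining > 1e-9) {
    span <- min(census_interval_years, remaining)
    remaining <- remaining - span
    gens <- span / params$generation_time
    L <- nchar(seq)
    n <- c(sub = rpois(1L, params$sub_rate * L * gens),
           ins = rpois(1L, params$ins_rate * L * gens),
           del = rpois(1L, params$del_rate * L * gens))
    if (sum(n) == 0L) next
    kinds <- sample(rep(names(n), n))
    for (kind in kinds) {
      L <- nchar(seq)
      if (L == 0L) break
      pos <- sample.int(L, 1L)
      in_cds <- track && !is.na(cds_start) &&
        pos >= cds_start && pos < cds_start + cds_length
      if (constrained && kind != "sub" && in_cds) {
        n_rejected <- n_rejected + 1L
        next
      }
      cand <- mutate_once(seq, kind, pos)
      if (constrained && kind == "sub" && in_cds) {
        cds <- substr(cand, cds_start, cds_start + cds_length - 1L)
        if (!is_orf_intact(cds, L0_cds)) {
          n_rejected <- n_rejected + 1L
          next
        }
      }
      seq <- cand
      ev_type <- c(ev_type, kind)
      ev_pos <- c(ev_pos, pos)
      if (track && kind != "sub") {
        shift <- if (kind == "ins") 1L else -1L
        if (kind == "ins" && pos < cds_start) {
          cds_start <- cds_start + 1L
        } else if (kind == "del" && pos < cds_start) {
          cds_start <- cds_start - 1L
        } else if (in_cds) {
          cds_length <- cds_length + shift
        }
      }
    }
  }
  list(seq = seq, cds_start = cds_start, cds_length = cds_length,
       n_events = length(ev_type), n_rejected = n_rejected,
       events = data.frame(type = ev_type, position = ev_pos))
}
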