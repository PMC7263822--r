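# Properties of the neutral decay simulator on toy ORFs. Monte-Carlo
# assertions use a 3-standard-error tolerance.

toy_config <- function(...) {
  simulation_config(horizon_years = 1e6, census_interval_years = 5e4,
                    n_replicates = 500, ...)
}

test_that("zero mutation rates leave every replicate intact forever", {
  p0 <- mutation_params(0, 0, 0, 1, "null")
  tr <- simulate_decay(random_orf(40), p0, toy_config(seed = 1))
  expect_true(all(tr$intact_fraction == 1))
  expect_equal(tr$intact_counts[1], tr$n_replicates)
})

test_that("identical seeds give bit-identical trajectories", {
  set.seed(21)
  orf <- random_orf(50)
  p <- mutation_params(1e-7, 1e-8, 1e-8, 1, "fast")
  t1 <- simulate_decay(orf, p, toy_config(seed = 42))
  t2 <- simulate_decay(orf, p, toy_config(seed = 42))
  expect_identical(t1$intact_counts, t2$intact_counts)
  t3 <- simulate_decay(orf, p, toy_config(seed = 43))
  expect_false(identical(t1$intact_counts, t3$intact_counts))
})

test_that("halving generation time equals doubling all rates", {
  # equal Poisson means per interval make the two parameterisations
  # identical in distribution; with a shared seed they coincide exactly
  set.seed(22)
  orf <- random_orf(50)
  p1 <- mutation_params(2e-7, 2e-8, 2e-8, 1, "double-rate")
  p2 <- mutation_params(1e-7, 1e-8, 1e-8, 0.5, "half-generation")
  t1 <- simulate_decay(orf, p1, toy_config(seed = 5))
  t2 <- simulate_decay(orf, p2, toy_config(seed = 5))
  expect_identical(t1$intact_counts, t2$intact_counts)
})

test_that("doubling the substitution rate cannot slow decay", {
  set.seed(23)
  orf <- random_orf(60)
  cfg <- simulation_config(horizon_years = 1e6,
                           census_interval_years = 5e4,
                           n_replicates = 2000, seed = 9)
  p1 <- mutation_params(5e-8, 0, 0, 1, "x1")
  p2 <- mutation_params(1e-7, 0, 0, 1, "x2")
  f1 <- simulate_decay(orf, p1, cfg)$intact_fraction
  f2 <- simulate_decay(orf, p2, cfg)$intact_fraction
  se <- sqrt(pmax(f1 * (1 - f1), f2 * (1 - f2)) / cfg$n_replicates)
  expect_true(all(f2 <= f1 + 3 * se + 1e-12))
})

test_that("substitution-only decay matches the Poisson-thinning closed form", {
  # one census; expected intact fraction = sum_k Pois(k; m) (1-f)^k
  # = exp(-m f) with f from the exhaustive single-substitution oracle
  set.seed(24)
  for (n_codons in c(20, 30)) {
    orf <- random_orf(n_codons)
    L <- nchar(orf)
    f_stop <- oracle_f_stop(orf)
    m_target <- 0.8
    rate <- m_target / (L * 1e4)   # one 10,000-generation interval
    cfg <- simulation_config(horizon_years = 1e4,
                             census_interval_years = 1e4,
                             n_replicates = 4000, seed = 30 + n_codons)
    p <- mutation_params(rate, 0, 0, 1, "sub-only")
    sim <- simulate_decay(orf, p, cfg)$intact_fraction[2]
    expected <- exp(-m_target * f_stop)
    se <- sqrt(expected * (1 - expected) / cfg$n_replicates)
    expect_lt(abs(sim - expected), 3 * se + 1e-12)
  }
})

test_that("percentile crossings match a linear-scan oracle", {
  tr <- structure(list(census_times = c(0, 2e7, 4e7),
                       intact_fraction = c(1, 0.04, 0.009),
                       intact_counts = c(1000, 40, 9),
                       n_replicates = 1000),
                  class = "decay_trajectory")
  out <- retention_percentiles(tr, c(0.01, 0.05))
  expect_equal(out$time_years, c(4e7, 2e7))
  flat <- tr
  flat$intact_fraction <- c(1, 1, 1)
  expect_true(all(is.na(retention_percentiles(flat)$time_years)))
  expect_error(retention_percentiles(tr, c(0, 0.05)), "\\(0, 1]")
  set.seed(25)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    fr <- c(1, sort(runif(n - 1), decreasing = TRUE))
    times <- seq(0, by = 5e4, length.out = n)
    trr <- structure(list(census_times = times, intact_fraction = fr,
                          intact_counts = round(fr * 100),
                          n_replicates = 100),
                     class = "decay_trajectory")
    ps <- runif(3, 0.001, 1)
    got <- retention_percentiles(trr, ps)$time_years
    expect_equal(got, oracle_percentiles(fr, times, ps))
  }
})

test_that("percentile crossings are monotone in the percentile", {
  set.seed(26)
  orf <- random_orf(40)
  p <- mutation_params(2e-7, 2e-8, 2e-8, 1, "fast")
  tr <- simulate_decay(orf, p, toy_config(seed = 3))
  out <- retention_percentiles(tr, c(0.01, 0.05))
  if (all(out$reached))
    expect_lte(out$time_years[out$percentile == 0.05],
               out$time_years[out$percentile == 0.01])
})

test_that("retention test: age zero is never flagged, old ages are", {
  orf <- random_orf(40)
  p <- mutation_params(2e-7, 2e-8, 2e-8, 1, "fast")
  cfg <- toy_config(seed = 4)
  rt0 <- retention_test(0, orf, p, cfg)
  expect_equal(rt0$intact_fraction, 1)
  expect_false(rt0$flagged)
  rt <- retention_test(1e6, orf, p, cfg)
  expect_lt(rt$intact_fraction, 0.05)
  expect_true(rt$flagged)
  # a broken observed copy is never flagged, whatever the null says
  rtb <- retention_test(1e6, orf, p, cfg, observed_intact = FALSE)
  expect_false(rtb$flagged)
  expect_error(retention_test(2e6, orf, p, cfg), "horizon")
})

test_that("simulation config enforces divisibility and replicate count", {
  expect_error(simulation_config(horizon_years = 1e6,
                                 census_interval_years = 3e5),
               "divisible")
  expect_error(simulation_config(n_replicates = 0))
  cfg <- simulation_config()
  expect_equal(cfg$horizon_years, 5e7)
  expect_equal(cfg$census_interval_years, 5e4)
  expect_equal(cfg$n_replicates, 10000L)
})

test_that("trajectory TSV and simulation config round-trip", {
  orf <- random_orf(30)
  tr <- simulate_decay(orf, mutation_params(0, 0, 0, 1, "null"),
                       toy_config(seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$intact_fraction, tr$intact_fraction)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("preset: nwm-like", "horizon_years: 2.0e6",
               "n_replicates: 100", "seed: 7"), yml)
  sc <- read_sim_config(yml)
  expect_equal(sc$params$sub_rate, 8.1e-9)
  expect_equal(sc$config$horizon_years, 2e6)
  expect_equal(sc$config$n_replicates, 100)
})
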