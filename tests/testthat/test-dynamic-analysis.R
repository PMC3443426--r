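test_that("environment sampling is uniform within configured ranges", {
  rng <- env_ranges(A = c(56, 100), B = 0, C = c(0, 100))
  set.seed(1)
  draws <- replicate(500, unclass(sample_environment(rng)))
  expect_true(all(draws["A", ] >= 56 & draws["A", ] <= 100))
  expect_true(all(draws["B", ] == 0))
  # uniform moments on (0, 100): mean 50, sd 100/sqrt(12)
  set.seed(2)
  x <- replicate(10000, unclass(sample_environment(env_ranges(X = c(0, 100))))[["X"]])
  expect_lt(abs(mean(x) - 50), 3 * (100 / sqrt(12)) / sqrt(10000))
  expect_error(env_ranges(A = c(60, 20)), "lo <= hi")
})

test_that("experiments record one reproducible row per simulation", {
  m <- motif_library()$pass_through
  rng <- env_ranges(X = c(0, 100))
  ex1 <- run_experiment(m, rng, n_simulations = 30, seed = 5,
                        burn_in = 50, measure_steps = 100)
  expect_identical(nrow(ex1), 30L)
  expect_true(all(c("sim", "env_X", "pct_X", "pct_Z") %in% names(ex1)))
  expect_true(all(ex1$pct_Z >= 0 & ex1$pct_Z <= 100))
  ex2 <- run_experiment(m, rng, n_simulations = 30, seed = 5,
                        burn_in = 50, measure_steps = 100)
  expect_identical(tibble::as_tibble(ex1), tibble::as_tibble(ex2))
  # growing the experiment must not change earlier records
  ex3 <- run_experiment(m, rng, n_simulations = 40, seed = 5,
                        burn_in = 50, measure_steps = 100)
  expect_equal(tibble::as_tibble(ex3)[1:30, ], tibble::as_tibble(ex1),
               ignore_attr = TRUE)
  # degenerate deterministic ranges with fixed initial state: identical rows
  exd <- run_experiment(m, env_ranges(X = 100), n_simulations = 5, seed = 1)
  expect_identical(nrow(dplyr::distinct(dplyr::select(tibble::as_tibble(exd), -sim))), 1L)
})

test_that("dose-response is a pure function of stored experiment data", {
  m <- motif_library()$pass_through
  ex <- run_experiment(m, env_ranges(X = c(0, 100)), n_simulations = 60,
                       seed = 3, burn_in = 50, measure_steps = 200)
  before <- tibble::as_tibble(ex)
  d1 <- dose_response(ex, "X", "Z", n_bins = 6)
  d2 <- dose_response(ex, "X", "Z", n_bins = 6)
  dx <- dose_response(ex, "X", "X", n_bins = 4)
  expect_identical(d1$binned, d2$binned)
  expect_identical(tibble::as_tibble(ex), before)
  expect_identical(nrow(d1$raw), 60L)
  expect_identical(nrow(d1$binned), 6L)
  expect_error(dose_response(ex, "Z", "X"), "not an external species")
  expect_error(dose_response(ex, "X", "Q"), "unknown output species")
})

test_that("pass-through and inverter dose-responses track the input level", {
  m <- motif_library()$pass_through
  ex <- run_experiment(m, env_ranges(X = c(0, 100)), n_simulations = 200,
                       seed = 11, burn_in = 200, measure_steps = 1000)
  dr <- dose_response(ex, "X", "Z", n_bins = 10)
  ok <- !is.na(dr$binned$mean_pct)
  # each bin mean should sit near its midpoint (binomial + uniform-within-bin
  # spread; bound with 3 SE of the dominant uniform term)
  tol <- 3 * (10 / sqrt(12)) / sqrt(pmax(dr$binned$n[ok], 1)) + 3
  expect_true(all(abs(dr$binned$mean_pct[ok] - dr$binned$midpoint[ok]) < tol))

  inv <- motif_library()$inverter
  exi <- run_experiment(inv, env_ranges(X = c(0, 100)), n_simulations = 200,
                        seed = 12, burn_in = 200, measure_steps = 1000)
  dri <- dose_response(exi, "X", "Z", n_bins = 10)
  expect_lt(stats::cor(dri$raw$input_level, dri$raw$output_pct), 0)
  bm <- dri$binned$mean_pct[!is.na(dri$binned$mean_pct)]
  expect_true(all(diff(bm) < 5))  # non-increasing up to sampling noise
})

test_that("an activator chain yields a monotone dose-response", {
  ch <- motif_library()$chain
  ex <- run_experiment(ch, env_ranges(X = c(0, 100)), n_simulations = 300,
                       seed = 21, burn_in = 200, measure_steps = 800)
  dr <- dose_response(ex, "X", "Z", n_bins = 10)
  ok <- !is.na(dr$binned$mean_pct)
  rho <- stats::cor(dr$binned$midpoint[ok], dr$binned$mean_pct[ok],
                    method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("knocking out a mandatory intermediate flattens downstream curves", {
  ch <- motif_library()$chain
  ex <- run_experiment(ch, env_ranges(X = c(0, 100)), n_simulations = 80,
                       seed = 31, burn_in = 100, measure_steps = 300,
                       mutations = list(mutation("B", "OFF")))
  dr <- dose_response(ex, "X", "Z", n_bins = 8)
  expect_true(all(dr$raw$output_pct == 0))
  expect_true(all(dr$binned$mean_pct[!is.na(dr$binned$mean_pct)] == 0))
})

test_that("experiment CSV round-trips through the readers", {
  m <- motif_library()$pass_through
  ex <- run_experiment(m, env_ranges(X = c(0, 100)), n_simulations = 25,
                       seed = 2, burn_in = 50, measure_steps = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_experiment_csv(ex, f)
  back <- read_experiment_csv(f)
  expect_equal(back$env_X, ex$env_X, tolerance = 1e-9)
  expect_equal(back$pct_Z, ex$pct_Z, tolerance = 1e-9)
  d1 <- dose_response(back, "X", "Z", n_bins = 5)
  d2 <- dose_response(back, "X", "Z", n_bins = 5)
  expect_identical(d1$binned, d2$binned)
})
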