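test_that("generated models have exact in-degree and pass validation", {
  for (k in c(2L, 5L)) {
    m <- generate_random_model(10, k, seed = 4)
    expect_true(is_valid(m))
    for (r in m$rules) {
      expect_identical(length(qualsim:::rule_deps(r)), k)
    }
  }
  m <- generate_random_model(20, 3, seed = 4, rule_style = "bio_logic")
  expect_true(is_valid(m))
  degs <- vapply(m$rules, function(r) length(qualsim:::rule_deps(r)), integer(1))
  expect_true(all(degs == 3L))
})

test_that("generation is reproducible from the seed and rejects infeasible specs", {
  a <- generate_random_model(15, 4, seed = 8)
  b <- generate_random_model(15, 4, seed = 8)
  expect_identical(a, b)
  c <- generate_random_model(15, 4, seed = 9)
  expect_false(identical(a, c))
  expect_error(generate_random_model(10, 10), "infeasible")
  expect_error(generate_random_model(10, 2, n_external = 10), "infeasible")
  expect_error(generate_random_model(30, 25, rule_style = "truth_function"),
               "capped at connectivity 20")
  m <- generate_random_model(30, 25, rule_style = "bio_logic", seed = 1)
  expect_true(is_valid(m))
})

test_that("motif library members behave as documented", {
  lib <- motif_library()
  expect_true(all(vapply(lib, is_valid, logical(1))))
  # AND gate with both inputs clamped ON -> output fixed ON
  att <- find_attractor(lib$and_gate, env_levels(X = 100, Y = 100))
  expect_identical(att$period, 1L)
  expect_identical(att$pct_on$pct_on[att$pct_on$species == "Z"], 100)
  # the ring oscillator: a 6-cycle plus a short 2-cycle partition the 8
  # states; every attractor keeps each species at 50 %ON
  ring <- lib$negative_feedback_ring
  periods <- integer(8)
  for (start in 0:7) {
    init <- oracle_index_to_state(start, 3L, species(ring)$name)
    att <- find_attractor(ring, initial_state = init)
    periods[start + 1] <- att$period
    expect_true(all(att$pct_on$pct_on == 50))
  }
  expect_setequal(unique(periods), c(6L, 2L))
  expect_identical(sum(periods == 2L), 2L)  # exactly 010 and 101
  expect_identical(find_attractor(ring, initial_state = "all_off")$period, 6L)
})

test_that("per-step cost grows at most linearly in nodes x connectivity", {
  grid <- expand.grid(n = c(10, 100, 500), k = c(2, 5, 10))
  grid <- grid[grid$k <= grid$n - 2, ]
  cost <- mapply(function(n, k) {
    m <- generate_random_model(n, k, seed = 17)
    env <- env_levels(stats::setNames(rep(50, sum(species(m)$kind == "external")),
                                      external_sp(m)))
    simulate_model(m, env, total_steps = 20, window = 5, seed = 1)  # warm up
    t0 <- proc.time()[["elapsed"]]
    simulate_model(m, env, total_steps = 400, window = 100, seed = 1)
    (proc.time()[["elapsed"]] - t0) / 400
  }, grid$n, grid$k)
  fit <- stats::lm(log(cost) ~ log(grid$n * grid$k))
  expect_lte(unname(stats::coef(fit)[2]), 1.3)
})
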