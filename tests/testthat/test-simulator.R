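test_that("external forcing is exact at the extremes and Bernoulli in between", {
  m <- boolean_model("chain", rules = list(Z = "X"))
  tr_on <- simulate_model(m, env_levels(X = 100), total_steps = 50, window = 10,
                          seed = 1)
  expect_true(all(tr_on$states$X[-1] == 1L))
  expect_true(all(tr_on$states$Z[-(1:2)] == 1L))
  tr_off <- simulate_model(m, env_levels(X = 0), total_steps = 50, window = 10,
                           seed = 1)
  expect_true(all(tr_off$states$X[-1] == 0L))

  # level 70: measured ON fraction of the downstream species within
  # 3 binomial standard errors over 10,000 steps
  st <- steady_pct_on(m, env_levels(X = 70), burn_in = 100,
                      measure_steps = 10000, seed = 42)
  se <- 100 * sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(st$pct_on[st$species == "Z"] - 70), 3 * se)
})

test_that("simulation is a deterministic function of the seed", {
  m <- generate_random_model(12, 3, n_external = 2, seed = 9)
  env <- env_levels(stats::setNames(c(35, 80), external_sp(m)))
  a <- simulate_model(m, env, total_steps = 300, window = 50, seed = 123)
  b <- simulate_model(m, env, total_steps = 300, window = 50, seed = 123)
  expect_identical(a$states, b$states)
  expect_identical(a$pct_on, b$pct_on)
  c <- simulate_model(m, env, total_steps = 300, window = 50, seed = 124)
  expect_false(identical(a$states, c$states))
})

test_that("sliding-window %ON matches its definition, with partial leading windows", {
  osc <- boolean_model("osc", rules = list(Z = "NOT Z"))
  tr <- simulate_model(osc, env_levels(), total_steps = 60, window = 10, seed = 1)
  # alternating species: exactly 50 once the window is full
  expect_true(all(tr$pct_on$Z[11:61] == 50))
  # partial-window prefix: fraction over the first t+1 states
  z <- tr$states$Z
  for (t in 1:9) {
    expect_equal(tr$pct_on$Z[t + 1], 100 * mean(z[1:(t + 1)]))
  }
  # bounds and constancy: all values in [0,100]; constant species exact
  m <- boolean_model("const", rules = list(Z = "X"))
  tr2 <- simulate_model(m, env_levels(X = 100), total_steps = 50, window = 5, seed = 1)
  expect_true(all(tr2$pct_on$X >= 0 & tr2$pct_on$X <= 100))
  expect_true(all(tr2$pct_on$Z[7:51] == 100))
})

test_that("attractors of hand-analyzed motifs are recovered exactly", {
  # fixed point: pass-through with input clamped ON
  m <- motif_library()$pass_through
  att <- find_attractor(m, env_levels(X = 100))
  expect_identical(att$period, 1L)
  expect_identical(att$pct_on$pct_on[att$pct_on$species == "Z"], 100)

  # negative-feedback 3-ring: 6-cycle, every species at 50 %ON
  ring <- motif_library()$negative_feedback_ring
  att <- find_attractor(ring)
  expect_identical(att$period, 6L)
  expect_true(all(att$pct_on$pct_on == 50))

  # positive feedback: two fixed points and a 2-cycle
  pf <- motif_library()$positive_feedback
  expect_identical(find_attractor(pf, initial_state = "all_off")$period, 1L)
  expect_identical(find_attractor(pf, initial_state = "all_on")$period, 1L)
  expect_identical(
    find_attractor(pf, initial_state = c(A = TRUE, B = FALSE))$period, 2L)

  expect_error(find_attractor(m, env_levels(X = 50)), "deterministic")
})

test_that("find_attractor agrees with the explicit transition-table oracle", {
  set.seed(303)
  for (rep in 1:25) {
    n <- sample(3:7, 1L)
    mdl <- random_small_model(n, n_external = 1L,
                              style = sample(c("bio_logic", "truth_function"), 1L))
    env01 <- stats::setNames(sample(c(0, 100), 1L), "E1")
    tt <- oracle_transition_table(mdl, env01)
    nms <- species(mdl)$name
    for (start in 0:(2^n - 1L)) {
      init <- oracle_index_to_state(start, n, nms)
      att <- find_attractor(mdl, env_levels(env01), initial_state = init)
      expect_attractor_matches_oracle(mdl, env01, att, tt, start)
    }
  }
})

test_that("steady %ON is exact under deterministic environments", {
  ring <- motif_library()$negative_feedback_ring
  st <- steady_pct_on(ring, env_levels())
  expect_identical(st$pct_on, rep(50, 3))
  att <- find_attractor(ring)
  expect_identical(st, att$pct_on)
})

test_that("mutation clamps dominate rules, environments and initial states", {
  m <- boolean_model("chain", rules = list(A = "X", Z = "A"))
  # loss of function beats a saturating input, from step 0 onward
  tr <- simulate_model(m, env_levels(X = 100), total_steps = 100, window = 10,
                       seed = 1, mutations = list(mutation("A", "OFF")),
                       initial_state = "all_on")
  expect_true(all(tr$states$A == 0L))
  expect_true(all(tr$pct_on$A == 0))
  expect_true(all(tr$states$Z[-(1:2)] == 0L))
  # gain of function beats a silent input
  st <- steady_pct_on(m, env_levels(X = 0),
                      mutations = list(mutation("A", "ON")))
  expect_identical(st$pct_on[st$species == "A"], 100)
  expect_identical(st$pct_on[st$species == "Z"], 100)
  # clamp wins in attractors too
  att <- find_attractor(m, env_levels(X = 100),
                        mutations = list(mutation("Z", "OFF")))
  expect_identical(att$pct_on$pct_on[att$pct_on$species == "Z"], 0)
})

test_that("external %ON converges to the set level without feedback", {
  m <- boolean_model("chain", rules = list(Z = "X"))
  for (a in c(10, 40, 95)) {
    st <- steady_pct_on(m, env_levels(X = a), burn_in = 200,
                        measure_steps = 10000, seed = a + 1)
    se <- 100 * sqrt((a / 100) * (1 - a / 100) / 10000)
    expect_lt(abs(st$pct_on[st$species == "X"] - a), 3 * se)
  }
})
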