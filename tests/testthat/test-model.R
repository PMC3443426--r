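test_that("model construction classifies species and keeps one rule per internal", {
  m <- boolean_model("toy", rules = list(Z = "X AND Y", W = "Z"))
  sp <- species(m)
  expect_setequal(sp$name[sp$kind == "external"], c("X", "Y"))
  expect_setequal(sp$name[sp$kind == "internal"], c("Z", "W"))
  expect_error(boolean_model("dup", rules = list(Z = "X", Z = "Y")),
               "duplicate rule target")
})

test_that("validation reports unresolved references and missing rules", {
  m <- boolean_model("toy", rules = list(Z = "X AND Y"))
  expect_identical(nrow(validate_model(m)), 0L)
  expect_true(is_valid(m))

  # rule referencing a species that is not declared anywhere: patch a model
  bad <- boolean_model("bad", rules = list(Z = "X"))
  bad$rules$Z <- bx_and(bx_var("X"), bx_var("Q"))
  rep <- validate_model(bad)
  expect_identical(sum(rep$type == "unresolved_reference"), 1L)
  expect_false(is_valid(bad))

  # internal species without a rule
  orphan <- boolean_model("orphan", rules = list(Z = "X"))
  orphan$species <- rbind(orphan$species,
                          tibble::tibble(name = "W", kind = "internal"))
  rep <- validate_model(orphan)
  expect_identical(sum(rep$type == "missing_rule"), 1L)
})

test_that("self-loops and unused externals are warnings, not errors", {
  m <- boolean_model("mem", rules = list(Z = "Z OR X"), external = "Y")
  rep <- validate_model(m)
  expect_setequal(rep$type, c("self_loop", "unused_external"))
  expect_true(all(rep$severity == "warning"))
  expect_true(is_valid(m))
})

test_that("mutations are validated against the model", {
  m <- boolean_model("toy", rules = list(Z = "X"))
  expect_error(
    simulate_model(m, env_levels(X = 0), total_steps = 10, window = 5,
                   mutations = list(mutation("Q", "ON"))),
    "unknown species")
  expect_error(
    simulate_model(m, env_levels(X = 0), total_steps = 10, window = 5,
                   mutations = list(mutation("Z", "ON"), mutation("Z", "OFF"))),
    "one mutation per species")
  expect_error(mutation("Z", "MAYBE"), "'ON' or 'OFF'")
})
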