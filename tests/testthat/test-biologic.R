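test_that("compiler reproduces the canonical activator semantics", {
  # both X and Y necessary
  both <- compile_biologic(biologic_rule("Z", list(c("X", "Y"))))
  expect_identical(format(both), "X AND Y")
  # either X or Y sufficient
  either <- compile_biologic(biologic_rule("Z", list("X", "Y")))
  expect_identical(format(either), "X OR Y")
  # single sufficient activator simplifies to the bare variable
  solo <- compile_biologic(biologic_rule("Z", list("A")))
  expect_identical(format(solo), "A")
})

test_that("inhibitors are dominant and compile to an AND NOT factor", {
  e <- compile_biologic(biologic_rule("Z", list("A", "B"), list("I")))
  expect_true(expr_equivalent(e, parse_flat_expression("(A OR B) AND NOT I")))
  tt <- truth_table(e)
  # any assignment with I active is OFF
  expect_true(all(!tt$output[tt$I]))
  expect_identical(sum(tt$output), 3L)
})

test_that("compiled rules match the set semantics on every assignment", {
  set.seed(42)
  for (rep in 1:120) {
    k <- sample(1:8, 1L)
    r <- random_biologic_rule(k)
    e <- compile_biologic(r)
    regs <- paste0("R", seq_len(k))
    for (i in 0:(2^k - 1L)) {
      st <- as.logical(bitwAnd(i %/% 2^(seq_len(k) - 1L), 1L))
      names(st) <- regs
      expect_identical(unname(eval_expr(e, st)), oracle_biologic_value(r, st))
    }
  }
})

test_that("compilation is deterministic and rejects unregulated species", {
  r <- biologic_rule("Z", list(c("Y", "X"), "W"), list(c("I", "J")))
  expect_identical(compile_biologic(r), compile_biologic(r))
  expect_error(biologic_rule("Z", list()), "unregulated internal species")
  expect_error(biologic_rule("Z", list(character())), "empty activator clause")
})

test_that("truth-table rules expand to equivalent expressions", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(1:5, 1L)
    r <- truthfn_rule("T", paste0("R", seq_len(k)), stats::runif(2^k) < 0.5)
    e <- truthfn_to_expr(r)
    for (i in 0:(2^k - 1L)) {
      st <- as.logical(bitwAnd(i %/% 2^(seq_len(k) - 1L), 1L))
      names(st) <- r$regulators
      expect_identical(unname(as.logical(eval_expr(e, st))),
                       unname(oracle_truthfn_value(r, st)))
    }
  }
  big <- truthfn_rule("T", paste0("R", 1:15), stats::runif(2^15) < 0.5)
  expect_error(truthfn_to_expr(big), "too large")
})
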