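test_that("evaluation follows standard Boolean semantics", {
  e <- bx_and(bx_var("X"), bx_var("Y"))
  expect_false(eval_expr(e, c(X = TRUE, Y = FALSE)))
  expect_true(eval_expr(e, c(X = TRUE, Y = TRUE)))
  expect_true(eval_expr(bx_const(TRUE), logical()))
  expect_false(eval_expr(bx_not(bx_const(TRUE)), logical()))
  expect_error(eval_expr(e, c(X = TRUE)), "incomplete state")
})

test_that("random expressions agree with R's own evaluator on all assignments", {
  set.seed(7)
  random_expr <- function(depth, vars) {
    if (depth == 0L || stats::runif(1) < 0.3) {
      if (stats::runif(1) < 0.1) return(bx_const(stats::runif(1) < 0.5))
      return(bx_var(sample(vars, 1L)))
    }
    op <- sample(c("not", "and", "or"), 1L)
    if (op == "not") return(bx_not(random_expr(depth - 1L, vars)))
    kids <- lapply(seq_len(sample(2:3, 1L)), function(i) random_expr(depth - 1L, vars))
    if (op == "and") bx_and(kids) else bx_or(kids)
  }
  vars <- c("A", "B", "C", "D")
  for (rep in 1:50) {
    e <- random_expr(4L, vars)
    used <- sort(expr_vars(e))
    k <- length(used)
    for (i in 0:(2^max(k, 1) - 1L)) {
      st <- as.logical(bitwAnd(i %/% 2^(seq_len(max(k, 1L)) - 1L), 1L))
      names(st) <- if (k > 0) used else "dummy"
      expect_identical(eval_expr(e, st), oracle_eval(e, st))
    }
  }
})

test_that("truth tables enumerate lexicographic variables in counting order", {
  tt <- truth_table(parse_flat_expression("X AND Y"))
  expect_identical(nrow(tt), 4L)
  expect_identical(tt$output, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(tt$X, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(tt$Y, c(FALSE, TRUE, FALSE, TRUE))

  expect_identical(sum(truth_table(parse_flat_expression("X OR Y"))$output), 3L)
  expect_identical(
    sum(truth_table(parse_flat_expression("(A OR B) AND NOT I"))$output), 3L)

  wide <- bx_or(lapply(paste0("V", 1:25), bx_var))
  expect_error(truth_table(wide), "table too large")
})

test_that("the infix printer round-trips through the parser", {
  set.seed(11)
  for (rep in 1:40) {
    k <- sample(2:4, 1L)
    r <- random_biologic_rule(k)
    e <- compile_biologic(r)
    expect_true(expr_equivalent(e, parse_flat_expression(format(e))))
  }
  e <- parse_flat_expression("NOT (A OR B) AND C")
  expect_true(expr_equivalent(e, parse_flat_expression(format(e))))
})
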