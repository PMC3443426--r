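#' Boolean expression constructors
#'
#' A Boolean expression is an abstract syntax tree over species names with
#' node kinds `var`, `not`, `and`, `or` and `const`. These constructors build
#' the tree directly; most users obtain expressions from [compile_biologic()],
#' [parse_flat_text()] or the expression mini-parser behind [boolean_model()].
#'
#' `bx_and()` and `bx_or()` require at least two operands; a single operand is
#' returned unchanged so compiled rules never carry degenerate connectives.
#'
#' @param name Species name (single non-empty string).
#' @param x,... Boolean expressions (operands).
#' @param value Logical scalar for `bx_const()`.
#' @return An object of class `boolexpr`.
#' @examples
#' e <- bx_and(bx_var("X"), bx_var("Y"))
#' eval_expr(e, c(X = TRUE, Y = FALSE))
#' @export
bx_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "var", name = name), class = "boolexpr")
}

#' @rdname bx_var
#' @export
bx_not <- function(x) {
  stopifnot(inherits(x, "boolexpr"))
  structure(list(kind = "not", child = x), class = "boolexpr")
}

#' @rdname bx_var
#' @export
bx_and <- function(...) {
  ch <- flatten_operands(list(...))
  if (length(ch) == 1L) return(ch[[1L]])
  structure(list(kind = "and", children = ch), class = "boolexpr")
}

#' @rdname bx_var
#' @export
bx_or <- function(...) {
  ch <- flatten_operands(list(...))
  if (length(ch) == 1L) return(ch[[1L]])
  structure(list(kind = "or", children = ch), class = "boolexpr")
}

#' @rdname bx_var
#' @export
bx_const <- function(value) {
  stopifnot(is.logical(value), length(value) == 1L, !is.na(value))
  structure(list(kind = "const", value = value), class = "boolexpr")
}

flatten_operands <- function(xs) {
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "boolexpr")) {
    xs <- xs[[1L]]
  }
  if (length(xs) == 0L) stop("at least one operand required", call. = FALSE)
  for (x in xs) stopifnot(inherits(x, "boolexpr"))
  xs
}

#' Evaluate a Boolean expression under a state assignment
#'
#' Standard Boolean semantics. The state may be a named logical vector or a
#' named list; values may be vectors of common length, in which case the
#' expression is evaluated elementwise (this is how truth tables are built).
#'
#' @param expr A `boolexpr`.
#' @param state Named logical vector/list assigning every variable in `expr`.
#' @return Logical vector (scalar for scalar states).
#' @export
eval_expr <- function(expr, state) {
  stopifnot(inherits(expr, "boolexpr"))
  switch(expr$kind,
    const = expr$value,
    var = {
      if (is.null(names(state)) || !(expr$name %in% names(state))) {
        stop("incomplete state: no value for variable '", expr$name, "'",
             call. = FALSE)
      }
      v <- if (is.list(state)) state[[expr$name]] else state[[expr$name]]
      as.logical(v)
    },
    not = !eval_expr(expr$child, state),
    and = Reduce(`&`, lapply(expr$children, eval_expr, state = state)),
    or  = Reduce(`|`, lapply(expr$children, eval_expr, state = state)),
    stop("unknown expression kind: ", expr$kind)
  )
}

#' Variables referenced by a Boolean expression
#'
#' @param expr A `boolexpr`.
#' @return Character vector of distinct variable names, in first-appearance
#'   order.
#' @export
expr_vars <- function(expr) {
  stopifnot(inherits(expr, "boolexpr"))
  out <- switch(expr$kind,
    const = character(),
    var = expr$name,
    not = expr_vars(expr$child),
    and = unlist(lapply(expr$children, expr_vars)),
    or  = unlist(lapply(expr$children, expr_vars))
  )
  unique(out)
}

#' Truth table of a Boolean expression
#'
#' Enumerates all assignments of the expression's variables. Variables are
#' ordered lexicographically; rows enumerate assignments in binary counting
#' order with the first variable as the most significant bit, so `X AND Y`
#' yields rows 00, 01, 10, 11 with outputs 0, 0, 0, 1.
#'
#' @param expr A `boolexpr` with at most `max_vars` distinct variables.
#' @param max_vars Guard on the number of variables (default 20).
#' @return A tibble with one logical column per variable plus `output`.
#' @export
truth_table <- function(expr, max_vars = 20L) {
  vars <- sort(expr_vars(expr))
  k <- length(vars)
  if (k > max_vars) {
    stop("table too large: ", k, " variables exceeds the guard of ", max_vars,
         call. = FALSE)
  }
  if (k == 0L) {
    return(tibble::tibble(output = eval_expr(expr, logical())))
  }
  idx <- 0:(2^k - 1L)
  cols <- lapply(seq_len(k), function(j) {
    # variable j is bit (k - j): first variable most significant
    bitwAnd(idx %/% 2^(k - j), 1L) == 1L
  })
  names(cols) <- vars
  out <- eval_expr(expr, cols)
  tibble::as_tibble(c(cols, list(output = rep_len(out, length(idx)))))
}

#' Test logical equivalence of two Boolean expressions
#'
#' Compares complete truth tables over the union of the two variable sets.
#'
#' @param a,b `boolexpr` objects.
#' @param max_vars Guard on the number of distinct variables.
#' @return `TRUE` if the expressions agree on every assignment.
#' @export
expr_equivalent <- function(a, b, max_vars = 20L) {
  vars <- sort(union(expr_vars(a), expr_vars(b)))
  k <- length(vars)
  if (k > max_vars) stop("table too large: ", k, " variables", call. = FALSE)
  if (k == 0L) return(identical(eval_expr(a, logical()), eval_expr(b, logical())))
  idx <- 0:(2^k - 1L)
  cols <- lapply(seq_len(k), function(j) bitwAnd(idx %/% 2^(k - j), 1L) == 1L)
  names(cols) <- vars
  all(rep_len(eval_expr(a, cols), length(idx)) ==
        rep_len(eval_expr(b, cols), length(idx)))
}

#' @export
format.boolexpr <- function(x, ...) {
  deparse_bx(x, parent = "top")
}

# precedence-aware infix printer: NOT > AND > OR; children wrap themselves
# when their operator binds looser than the parent's
deparse_bx <- function(e, parent) {
  switch(e$kind,
    const = if (e$value) "TRUE" else "FALSE",
    var = e$name,
    not = paste0("NOT ", deparse_bx(e$child, "not")),
    and = {
      parts <- vapply(e$children, deparse_bx, character(1), parent = "and")
      wrap_if(paste(parts, collapse = " AND "), parent == "not")
    },
    or = {
      parts <- vapply(e$children, deparse_bx, character(1), parent = "or")
      wrap_if(paste(parts, collapse = " OR "), parent %in% c("and", "not"))
    }
  )
}

wrap_if <- function(s, cond) if (cond) paste0("(", s, ")") else s

#' @export
print.boolexpr <- function(x, ...) {
  cat("<boolexpr> ", format(x), "\n", sep = "")
  invisible(x)
}
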