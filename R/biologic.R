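#' Qualitative "bio-logic" regulatory rules
#'
#' A bio-logic rule describes the regulation of one species by its upstream
#' activators and inhibitors, the way a bench scientist states it: each
#' *activator clause* is a set of co-required activators (all members jointly
#' necessary); distinct clauses are alternatives (any one fully active clause
#' suffices). *Inhibitor clauses* work the same way on the repressive side and
#' are dominant: if any inhibitor clause is fully active the target is forced
#' OFF regardless of its activators.
#'
#' Clause members are de-duplicated and stored sorted (clauses are sets);
#' clause order is preserved as given. An internal species must have at least
#' one activator clause — a species with no positive regulator is a modelling
#' error, not a constant.
#'
#' @param target Name of the regulated species.
#' @param activators List of character vectors (activator clauses); a plain
#'   character vector is treated as a single clause.
#' @param inhibitors List of character vectors (inhibitor clauses), possibly
#'   empty.
#' @return An object of class `biologic_rule`.
#' @examples
#' # both X and Y necessary:
#' compile_biologic(biologic_rule("Z", list(c("X", "Y"))))
#' # either X or Y sufficient:
#' compile_biologic(biologic_rule("Z", list("X", "Y")))
#' @export
biologic_rule <- function(target, activators, inhibitors = list()) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  norm <- function(cl, what) {
    if (is.character(cl)) cl <- list(cl)
    stopifnot(is.list(cl))
    cl <- lapply(cl, function(m) {
      m <- sort(unique(as.character(m)))
      if (length(m) == 0L || any(!nzchar(m))) {
        stop("empty ", what, " clause in rule for '", target, "'", call. = FALSE)
      }
      m
    })
    cl
  }
  activators <- norm(activators, "activator")
  if (length(activators) == 0L) {
    stop("unregulated internal species: rule for '", target,
         "' has no activator clause", call. = FALSE)
  }
  inhibitors <- if (length(inhibitors)) norm(inhibitors, "inhibitor") else list()
  structure(list(target = target, activators = activators,
                 inhibitors = inhibitors),
            class = "biologic_rule")
}

#' Compile a bio-logic rule to a Boolean expression
#'
#' Produces `(OR over activator clauses of (AND within clause)) AND NOT
#' (OR over inhibitor clauses of (AND within clause))`, with dominant
#' inhibition. Singleton clauses and single-clause ORs are simplified to their
#' child, and with no inhibitor clauses the `NOT (...)` factor is omitted.
#' Compilation is deterministic: the same rule always yields a structurally
#' identical AST.
#'
#' @param rule A [biologic_rule()].
#' @return A `boolexpr`.
#' @export
compile_biologic <- function(rule) {
  stopifnot(inherits(rule, "biologic_rule"))
  clause_expr <- function(members) {
    vars <- lapply(members, bx_var)
    if (length(vars) == 1L) vars[[1L]] else bx_and(vars)
  }
  act <- lapply(rule$activators, clause_expr)
  act_expr <- if (length(act) == 1L) act[[1L]] else bx_or(act)
  if (length(rule$inhibitors) == 0L) return(act_expr)
  inh <- lapply(rule$inhibitors, clause_expr)
  inh_expr <- if (length(inh) == 1L) inh[[1L]] else bx_or(inh)
  bx_and(act_expr, bx_not(inh_expr))
}

#' @export
print.biologic_rule <- function(x, ...) {
  fmt <- function(cl) paste(vapply(cl, paste, character(1), collapse = " + "),
                            collapse = " | ")
  cat("<biologic_rule> ", x$target, " <- activators: ", fmt(x$activators),
      if (length(x$inhibitors)) paste0("; inhibitors: ", fmt(x$inhibitors)),
      "\n", sep = "")
  invisible(x)
}

#' Truth-table rules
#'
#' A rule given directly as an arbitrary Boolean function of its regulators:
#' an output column over all `2^k` assignments of the `k` regulators. This is
#' the rule style used for random benchmark networks, where a clause structure
#' is not meaningful.
#'
#' The output vector is indexed by `1 + sum_j state[regulators[j]] * 2^(j-1)`:
#' the first regulator is the least significant bit.
#'
#' @param target Name of the regulated species.
#' @param regulators Character vector of distinct regulator names (k >= 1,
#'   k <= 20).
#' @param outputs Logical vector of length `2^k`.
#' @return An object of class `truthfn_rule`.
#' @export
truthfn_rule <- function(target, regulators, outputs) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  regulators <- as.character(regulators)
  k <- length(regulators)
  if (k < 1L || anyDuplicated(regulators)) {
    stop("regulators must be a non-empty set of distinct names", call. = FALSE)
  }
  if (k > 20L) stop("truth-table rules capped at 20 regulators", call. = FALSE)
  outputs <- as.logical(outputs)
  if (length(outputs) != 2^k || anyNA(outputs)) {
    stop("outputs must be a complete logical vector of length 2^k", call. = FALSE)
  }
  structure(list(target = target, regulators = regulators, outputs = outputs),
            class = "truthfn_rule")
}

#' @export
print.truthfn_rule <- function(x, ...) {
  cat("<truthfn_rule> ", x$target, " <- f(",
      paste(x$regulators, collapse = ", "), "), ",
      sum(x$outputs), "/", length(x$outputs), " rows ON\n", sep = "")
  invisible(x)
}

#' Expand a truth-table rule to a Boolean expression
#'
#' Builds the disjunctive normal form over the ON rows. Only sensible for
#' small regulator sets; guarded at `max_vars` regulators (default 12) because
#' the DNF has one minterm per ON row.
#'
#' @param rule A [truthfn_rule()].
#' @param max_vars Guard on the regulator count.
#' @return A `boolexpr` logically equal to the tabulated function.
#' @export
truthfn_to_expr <- function(rule, max_vars = 12L) {
  stopifnot(inherits(rule, "truthfn_rule"))
  k <- length(rule$regulators)
  if (k > max_vars) {
    stop("rule for '", rule$target, "' has ", k,
         " regulators; too large to serialize as an expression", call. = FALSE)
  }
  on_rows <- which(rule$outputs) - 1L
  if (length(on_rows) == 0L) return(bx_const(FALSE))
  if (length(on_rows) == 2^k) return(bx_const(TRUE))
  minterm <- function(row) {
    lits <- lapply(seq_len(k), function(j) {
      v <- bx_var(rule$regulators[j])
      if (bitwAnd(row %/% 2^(j - 1L), 1L) == 1L) v else bx_not(v)
    })
    if (length(lits) == 1L) lits[[1L]] else bx_and(lits)
  }
  terms <- lapply(on_rows, minterm)
  if (length(terms) == 1L) terms[[1L]] else bx_or(terms)
}

# normalize any rule object to the boolexpr that drives the update
rule_to_expr <- function(rule) {
  if (inherits(rule, "boolexpr")) return(rule)
  if (inherits(rule, "biologic_rule")) return(compile_biologic(rule))
  if (inherits(rule, "truthfn_rule")) return(truthfn_to_expr(rule))
  stop("unsupported rule object of class ", paste(class(rule), collapse = "/"),
       call. = FALSE)
}

# names a rule depends on, without expanding truth-table rules
rule_deps <- function(rule) {
  if (inherits(rule, "boolexpr")) return(expr_vars(rule))
  if (inherits(rule, "biologic_rule")) {
    return(unique(unlist(c(rule$activators, rule$inhibitors))))
  }
  if (inherits(rule, "truthfn_rule")) return(rule$regulators)
  stop("unsupported rule object", call. = FALSE)
}
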