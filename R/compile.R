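# Lower a validated model to the stepper's compiled form: every rule becomes
# either a postfix program over species indices or a truth-table lookup.
# The compiled form is cached on first use inside simulation calls.

compile_for_stepper <- function(model) {
  sp <- model$species$name
  idx0 <- stats::setNames(seq_along(sp) - 1L, sp)
  targets <- names(model$rules)
  rule_type <- integer(length(targets))
  ops <- vector("list", length(targets))
  args <- vector("list", length(targets))
  regs <- vector("list", length(targets))
  tts <- vector("list", length(targets))
  stack_need <- 1L
  for (i in seq_along(targets)) {
    r <- model$rules[[i]]
    if (inherits(r, "truthfn_rule")) {
      rule_type[i] <- 2L
      regs[[i]] <- unname(idx0[r$regulators])
      tts[[i]] <- as.raw(r$outputs)
      ops[[i]] <- integer()
      args[[i]] <- integer()
    } else {
      e <- rule_to_expr(r)
      prog <- flatten_rpn(e, idx0)
      rule_type[i] <- 1L
      ops[[i]] <- prog$ops
      args[[i]] <- prog$args
      regs[[i]] <- integer()
      tts[[i]] <- raw()
      stack_need <- max(stack_need, prog$depth)
    }
  }
  list(
    n = length(sp),
    target_idx = unname(idx0[targets]),
    rule_type = rule_type,
    ops = ops, args = args, regs = regs, tts = tts,
    ext_idx = unname(idx0[external_species(model)]),
    stack_need = stack_need
  )
}

# postfix-flatten a boolexpr; returns ops/args vectors and max stack depth
flatten_rpn <- function(e, idx0) {
  ops <- integer()
  args <- integer()
  emit <- function(op, arg) {
    ops[[length(ops) + 1L]] <<- op
    args[[length(args) + 1L]] <<- arg
  }
  walk <- function(x) {
    switch(x$kind,
      const = { emit(0L, as.integer(x$value)); 1L },
      var = {
        if (is.na(idx0[x$name])) stop("unresolved variable '", x$name, "'", call. = FALSE)
        emit(1L, unname(idx0[x$name])); 1L
      },
      not = { d <- walk(x$child); emit(2L, 0L); d },
      and = {
        ds <- integer(length(x$children))
        for (j in seq_along(x$children)) ds[j] <- walk(x$children[[j]]) + (j - 1L)
        emit(3L, length(x$children)); max(ds)
      },
      or = {
        ds <- integer(length(x$children))
        for (j in seq_along(x$children)) ds[j] <- walk(x$children[[j]]) + (j - 1L)
        emit(4L, length(x$children)); max(ds)
      }
    )
  }
  depth <- walk(e)
  list(ops = ops, args = args, depth = depth)
}

#' Pre-validate and pre-compile a model
#'
#' Simulation entry points validate a model and lower its rules to the
#' internal update program on every call. For workloads that run thousands of
#' short simulations on the same model (attractor sweeps over all initial
#' states, large experiments), `precompile()` performs both once and caches
#' the results on the returned model object; every simulation function reuses
#' the cache.
#'
#' @param model A `boolean_model`.
#' @return The same model with validation and compilation caches attached.
#' @export
precompile <- function(model) {
  stop_if_invalid(model)
  attr(model, "validated") <- TRUE
  attr(model, "compiled") <- compile_for_stepper(model)
  model
}

get_compiled <- function(model) {
  cc <- attr(model, "compiled")
  if (is.null(cc)) cc <- compile_for_stepper(model)
  cc
}
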