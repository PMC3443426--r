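# Independent brute-force oracles. These deliberately avoid the package's
# evaluation and simulation code paths: expressions are converted to R
# language and evaluated by R itself; the synchronous map is tabulated
# explicitly over all 2^n states and cycles are extracted by walking the
# table.

# boolexpr -> R source using &, |, ! (independent of the package printer)
oracle_expr_to_r <- function(e) {
  switch(e$kind,
    const = if (e$value) "TRUE" else "FALSE",
    var = e$name,
    not = paste0("(!", oracle_expr_to_r(e$child), ")"),
    and = paste0("(", paste(vapply(e$children, oracle_expr_to_r, character(1)),
                            collapse = " & "), ")"),
    or = paste0("(", paste(vapply(e$children, oracle_expr_to_r, character(1)),
                           collapse = " | "), ")")
  )
}

oracle_eval <- function(e, state) {
  eval(parse(text = oracle_expr_to_r(e)), envir = as.list(state))
}

# set-semantics of a bio-logic rule: some fully active activator clause and
# no fully active inhibitor clause
oracle_biologic_value <- function(rule, state) {
  act <- any(vapply(rule$activators, function(cl) all(state[cl]), logical(1)))
  inh <- length(rule$inhibitors) > 0 &&
    any(vapply(rule$inhibitors, function(cl) all(state[cl]), logical(1)))
  act && !inh
}

# documented truth-table rule indexing, re-derived here
oracle_truthfn_value <- function(rule, state) {
  idx <- 1 + sum(as.integer(state[rule$regulators]) * 2^(seq_along(rule$regulators) - 1))
  rule$outputs[idx]
}

oracle_rule_value <- function(rule, state) {
  if (inherits(rule, "truthfn_rule")) return(oracle_truthfn_value(rule, state))
  if (inherits(rule, "biologic_rule")) return(oracle_biologic_value(rule, state))
  oracle_eval(rule, state)
}

# one synchronous update under a deterministic environment (named 0/100) and
# optional mutations
oracle_step <- function(model, state, env01, mutations = list()) {
  sp <- species(model)
  nxt <- state
  for (tgt in names(model$rules)) {
    nxt[tgt] <- oracle_rule_value(model$rules[[tgt]], state)
  }
  for (e in sp$name[sp$kind == "external"]) nxt[e] <- env01[[e]] >= 100
  for (m in mutations) nxt[m$species] <- (m$state == "ON")
  nxt
}

oracle_index_to_state <- function(idx, n, nms) {
  st <- as.logical(bitwAnd(idx %/% 2^(seq_len(n) - 1L), 1L))
  names(st) <- nms
  st
}

oracle_state_to_index <- function(state) {
  sum(as.integer(state) * 2^(seq_along(state) - 1L))
}

# full explicit state-transition table: next[i + 1] for state index i.
# Vectorized over all 2^n states at once, using R's own evaluator for
# expression rules and the clause set-semantics / documented lookup rule for
# the structured rule types.
oracle_transition_table <- function(model, env01, mutations = list()) {
  sp <- species(model)
  nms <- sp$name
  n <- length(nms)
  idx <- 0:(2^n - 1L)
  cols <- lapply(seq_len(n), function(j) bitwAnd(idx %/% 2^(j - 1L), 1L) == 1L)
  names(cols) <- nms
  nxt <- cols
  for (tgt in names(model$rules)) {
    r <- model$rules[[tgt]]
    if (inherits(r, "truthfn_rule")) {
      ii <- Reduce(`+`, lapply(seq_along(r$regulators), function(j) {
        as.integer(cols[[r$regulators[j]]]) * 2^(j - 1L)
      })) + 1L
      nxt[[tgt]] <- r$outputs[ii]
    } else if (inherits(r, "biologic_rule")) {
      act <- Reduce(`|`, lapply(r$activators, function(cl) Reduce(`&`, cols[cl])))
      inh <- if (length(r$inhibitors)) {
        Reduce(`|`, lapply(r$inhibitors, function(cl) Reduce(`&`, cols[cl])))
      } else FALSE
      nxt[[tgt]] <- act & !inh
    } else {
      nxt[[tgt]] <- rep_len(
        eval(parse(text = oracle_expr_to_r(r)), envir = cols), length(idx))
    }
  }
  for (e in nms[sp$kind == "external"]) {
    nxt[[e]] <- rep(env01[[e]] >= 100, length(idx))
  }
  for (m in mutations) nxt[[m$species]] <- rep(m$state == "ON", length(idx))
  Reduce(`+`, lapply(seq_len(n), function(j) as.integer(nxt[[nms[j]]]) * 2^(j - 1L)))
}

# walk the table from a start index; cycle starts at the first revisited state
oracle_attractor <- function(tt, start) {
  seen <- rep(-1L, length(tt))
  path <- integer()
  cur <- start
  t <- 0L
  while (seen[cur + 1L] < 0L) {
    seen[cur + 1L] <- t
    path <- c(path, cur)
    cur <- as.integer(tt[cur + 1L])
    t <- t + 1L
  }
  first <- seen[cur + 1L]
  list(transient_length = first, cycle = path[(first + 1L):length(path)])
}

external_sp <- function(m) species(m)$name[species(m)$kind == "external"]

# random bio-logic rule over regulators R1..Rk with >= 1 activator clause
random_biologic_rule <- function(k) {
  regs <- paste0("R", seq_len(k))
  n_act <- sample(seq_len(k), 1L)
  act <- regs[seq_len(n_act)]
  inh <- if (n_act < k) regs[(n_act + 1L):k] else character()
  part <- function(m) {
    if (length(m) == 0L) return(list())
    unname(split(m, sort(sample(seq_along(m), length(m), replace = TRUE))))
  }
  biologic_rule("T", part(act), part(inh))
}

# random small model with deterministic-friendly structure for attractor
# oracle tests; mixes rule styles
random_small_model <- function(n_species, n_external = 1L,
                               style = c("bio_logic", "truth_function")) {
  style <- match.arg(style)
  stopifnot(n_species >= 2L, n_external < n_species)
  ext <- if (n_external > 0L) paste0("E", seq_len(n_external)) else character()
  int <- paste0("S", seq_len(n_species - n_external))
  all_sp <- c(ext, int)
  rules <- lapply(int, function(tgt) {
    k <- sample(1:min(3L, n_species - 1L), 1L)
    regs <- sample(setdiff(all_sp, tgt), k)
    if (style == "truth_function") {
      truthfn_rule(tgt, regs, stats::runif(2^k) < 0.5)
    } else {
      n_act <- sample(seq_len(k), 1L)
      part <- function(m) {
        if (length(m) == 0L) return(list())
        unname(split(m, sort(sample(seq_along(m), length(m), replace = TRUE))))
      }
      biologic_rule(tgt, part(regs[seq_len(n_act)]),
                    part(if (n_act < k) regs[(n_act + 1L):k] else character()))
    }
  })
  names(rules) <- int
  boolean_model(paste0("rnd_", n_species), rules, external = ext)
}

# compare a find_attractor() result with the oracle for one start state
expect_attractor_matches_oracle <- function(model, env01, att, tt, start_idx) {
  orc <- oracle_attractor(tt, start_idx)
  expect_identical(att$transient_length, orc$transient_length)
  expect_identical(att$period, length(orc$cycle))
  nms <- species(model)$name
  impl_idx <- apply(as.matrix(att$cycle_states), 1, function(r) {
    sum(as.integer(r) * 2^(seq_along(r) - 1L))
  })
  expect_identical(as.integer(impl_idx), as.integer(orc$cycle))
}
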