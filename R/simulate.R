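#' Specify an extracellular environment
#'
#' An environment assigns every external species of a model an activity level
#' in %ON on a 0-100 scale. During simulation each external species is set ON
#' independently at each step with probability `level/100` (one Bernoulli
#' draw per external species per step, in model declaration order), so its
#' long-run measured %ON equals the set level.
#'
#' @param ... Named levels (`X = 70, Y = 0`), or a single named numeric
#'   vector.
#' @return A named numeric vector of class `env_levels`.
#' @examples
#' env_levels(EGF = 100, ECM = 75)
#' @export
env_levels <- function(...) {
  xs <- list(...)
  if (length(xs) == 0L) return(structure(numeric(), class = "env_levels"))
  if (length(xs) == 1L && is.null(names(xs)) && !is.null(names(xs[[1L]]))) {
    v <- xs[[1L]]
  } else {
    v <- unlist(xs)
  }
  v <- vapply(v, as.numeric, numeric(1))
  if (length(v) == 0L) return(structure(numeric(), class = "env_levels"))
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop("every environment level must be named", call. = FALSE)
  }
  if (any(v < 0 | v > 100 | is.na(v))) {
    stop("activity levels must lie in [0, 100] %ON", call. = FALSE)
  }
  structure(v, class = "env_levels")
}

# align an environment with a model's external species; errors on gaps
check_environment <- function(model, env) {
  ext <- external_species(model)
  if (length(ext) == 0L) return(numeric())
  if (inherits(env, "env_levels")) env <- unclass(env)
  env <- vapply(env, as.numeric, numeric(1))
  missing <- setdiff(ext, names(env))
  if (length(missing)) {
    stop("unbound external species: no activity level for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(env), ext)
  if (length(extra)) {
    stop("environment names unknown external species: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(env < 0 | env > 100 | is.na(env))) {
    stop("activity levels must lie in [0, 100] %ON", call. = FALSE)
  }
  env[ext]
}

resolve_initial <- function(model, initial_state, mutations) {
  sp <- model$species$name
  n <- length(sp)
  st <- if (is.character(initial_state) && length(initial_state) == 1L) {
    switch(initial_state,
      all_off = rep(FALSE, n),
      all_on = rep(TRUE, n),
      random = stats::runif(n) < 0.5,
      stop("initial_state must be 'all_off', 'all_on', 'random' or a named logical vector",
           call. = FALSE)
    )
  } else {
    v <- rep(FALSE, n)
    init <- as.logical(initial_state)
    names(init) <- names(initial_state)
    unknown <- setdiff(names(init), sp)
    if (length(unknown)) {
      stop("initial state names unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    v[match(names(init), sp)] <- init
    v
  }
  names(st) <- sp
  for (m in mutations) st[m$species] <- (m$state == "ON")
  st
}

mutation_idx <- function(model, mutations) {
  sp <- model$species$name
  list(
    idx = vapply(mutations, function(m) match(m$species, sp) - 1L, integer(1)),
    val = vapply(mutations, function(m) as.integer(m$state == "ON"), integer(1))
  )
}

#' Simulate a model under continuous external stimuli
#'
#' Runs `total_steps` synchronous updates: every internal species takes the
#' value of its rule evaluated on the previous full state, every external
#' species is redrawn ON with probability `level/100`, and mutated species
#' are clamped last. Alongside the raw Boolean states, a per-species moving
#' average activity (%ON over a sliding window of `window` steps; a partial
#' window is used for the leading `window - 1` steps) is reported.
#'
#' @param model A valid `boolean_model`.
#' @param env An [env_levels()] environment covering every external species.
#' @param total_steps Number of update steps (default 1000).
#' @param window Sliding-window length in steps (default 100; must not exceed
#'   `total_steps`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param mutations List of [mutation()] objects (at most one per species).
#' @param initial_state `"all_off"` (default), `"all_on"`, `"random"`, or a
#'   named logical vector (unnamed species start OFF).
#' @return An object of class `trajectory` with tibbles `states` (step 0 is
#'   the initial state) and `pct_on`, plus the configuration. Use
#'   [generics::tidy()] for a long tibble and [ggplot2::autoplot()] to plot
#'   activity traces.
#' @examples
#' m <- boolean_model("chain", rules = list(Z = "X"))
#' tr <- simulate_model(m, env_levels(X = 70), total_steps = 200, seed = 1)
#' dplyr::last(tr$pct_on$Z)
#' @export
simulate_model <- function(model, env, total_steps = 1000L, window = 100L,
                           seed = NULL, mutations = list(),
                           initial_state = "all_off") {
  stop_if_invalid(model)
  total_steps <- as.integer(total_steps)
  window <- as.integer(window)
  stopifnot(total_steps >= 1L, window >= 1L)
  if (window > total_steps) {
    stop("window must not exceed total_steps", call. = FALSE)
  }
  mutations <- check_mutations(model, mutations)
  lv <- check_environment(model, env)
  if (!is.null(seed)) set.seed(seed)
  init <- resolve_initial(model, initial_state, mutations)
  mu <- mutation_idx(model, mutations)
  cm <- get_compiled(model)
  S <- cpp_simulate(cm, lv / 100, mu$idx, mu$val, unname(init), total_steps)
  colnames(S) <- model$species$name
  pct <- sliding_pct_on(S, window)
  structure(list(
    states = tibble::as_tibble(cbind(data.frame(step = 0:total_steps),
                                     as.data.frame(S * 1L))),
    pct_on = tibble::as_tibble(cbind(data.frame(step = 0:total_steps),
                                     as.data.frame(pct))),
    model_name = model$name,
    env = lv, window = window, seed = seed,
    mutations = mutations, initial_state = initial_state
  ), class = "trajectory")
}

# %ON at row t = 100 * mean of the last min(t, window) states (rows are
# steps 0..T)
sliding_pct_on <- function(S, window) {
  S <- matrix(as.numeric(S), nrow = nrow(S), dimnames = dimnames(S))
  cs <- apply(S, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(S), dimnames = dimnames(S))
  t_idx <- seq_len(nrow(S))
  lag <- pmax(t_idx - window, 0L)
  num <- cs - cs[pmax(lag, 1L), , drop = FALSE] * (lag > 0)
  denom <- pmin(t_idx, window)
  100 * num / denom
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model_name, ": ", nrow(x$states) - 1L, " steps, ",
      ncol(x$states) - 1L, " species, window ", x$window, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.trajectory <- function(x, ...) {
  st <- tidyr::pivot_longer(x$states, -"step", names_to = "species",
                            values_to = "state")
  pc <- tidyr::pivot_longer(x$pct_on, -"step", names_to = "species",
                            values_to = "pct_on")
  dplyr::left_join(st, pc, by = c("step", "species"))
}

#' @export
autoplot.trajectory <- function(object, species = NULL, ...) {
  d <- tidy.trajectory(object)
  if (!is.null(species)) d <- dplyr::filter(d, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$pct_on,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "activity (%ON)", colour = "species") +
    ggplot2::ylim(0, 100)
}

#' Find the attractor reached under a deterministic environment
#'
#' When every external activity level is exactly 0 or 100 the synchronous
#' dynamics are a deterministic map; iterating from the initial state must
#' eventually revisit a state, closing a cycle (a fixed point when the cycle
#' has length 1). The attractor %ON of a species is the percentage of cycle
#' states in which it is ON — the settled activity the sliding-window measure
#' converges to.
#'
#' @inheritParams simulate_model
#' @param env Environment with every level exactly 0 or 100.
#' @param cap Iteration cap before giving up (default `2^22`).
#' @return An object of class `attractor`: `cycle_states` tibble (one row per
#'   cycle state), `transient_length`, `period` and a `pct_on` tibble.
#' @examples
#' ring <- boolean_model("ring", rules = list(A = "NOT C", B = "A", C = "B"))
#' find_attractor(ring, env_levels())$period
#' @export
find_attractor <- function(model, env = env_levels(), mutations = list(),
                           initial_state = "all_off", cap = 2^22) {
  stop_if_invalid(model)
  mutations <- check_mutations(model, mutations)
  lv <- check_environment(model, env)
  if (!all(lv %in% c(0, 100))) {
    stop("find_attractor requires a deterministic environment: every level exactly 0 or 100",
         call. = FALSE)
  }
  init <- resolve_initial(model, initial_state, mutations)
  mu <- mutation_idx(model, mutations)
  cm <- get_compiled(model)
  res <- cpp_find_attractor(cm, as.integer(lv == 100), mu$idx, mu$val,
                            unname(init), cap)
  cyc <- res$cycle
  colnames(cyc) <- model$species$name
  pct <- 100 * colMeans(matrix(as.numeric(cyc), nrow = nrow(cyc)))
  structure(list(
    cycle_states = tibble::as_tibble(as.data.frame(cyc * 1L)),
    transient_length = res$transient_length,
    period = nrow(cyc),
    pct_on = tibble::tibble(species = model$species$name,
                            kind = model$species$kind,
                            pct_on = pct),
    model_name = model$name, env = lv, mutations = mutations
  ), class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor> ", x$model_name, ": period ", x$period,
      ", transient ", x$transient_length, "\n", sep = "")
  print(x$pct_on)
  invisible(x)
}

#' @export
tidy.attractor <- function(x, ...) x$pct_on

#' Measure steady-state activity (%ON) of every species
#'
#' Discards `burn_in` steps, then measures the ON-fraction of each species
#' over the next `measure_steps` steps. When the environment is deterministic
#' (all levels exactly 0 or 100) and the initial state is fixed, the dynamics
#' settle in an attractor and the exact attractor %ON is returned via
#' [find_attractor()] instead of a sampled estimate.
#'
#' @inheritParams simulate_model
#' @param burn_in Steps discarded before measuring (default 1000).
#' @param measure_steps Steps measured (default 2000).
#' @return A tibble with columns `species`, `kind` and `pct_on`.
#' @examples
#' m <- boolean_model("chain", rules = list(Z = "X"))
#' steady_pct_on(m, env_levels(X = 40), seed = 1)
#' @export
steady_pct_on <- function(model, env, burn_in = 1000L, measure_steps = 2000L,
                          seed = NULL, mutations = list(),
                          initial_state = "all_off") {
  stop_if_invalid(model)
  burn_in <- as.integer(burn_in)
  measure_steps <- as.integer(measure_steps)
  stopifnot(burn_in >= 0L, measure_steps >= 1L)
  mutations <- check_mutations(model, mutations)
  lv <- check_environment(model, env)
  deterministic <- all(lv %in% c(0, 100)) &&
    !(is.character(initial_state) && identical(initial_state, "random"))
  if (deterministic) {
    att <- find_attractor(model, env, mutations = mutations,
                          initial_state = initial_state)
    return(att$pct_on)
  }
  if (!is.null(seed)) set.seed(seed)
  init <- resolve_initial(model, initial_state, mutations)
  mu <- mutation_idx(model, mutations)
  cm <- get_compiled(model)
  counts <- cpp_steady_counts(cm, lv / 100, mu$idx, mu$val, unname(init),
                              burn_in, measure_steps)
  tibble::tibble(species = model$species$name, kind = model$species$kind,
                 pct_on = 100 * counts / measure_steps)
}

#' Write a trajectory to CSV
#'
#' One row per step, one column per species (header names the species), for
#' either the sliding-window %ON series or the raw Boolean states.
#'
#' @param trajectory A `trajectory` object.
#' @param path Output file path.
#' @param what `"pct_on"` (default) or `"states"`.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, what = c("pct_on", "states")) {
  stopifnot(inherits(trajectory, "trajectory"))
  what <- match.arg(what)
  readr::write_csv(trajectory[[what]], path)
  invisible(path)
}
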