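#' Define per-species activity ranges for a dynamic-analysis experiment
#'
#' Each external species gets an activity range in %ON; during an experiment
#' a level is drawn independently and uniformly within the range for every
#' simulation, emulating a batch of laboratory experiments run under varying
#' extracellular conditions. A degenerate range (`lo == hi`, or a single
#' number) fixes the level.
#'
#' @param ... Named ranges: a length-2 numeric `c(lo, hi)` or a single number.
#' @return A tibble of class `env_ranges` with columns `species`, `lo`, `hi`.
#' @examples
#' env_ranges(EGF = c(0, 100), ECM = c(56, 100), Stress = 0)
#' @export
env_ranges <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is.null(names(xs[[1L]]))) {
    xs <- xs[[1L]]
  }
  if (length(xs) == 0L) {
    out <- tibble::tibble(species = character(), lo = numeric(), hi = numeric())
    class(out) <- c("env_ranges", class(out))
    return(out)
  }
  if (is.null(names(xs)) || any(!nzchar(names(xs)))) {
    stop("every range must be named after an external species", call. = FALSE)
  }
  lo <- vapply(xs, function(r) as.numeric(r)[1L], numeric(1))
  hi <- vapply(xs, function(r) {
    r <- as.numeric(r)
    if (length(r) == 1L) r else r[2L]
  }, numeric(1))
  if (any(is.na(lo) | is.na(hi) | lo < 0 | hi > 100 | lo > hi)) {
    stop("ranges must satisfy 0 <= lo <= hi <= 100", call. = FALSE)
  }
  out <- tibble::tibble(species = names(xs), lo = unname(lo), hi = unname(hi))
  class(out) <- c("env_ranges", class(out))
  out
}

check_ranges <- function(model, ranges) {
  stopifnot(inherits(ranges, "env_ranges"))
  ext <- external_species(model)
  missing <- setdiff(ext, ranges$species)
  if (length(missing)) {
    stop("no activity range for external species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(ranges$species, ext)
  if (length(extra)) {
    stop("range names unknown external species: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ranges[match(ext, ranges$species), ]
}

#' Sample one environment within configured ranges
#'
#' Draws each species' activity level independently and uniformly (continuous)
#' on its `[lo, hi]` range.
#'
#' @param ranges An [env_ranges()] table.
#' @return An [env_levels()] environment.
#' @export
sample_environment <- function(ranges) {
  stopifnot(inherits(ranges, "env_ranges"))
  lv <- stats::runif(nrow(ranges), ranges$lo, ranges$hi)
  env_levels(stats::setNames(lv, ranges$species))
}

# deterministic per-simulation seed: mixing keeps earlier records stable when
# n_simulations grows; stays below 2^31 (computed exactly in doubles)
derive_seed <- function(seed, i) {
  h <- ((seed %% 2147483647) * 48271 + i * 1103515245) %% 2147483647
  as.integer(h) + 1L
}

#' Run a dynamic-analysis experiment
#'
#' Performs `n_simulations` independent simulations. For each, an activity
#' level is sampled for every external species within its configured range,
#' the model is run to its steady behaviour (see [steady_pct_on()]), and the
#' sampled environment plus the measured steady %ON of every species are
#' recorded — one row per simulation, the raw data behind dose-response
#' curves. Per-simulation seeds are derived deterministically from the
#' experiment seed and the simulation index, so the whole table reproduces
#' from `seed` and earlier records do not change when `n_simulations` grows.
#'
#' @param model A valid `boolean_model`.
#' @param ranges An [env_ranges()] table covering every external species.
#' @param n_simulations Number of simulated experiments (default 100).
#' @param seed Integer experiment seed (default 1).
#' @param mutations List of [mutation()] objects applied in every simulation.
#' @param burn_in,measure_steps Passed to [steady_pct_on()].
#' @param initial_state Initial-state policy per simulation (default
#'   `"all_off"`; `"random"` re-randomizes internal states each simulation).
#' @return A tibble of class `experiment_result`: column `sim`, then one
#'   `env_<species>` column per external species (sampled levels), then one
#'   `pct_<species>` column per species (steady %ON). The ranges and
#'   configuration are attached as attributes.
#' @examples
#' m <- boolean_model("chain", rules = list(Z = "X"))
#' ex <- run_experiment(m, env_ranges(X = c(0, 100)), n_simulations = 20,
#'                      seed = 1, burn_in = 100, measure_steps = 200)
#' dose_response(ex, "X", "Z", n_bins = 5)
#' @export
run_experiment <- function(model, ranges, n_simulations = 100L, seed = 1L,
                           mutations = list(), burn_in = 1000L,
                           measure_steps = 2000L, initial_state = "all_off") {
  stop_if_invalid(model)
  n_simulations <- as.integer(n_simulations)
  stopifnot(n_simulations >= 1L)
  mutations <- check_mutations(model, mutations)
  ranges <- check_ranges(model, ranges)
  seed <- as.integer(seed)
  sp <- model$species$name
  ext <- external_species(model)
  rows <- vector("list", n_simulations)
  for (i in seq_len(n_simulations)) {
    set.seed(derive_seed(seed, i))
    env <- sample_environment(ranges)
    st <- steady_pct_on(model, env, burn_in = burn_in,
                        measure_steps = measure_steps, seed = NULL,
                        mutations = mutations, initial_state = initial_state)
    rec <- c(list(sim = i),
             stats::setNames(as.list(unclass(env)), paste0("env_", ext)),
             stats::setNames(as.list(st$pct_on), paste0("pct_", sp)))
    rows[[i]] <- tibble::as_tibble(rec)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ranges") <- ranges
  attr(out, "model_name") <- model$name
  attr(out, "species") <- sp
  attr(out, "external") <- ext
  attr(out, "config") <- list(n_simulations = n_simulations, seed = seed,
                              burn_in = burn_in, measure_steps = measure_steps,
                              initial_state = initial_state,
                              mutations = mutations)
  class(out) <- c("experiment_result", class(out))
  out
}

#' @export
glance.experiment_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(model = attr(x, "model_name"),
                 n_simulations = nrow(x),
                 n_external = length(attr(x, "external")),
                 n_species = length(attr(x, "species")),
                 seed = cfg$seed, burn_in = cfg$burn_in,
                 measure_steps = cfg$measure_steps)
}

#' Derive a dose-response curve from stored experiment data
#'
#' A pure function of an [run_experiment()] result: it never re-simulates, so
#' any number of input/output pairs can be analyzed from one experiment. The
#' raw points pair each simulation's sampled input level with the measured
#' steady %ON of the output species; the curve bins the input's configured
#' range into `n_bins` equal-width bins and reports per-bin mean output and
#' count (empty bins keep `NA` means, visible rather than silently zero).
#'
#' @param result An `experiment_result`.
#' @param input_species An external species of the experiment's model.
#' @param output_species Any species of the model.
#' @param n_bins Number of equal-width bins (default 10).
#' @return An object of class `dose_response` with tibbles `raw`
#'   (`sim`, `input_level`, `output_pct`) and `binned`
#'   (`bin`, `lo`, `hi`, `midpoint`, `mean_pct`, `n`).
#' @export
dose_response <- function(result, input_species, output_species, n_bins = 10L) {
  stopifnot(inherits(result, "experiment_result"))
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  ext <- attr(result, "external")
  sp <- attr(result, "species")
  if (!input_species %in% ext) {
    stop("input species '", input_species, "' is not an external species",
         call. = FALSE)
  }
  if (!output_species %in% sp) {
    stop("unknown output species '", output_species, "'", call. = FALSE)
  }
  raw <- tibble::tibble(
    sim = result$sim,
    input_level = result[[paste0("env_", input_species)]],
    output_pct = result[[paste0("pct_", output_species)]]
  )
  ranges <- attr(result, "ranges")
  if (!is.null(ranges) && input_species %in% ranges$species) {
    r <- ranges[ranges$species == input_species, ]
    lo <- r$lo; hi <- r$hi
  } else {
    lo <- min(raw$input_level); hi <- max(raw$input_level)
  }
  if (hi <= lo) {
    warning("input species '", input_species,
            "' has a degenerate range; returning a single bin", call. = FALSE)
    n_bins <- 1L
    hi <- lo
  }
  if (n_bins == 1L || hi == lo) {
    binned <- tibble::tibble(bin = 1L, lo = lo, hi = max(hi, lo),
                             midpoint = (lo + max(hi, lo)) / 2,
                             mean_pct = mean(raw$output_pct),
                             n = nrow(raw))
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    bin <- pmin(pmax(findInterval(raw$input_level, edges,
                                  rightmost.closed = TRUE), 1L), n_bins)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(bin = bin, y = raw$output_pct), .data$bin),
      mean_pct = mean(.data$y), n = dplyr::n(), .groups = "drop")
    binned <- tibble::tibble(bin = seq_len(n_bins),
                             lo = edges[-(n_bins + 1L)], hi = edges[-1L])
    binned$midpoint <- (binned$lo + binned$hi) / 2
    binned <- dplyr::left_join(binned, agg, by = "bin")
    binned$n[is.na(binned$n)] <- 0L
  }
  structure(list(input_species = input_species,
                 output_species = output_species,
                 raw = raw, binned = binned,
                 model_name = attr(result, "model_name")),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("<dose_response> ", x$model_name, ": ", x$input_species, " -> ",
      x$output_species, " (", nrow(x$raw), " simulations, ",
      nrow(x$binned), " bins)\n", sep = "")
  print(x$binned)
  invisible(x)
}

#' @export
tidy.dose_response <- function(x, ...) x$binned

#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object$raw,
                  ggplot2::aes(x = .data$input_level, y = .data$output_pct)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = dplyr::filter(object$binned, !is.na(.data$mean_pct)),
                       ggplot2::aes(x = .data$midpoint, y = .data$mean_pct),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = paste0(object$input_species, " activity (%ON)"),
                  y = paste0(object$output_species, " steady activity (%ON)"),
                  title = paste0(object$model_name, ": ", object$input_species,
                                 " → ", object$output_species)) +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Write experiment results or dose-response curves to CSV
#'
#' `write_experiment_csv()` writes one row per simulation (environment columns
#' prefixed `env_`, steady %ON columns prefixed `pct_`);
#' `read_experiment_csv()` reconstructs an `experiment_result` from such a
#' file (configured ranges are inferred from the observed levels).
#' `write_dose_response_csv()` writes the binned curve and, optionally, the
#' raw points alongside.
#'
#' @param result An `experiment_result`.
#' @param path Output (or input) CSV path.
#' @return The path (readers return the reconstructed object), invisibly for
#'   writers.
#' @export
write_experiment_csv <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  readr::write_csv(tibble::as_tibble(result), path)
  invisible(path)
}

#' @rdname write_experiment_csv
#' @export
read_experiment_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  env_cols <- grep("^env_", names(d), value = TRUE)
  pct_cols <- grep("^pct_", names(d), value = TRUE)
  if (!"sim" %in% names(d) || length(pct_cols) == 0L) {
    stop("not an experiment CSV: expected 'sim' and pct_* columns", call. = FALSE)
  }
  ext <- sub("^env_", "", env_cols)
  sp <- sub("^pct_", "", pct_cols)
  rng <- env_ranges(stats::setNames(
    lapply(env_cols, function(cn) c(min(d[[cn]]), max(d[[cn]]))), ext))
  attr(d, "ranges") <- rng
  attr(d, "model_name") <- "imported"
  attr(d, "species") <- sp
  attr(d, "external") <- ext
  class(d) <- c("experiment_result", class(d))
  d
}

#' @rdname write_experiment_csv
#' @param curve A `dose_response` object.
#' @param raw_path Optional path for the raw points.
#' @export
write_dose_response_csv <- function(curve, path, raw_path = NULL) {
  stopifnot(inherits(curve, "dose_response"))
  readr::write_csv(curve$binned, path)
  if (!is.null(raw_path)) readr::write_csv(curve$raw, raw_path)
  invisible(path)
}
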