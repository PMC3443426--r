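#' Construct a qualitative Boolean network model
#'
#' A model is a set of named species, each either *external* (an extracellular
#' input driven by a set activity level, with no rule) or *internal* (governed
#' by exactly one regulatory rule). Rules may be given as [biologic_rule()]
#' objects, [truthfn_rule()] objects, `boolexpr` ASTs, or strings in the
#' flat-text expression dialect (`"X AND NOT Y"`); strings are parsed on
#' construction.
#'
#' Internal species are the names of `rules`; any species referenced by a rule
#' but not itself regulated is external, as are any extra names in `external`.
#' Species order (externals first, then internals) fixes the column order of
#' every state vector and the per-step random draw order, so it is part of the
#' model's reproducibility contract.
#'
#' @param name Model name.
#' @param rules Named list of rules, one per internal species. The element
#'   name is the target; for rule objects carrying their own target the two
#'   must agree (unnamed elements take the rule's target).
#' @param external Character vector of additional external species (optional;
#'   referenced-but-unregulated species are external automatically).
#' @return An object of class `boolean_model`.
#' @examples
#' m <- boolean_model("toy", rules = list(Z = "X AND Y"))
#' species(m)
#' @export
boolean_model <- function(name, rules, external = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.list(rules))
  nm <- names(rules)
  if (is.null(nm)) nm <- rep("", length(rules))
  rules <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    if (is.character(r)) r <- parse_flat_expression(r)
    if (inherits(r, c("biologic_rule", "truthfn_rule"))) {
      if (nzchar(nm[i]) && !identical(nm[i], r$target)) {
        stop("rule list name '", nm[i], "' disagrees with rule target '",
             r$target, "'", call. = FALSE)
      }
      nm[i] <<- r$target
    }
    if (!inherits(r, c("biologic_rule", "truthfn_rule", "boolexpr"))) {
      stop("rules must be biologic_rule, truthfn_rule, boolexpr or character",
           call. = FALSE)
    }
    r
  })
  if (any(!nzchar(nm))) stop("every rule needs a target name", call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate rule target: ", paste(unique(nm[duplicated(nm)]), collapse = ", "),
         call. = FALSE)
  }
  names(rules) <- nm
  referenced <- unique(unlist(lapply(rules, rule_deps)))
  ext <- unique(c(as.character(external), setdiff(referenced, nm)))
  ext <- setdiff(ext, nm)
  sp <- tibble::tibble(
    name = c(ext, nm),
    kind = c(rep("external", length(ext)), rep("internal", length(nm)))
  )
  if (any(!nzchar(sp$name))) stop("species names must be non-empty", call. = FALSE)
  structure(list(name = name, species = sp, rules = rules),
            class = "boolean_model")
}

#' Species table of a model
#'
#' @param model A `boolean_model`.
#' @return A tibble with columns `name` and `kind` (`external`/`internal`),
#'   in model declaration order.
#' @export
species <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  model$species
}

external_species <- function(model) {
  model$species$name[model$species$kind == "external"]
}

internal_species <- function(model) {
  model$species$name[model$species$kind == "internal"]
}

#' @export
print.boolean_model <- function(x, ...) {
  cat("<boolean_model> ", x$name, ": ", nrow(x$species), " species (",
      sum(x$species$kind == "external"), " external, ",
      sum(x$species$kind == "internal"), " internal)\n", sep = "")
  for (tgt in names(x$rules)) {
    r <- x$rules[[tgt]]
    txt <- if (inherits(r, "truthfn_rule")) {
      paste0("f(", paste(r$regulators, collapse = ", "), ") [truth table]")
    } else {
      format(rule_to_expr(r))
    }
    cat("  ", tgt, " = ", txt, "\n", sep = "")
  }
  invisible(x)
}

#' Validate a model
#'
#' Checks the structural invariants: every rule reference resolves to a model
#' species, every internal species has a rule, no internal species lacks a
#' positive regulator, and reports (as warnings, not errors) self-regulating
#' species and external species no rule uses.
#'
#' @param model A `boolean_model`.
#' @return A tibble with columns `severity` (`error`/`warning`), `type`,
#'   `species` and `message`; zero error rows iff the model invariants hold.
#'   Use [is_valid()] for a logical answer.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  rows <- list()
  add <- function(severity, type, sp, msg) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      severity = severity, type = type, species = sp, message = msg)
  }
  all_names <- model$species$name
  if (anyDuplicated(all_names)) {
    for (d in unique(all_names[duplicated(all_names)])) {
      add("error", "duplicate_species", d, paste0("species '", d, "' declared more than once"))
    }
  }
  for (tgt in internal_species(model)) {
    if (is.null(model$rules[[tgt]])) {
      add("error", "missing_rule", tgt,
          paste0("internal species '", tgt, "' has no regulatory rule"))
    }
  }
  for (tgt in names(model$rules)) {
    r <- model$rules[[tgt]]
    deps <- rule_deps(r)
    for (d in setdiff(deps, all_names)) {
      add("error", "unresolved_reference", tgt,
          paste0("rule for '", tgt, "' references unknown species '", d, "'"))
    }
    if (inherits(r, "biologic_rule") && length(r$activators) == 0L) {
      add("error", "unregulated_internal", tgt,
          paste0("internal species '", tgt, "' has no activator clause"))
    }
    if (tgt %in% deps) {
      add("warning", "self_loop", tgt,
          paste0("species '", tgt, "' regulates itself"))
    }
  }
  used <- unique(unlist(lapply(model$rules, rule_deps)))
  for (e in setdiff(external_species(model), used)) {
    add("warning", "unused_external", e,
        paste0("external species '", e, "' is not used by any rule"))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(severity = character(), type = character(),
                   species = character(), message = character())
  }
  class(out) <- c("validation_report", class(out))
  out
}

#' @rdname validate_model
#' @param report A validation report from `validate_model()` (or a model,
#'   which is validated first).
#' @return `is_valid()`: `TRUE` when the report contains no error rows.
#' @export
is_valid <- function(report) {
  if (inherits(report, "boolean_model")) report <- validate_model(report)
  !any(report$severity == "error")
}

#' Declare a gain- or loss-of-function mutation
#'
#' A mutation clamps one species permanently ON (gain-of-function,
#' constitutive activation) or OFF (loss-of-function, knockout). The clamp is
#' applied at every simulation step after rule evaluation and external draws,
#' and to the initial state, so it dominates both rules and environment
#' levels.
#'
#' @param species Species name.
#' @param state `"ON"` or `"OFF"` (case-insensitive).
#' @return An object of class `mutation`.
#' @examples
#' mutation("Akt", "OFF")
#' @export
mutation <- function(species, state) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  state <- toupper(as.character(state))
  if (!state %in% c("ON", "OFF")) stop("state must be 'ON' or 'OFF'", call. = FALSE)
  structure(list(species = species, state = state), class = "mutation")
}

#' @export
print.mutation <- function(x, ...) {
  cat("<mutation> ", x$species, " clamped ", x$state, "\n", sep = "")
  invisible(x)
}

# normalize a mutations argument to a validated list of mutation objects
check_mutations <- function(model, mutations) {
  if (inherits(mutations, "mutation")) mutations <- list(mutations)
  stopifnot(is.list(mutations))
  if (length(mutations) == 0L) return(list())
  for (m in mutations) {
    if (!inherits(m, "mutation")) stop("mutations must be mutation() objects", call. = FALSE)
    if (!m$species %in% model$species$name) {
      stop("mutation targets unknown species '", m$species, "'", call. = FALSE)
    }
  }
  sp <- vapply(mutations, `[[`, character(1), "species")
  if (anyDuplicated(sp)) {
    stop("at most one mutation per species (duplicate: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "), ")", call. = FALSE)
  }
  mutations
}

stop_if_invalid <- function(model) {
  if (isTRUE(attr(model, "validated"))) return(invisible(model))
  rep <- validate_model(model)
  if (any(rep$severity == "error")) {
    stop("model '", model$name, "' fails validation:\n  ",
         paste(rep$message[rep$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  invisible(model)
}
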