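#' Read / write bio-logic model definition files
#'
#' A human-editable YAML document that preserves the qualitative clause
#' structure of a model's regulation (which the flat-text expression format
#' flattens away). Layout:
#'
#' ```yaml
#' name: toy
#' species:
#'   - {name: X, kind: external}
#'   - {name: Z, kind: internal}
#' rules:
#'   Z:
#'     activators: [[X, Y], [W]]   # clauses: (X AND Y) OR W
#'     inhibitors: [[I]]           # dominant: forces Z OFF
#' ```
#'
#' A rule may instead carry `expression: "X AND NOT Y"` (flat-text dialect)
#' as an escape hatch for logic the clause grammar cannot express.
#'
#' @param path File path.
#' @param model A `boolean_model`.
#' @return `read_biologic_yaml()`: a `boolean_model`;
#'   `write_biologic_yaml()`: the path, invisibly.
#' @export
read_biologic_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$rules) || length(doc$rules) == 0L) {
    stop("bio-logic file has no rules", call. = FALSE)
  }
  rules <- lapply(names(doc$rules), function(tgt) {
    r <- doc$rules[[tgt]]
    if (!is.null(r$expression)) {
      return(parse_flat_expression(r$expression))
    }
    as_clauses <- function(x) {
      if (is.null(x)) return(list())
      if (!is.list(x)) x <- list(x)
      lapply(x, as.character)
    }
    biologic_rule(tgt, as_clauses(r$activators), as_clauses(r$inhibitors))
  })
  names(rules) <- names(doc$rules)
  ext <- character()
  if (!is.null(doc$species)) {
    kinds <- vapply(doc$species, function(s) as.character(s$kind %||% "internal"), character(1))
    nms <- vapply(doc$species, function(s) as.character(s$name), character(1))
    ext <- nms[kinds == "external"]
    declared_internal <- nms[kinds == "internal"]
    undeclared <- setdiff(declared_internal, names(rules))
    if (length(undeclared)) {
      stop("internal species without a rule: ", paste(undeclared, collapse = ", "),
           call. = FALSE)
    }
  }
  boolean_model(doc$name %||% "biologic_model", rules, external = ext)
}

#' @rdname read_biologic_yaml
#' @export
write_biologic_yaml <- function(model, path) {
  stopifnot(inherits(model, "boolean_model"))
  rules <- lapply(names(model$rules), function(tgt) {
    r <- model$rules[[tgt]]
    if (inherits(r, "biologic_rule")) {
      out <- list(activators = lapply(r$activators, as.list))
      if (length(r$inhibitors)) out$inhibitors <- lapply(r$inhibitors, as.list)
      out
    } else {
      list(expression = format(rule_to_expr(r)))
    }
  })
  names(rules) <- names(model$rules)
  doc <- list(
    name = model$name,
    species = lapply(seq_len(nrow(model$species)), function(i) {
      list(name = model$species$name[i], kind = model$species$kind[i])
    }),
    rules = rules
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
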