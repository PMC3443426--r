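# SBML Level 3 + qualitative-models package (Boolean, maxLevel 1) exchange.
# Expressions are encoded in the function term's MathML with <eq>/<ci>/<cn>
# literals; the default term carries resultLevel 0 (OFF), the single function
# term resultLevel 1 (ON).

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# read a qual-package attribute whether it is namespaced or plain
qattr <- function(x, name, ns) {
  a <- xml2::xml_attr(x, paste0("qual:", name), ns = ns)
  ifelse(is.na(a), xml2::xml_attr(x, name), a)
}

# deterministic SBML id sanitization: SBML SIds match [A-Za-z_][A-Za-z0-9_]*
sanitize_sbml_ids <- function(names) {
  ids <- ifelse(grepl("^[A-Za-z_]", names), names, paste0("s_", names))
  ids <- gsub("[^A-Za-z0-9_]", "_", ids)
  while (anyDuplicated(ids)) {
    d <- duplicated(ids)
    ids[d] <- paste0(ids[d], "_")
  }
  stats::setNames(ids, names)
}

#' Export a model as SBML Level 3 with the qualitative-models package
#'
#' Every species becomes a `qualitativeSpecies` with `maxLevel` 1 (external
#' species are marked constant); every internal species gets one transition
#' whose inputs are the rule's variables and whose function term encodes the
#' Boolean expression as MathML logic (`resultLevel` 1, default term 0).
#' Species names that are not valid SBML identifiers are sanitized
#' deterministically; the original name is preserved in the `qual:name`
#' attribute and an id-mapping table is written alongside the document
#' (`<path>.idmap.tsv`) whenever sanitization changed anything.
#'
#' @param model A valid `boolean_model`.
#' @param path Output file path (`.sbml`/`.xml`). If `NULL`, the `xml2`
#'   document is returned without writing.
#' @return The `xml_document`, invisibly when written to a file.
#' @export
write_sbml_qual <- function(model, path = NULL) {
  stop_if_invalid(model)
  ids <- sanitize_sbml_ids(model$species$name)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:qual" = SBML_QUAL_NS,
    level = "3", version = "1", "qual:required" = "true"
  )
  model_id <- unname(sanitize_sbml_ids(if (nzchar(model$name)) model$name else "model"))
  mdl <- xml2::xml_add_child(doc, "model", id = model_id, name = model$name)
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "default", constant = "true")
  losp <- xml2::xml_add_child(mdl, "qual:listOfQualitativeSpecies")
  for (i in seq_len(nrow(model$species))) {
    nm <- model$species$name[i]
    xml2::xml_add_child(
      losp, "qual:qualitativeSpecies",
      "qual:id" = unname(ids[nm]), "qual:name" = nm,
      "qual:compartment" = "default",
      "qual:constant" = if (model$species$kind[i] == "external") "true" else "false",
      "qual:maxLevel" = "1", "qual:initialLevel" = "0"
    )
  }
  lot <- xml2::xml_add_child(mdl, "qual:listOfTransitions")
  for (tgt in names(model$rules)) {
    expr <- rule_to_expr(model$rules[[tgt]])
    tr <- xml2::xml_add_child(lot, "qual:transition",
                              "qual:id" = paste0("tr_", unname(ids[tgt])))
    vars <- expr_vars(expr)
    if (length(vars)) {
      loi <- xml2::xml_add_child(tr, "qual:listOfInputs")
      for (v in vars) {
        xml2::xml_add_child(
          loi, "qual:input",
          "qual:id" = paste0("in_", unname(ids[tgt]), "_", unname(ids[v])),
          "qual:qualitativeSpecies" = unname(ids[v]),
          "qual:transitionEffect" = "none"
        )
      }
    }
    loo <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(loo, "qual:output",
                        "qual:qualitativeSpecies" = unname(ids[tgt]),
                        "qual:transitionEffect" = "assignmentLevel")
    loft <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    ft <- xml2::xml_add_child(loft, "qual:functionTerm", "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = MATHML_NS)
    add_mathml(math, expr, ids)
    xml2::xml_add_child(loft, "qual:defaultTerm", "qual:resultLevel" = "0")
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    if (any(ids != names(ids))) {
      readr::write_tsv(tibble::tibble(species = names(ids), sbml_id = unname(ids)),
                       paste0(path, ".idmap.tsv"))
    }
    return(invisible(doc))
  }
  doc
}

add_mathml <- function(parent, expr, ids) {
  switch(expr$kind,
    const = xml2::xml_add_child(parent, if (expr$value) "true" else "false"),
    var = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "eq")
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci, unname(ids[expr$name]))
      cn <- xml2::xml_add_child(ap, "cn", type = "integer")
      xml2::xml_set_text(cn, "1")
    },
    not = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "not")
      add_mathml(ap, expr$child, ids)
    },
    and = ,
    or = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, expr$kind)
      for (c in expr$children) add_mathml(ap, c, ids)
    }
  )
  invisible(parent)
}

#' Import an SBML Level 3 qualitative-models document
#'
#' Transitions become rules of their output species; qualitative species
#' without a transition become external. Only Boolean documents are
#' supported: any `qualitativeSpecies` with `maxLevel` greater than 1 is
#' rejected. Original names stored in `qual:name` are restored when present.
#'
#' @param path Path to an SBML L3 qual file (or an `xml2` document).
#' @return A `boolean_model`.
#' @export
read_sbml_qual <- function(path) {
  # re-parse in-memory documents so namespace bindings are normalized
  doc <- if (inherits(path, "xml_document")) xml2::read_xml(as.character(path))
         else xml2::read_xml(path)
  ns <- c(core = SBML_CORE_NS, qual = SBML_QUAL_NS, m = MATHML_NS)
  qs <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  if (length(qs) == 0L) stop("no qualitativeSpecies found: not an SBML qual document", call. = FALSE)
  sid <- qattr(qs, "id", ns)
  snm <- qattr(qs, "name", ns)
  maxlev <- qattr(qs, "maxLevel", ns)
  maxlev <- ifelse(is.na(maxlev), "1", maxlev)
  if (any(as.integer(maxlev) > 1L)) {
    bad <- sid[as.integer(maxlev) > 1L]
    stop("unsupported feature: multi-level qualitativeSpecies (maxLevel > 1): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  display <- ifelse(is.na(snm) | !nzchar(snm), sid, snm)
  names(display) <- sid
  trs <- xml2::xml_find_all(doc, ".//qual:transition", ns)
  rules <- list()
  for (tr in trs) {
    out <- xml2::xml_find_first(tr, ".//qual:output", ns)
    if (inherits(out, "xml_missing")) stop("transition without output", call. = FALSE)
    tgt_id <- qattr(out, "qualitativeSpecies", ns)
    tgt <- unname(display[tgt_id])
    if (is.na(tgt)) stop("transition output references unknown species '", tgt_id, "'", call. = FALSE)
    ft <- xml2::xml_find_first(
      tr, ".//qual:functionTerm[@qual:resultLevel='1']", ns)
    if (inherits(ft, "xml_missing")) {
      # no ON term: species is constantly OFF
      rules[[tgt]] <- bx_const(FALSE)
      next
    }
    math <- xml2::xml_find_first(ft, "./m:math", ns)
    if (inherits(math, "xml_missing")) math <- xml2::xml_find_first(ft, "./math", ns)
    if (inherits(math, "xml_missing")) stop("functionTerm without MathML", call. = FALSE)
    kids <- xml2::xml_children(math)
    if (length(kids) != 1L) stop("malformed MathML: expected one root element", call. = FALSE)
    rules[[tgt]] <- parse_mathml(kids[[1L]], display)
  }
  mdl <- xml2::xml_find_first(doc, ".//core:model", ns)
  nm <- if (!inherits(mdl, "xml_missing")) xml2::xml_attr(mdl, "name") else NA
  if (is.na(nm) || !nzchar(nm)) nm <- "sbml_model"
  boolean_model(nm, rules, external = setdiff(unname(display), names(rules)))
}

parse_mathml <- function(node, display) {
  nm <- xml2::xml_name(node)
  if (nm == "true") return(bx_const(TRUE))
  if (nm == "false") return(bx_const(FALSE))
  if (nm == "ci") {
    id <- trimws(xml2::xml_text(node))
    v <- display[id]
    if (is.na(v)) stop("MathML references unknown species '", id, "'", call. = FALSE)
    return(bx_var(unname(v)))
  }
  if (nm != "apply") stop("malformed MathML: unexpected <", nm, ">", call. = FALSE)
  kids <- xml2::xml_children(node)
  if (length(kids) < 2L) stop("malformed MathML: empty <apply>", call. = FALSE)
  op <- xml2::xml_name(kids[[1L]])
  argn <- kids[-1L]
  if (op %in% c("eq", "geq")) {
    ci <- argn[[which(xml2::xml_name(argn) == "ci")[1L]]]
    cn <- argn[[which(xml2::xml_name(argn) == "cn")[1L]]]
    lev <- as.numeric(trimws(xml2::xml_text(cn)))
    v <- parse_mathml(ci, display)
    if (lev >= 1) return(v)
    # eq with 0 means "species is OFF"
    return(if (op == "eq") bx_not(v) else bx_const(TRUE))
  }
  args <- lapply(seq_along(argn), function(i) parse_mathml(argn[[i]], display))
  switch(op,
    not = bx_not(args[[1L]]),
    and = if (length(args) == 1L) args[[1L]] else bx_and(args),
    or = if (length(args) == 1L) args[[1L]] else bx_or(args),
    stop("malformed MathML: unsupported operator <", op, ">", call. = FALSE)
  )
}

#' Structural conformance check for SBML qual documents
#'
#' Verifies the document shape this package relies on: SBML root in the Level
#' 3 core namespace with the qual package namespace declared, qualitative
#' species with ids and Boolean `maxLevel`, transitions carrying exactly one
#' output, a default term, one ON function term with well-formed MathML
#' restricted to the logical subset, and input declarations consistent with
#' the variables used in each function term.
#'
#' @param path Path to an SBML file (or `xml2` document).
#' @return A tibble of issues with columns `where` and `message`; zero rows
#'   means the document passed every check.
#' @export
check_sbml_qual <- function(path) {
  doc <- if (inherits(path, "xml_document")) xml2::read_xml(as.character(path))
         else xml2::read_xml(path)
  issues <- list()
  add <- function(where, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(where = where, message = msg)
  }
  root_ns <- xml2::xml_ns(doc)
  if (!SBML_CORE_NS %in% unlist(root_ns)) add("root", "SBML L3v1 core namespace missing")
  if (!SBML_QUAL_NS %in% unlist(root_ns)) add("root", "qual package namespace missing")
  if (xml2::xml_name(doc) != "sbml") add("root", "root element is not <sbml>")
  ns <- c(core = SBML_CORE_NS, qual = SBML_QUAL_NS, m = MATHML_NS)
  qs <- xml2::xml_find_all(doc, ".//qual:qualitativeSpecies", ns)
  sid <- qattr(qs, "id", ns)
  if (anyNA(sid)) add("qualitativeSpecies", "species without qual:id")
  if (anyDuplicated(stats::na.omit(sid))) add("qualitativeSpecies", "duplicate qual:id")
  bad_id <- stats::na.omit(sid)[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", stats::na.omit(sid))]
  for (b in bad_id) add("qualitativeSpecies", paste0("invalid SBML id '", b, "'"))
  ml <- qattr(qs, "maxLevel", ns)
  if (any(!is.na(ml) & as.integer(ml) > 1L)) {
    add("qualitativeSpecies", "maxLevel > 1 present (not Boolean)")
  }
  for (tr in xml2::xml_find_all(doc, ".//qual:transition", ns)) {
    tid <- qattr(tr, "id", ns)
    where <- paste0("transition ", if (is.na(tid)) "<anonymous>" else tid)
    outs <- xml2::xml_find_all(tr, ".//qual:output", ns)
    if (length(outs) != 1L) add(where, "expected exactly one output")
    for (o in outs) {
      osp <- qattr(o, "qualitativeSpecies", ns)
      if (is.na(osp) || !osp %in% sid) add(where, "output references unknown species")
    }
    if (length(xml2::xml_find_all(tr, ".//qual:defaultTerm", ns)) != 1L) {
      add(where, "expected exactly one defaultTerm")
    }
    fts <- xml2::xml_find_all(tr, ".//qual:functionTerm", ns)
    if (length(fts) != 1L) add(where, "expected exactly one functionTerm")
    ins <- qattr(xml2::xml_find_all(tr, ".//qual:input", ns),
                  "qualitativeSpecies", ns)
    for (ft in fts) {
      math <- xml2::xml_find_first(ft, "./m:math", ns)
      if (inherits(math, "xml_missing")) {
        add(where, "functionTerm without MathML <math>")
        next
      }
      cis <- trimws(xml2::xml_text(xml2::xml_find_all(math, ".//m:ci", ns)))
      for (v in setdiff(cis, sid)) add(where, paste0("MathML uses undeclared species '", v, "'"))
      for (v in setdiff(cis, ins)) add(where, paste0("MathML uses species '", v, "' not listed as input"))
      ops <- xml2::xml_name(xml2::xml_children(xml2::xml_find_all(math, ".//m:apply", ns)))
      bad_ops <- setdiff(unique(ops), c("and", "or", "not", "eq", "geq", "ci", "cn", "apply", "true", "false"))
      for (b in bad_ops) add(where, paste0("unsupported MathML operator <", b, ">"))
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(where = character(), message = character())
  }
}
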