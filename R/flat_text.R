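# Flat-text model dialect: one rule per line, "<target> = <expression>";
# operators AND, OR, NOT (case-insensitive), parentheses; identifiers
# [A-Za-z0-9_]+; lines starting with "#" are comments; species never
# appearing as a target are external.

FLAT_KEYWORDS <- c("AND", "OR", "NOT", "TRUE", "FALSE")

tokenize_flat <- function(text, line_no = NA_integer_) {
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen"); pos <- pos + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen"); pos <- pos + 1L; next }
    m <- regmatches(substr(text, pos, n),
                    regexpr("^[A-Za-z0-9_]+", substr(text, pos, n)))
    if (length(m) == 1L) {
      up <- toupper(m)
      type <- if (up %in% FLAT_KEYWORDS) tolower(up) else "ident"
      toks[[length(toks) + 1L]] <- list(type = type, value = m)
      pos <- pos + nchar(m)
      next
    }
    stop("syntax error", if (!is.na(line_no)) paste0(" on line ", line_no),
         ": unexpected character '", ch, "'", call. = FALSE)
  }
  toks
}

# recursive descent with precedence NOT > AND > OR
parse_expr_tokens <- function(toks, line_no = NA_integer_) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else "eof"
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  err <- function(msg) {
    stop("syntax error", if (!is.na(line_no)) paste0(" on line ", line_no),
         ": ", msg, call. = FALSE)
  }
  parse_or <- function() {
    parts <- list(parse_and())
    while (peek() == "or") { advance(); parts[[length(parts) + 1L]] <- parse_and() }
    if (length(parts) == 1L) parts[[1L]] else bx_or(parts)
  }
  parse_and <- function() {
    parts <- list(parse_unary())
    while (peek() == "and") { advance(); parts[[length(parts) + 1L]] <- parse_unary() }
    if (length(parts) == 1L) parts[[1L]] else bx_and(parts)
  }
  parse_unary <- function() {
    if (peek() == "not") { advance(); return(bx_not(parse_unary())) }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t == "lparen") {
      advance()
      e <- parse_or()
      if (peek() != "rparen") err("expected ')'")
      advance()
      return(e)
    }
    if (t == "ident") return(bx_var(advance()$value))
    if (t == "true") { advance(); return(bx_const(TRUE)) }
    if (t == "false") { advance(); return(bx_const(FALSE)) }
    err(paste0("unexpected ", if (t == "eof") "end of expression" else paste0("token '", t, "'")))
  }
  e <- parse_or()
  if (peek() != "eof") err("trailing input after expression")
  e
}

#' Parse a Boolean expression in the flat-text dialect
#'
#' Operators `AND`, `OR`, `NOT` (case-insensitive; precedence `NOT` > `AND` >
#' `OR`), parentheses, constants `TRUE`/`FALSE`, identifiers `[A-Za-z0-9_]+`.
#'
#' @param text Expression string.
#' @return A `boolexpr`.
#' @examples
#' parse_flat_expression("(X AND Y) OR NOT I")
#' @export
parse_flat_expression <- function(text) {
  parse_expr_tokens(tokenize_flat(text))
}

#' Read / write models in the flat-text Boolean expression format
#'
#' The flat-text format carries one line per internal species,
#' `"<target> = <expression>"`; lines starting with `#` are comments; species
#' never appearing as a target are external. This is the plain-text exchange
#' form of a model's mathematical expressions: clause structure of bio-logic
#' rules is flattened into the compiled expression (documented as lossy), and
#' truth-table rules are expanded to disjunctive normal form (supported up to
#' 12 regulators).
#'
#' @param text Character scalar (the file contents) or a vector of lines.
#' @param name Model name for the parsed model.
#' @return `parse_flat_text()` / `read_flat_text()`: a `boolean_model`;
#'   `format_flat_text()`: a character scalar; `write_flat_text()`: the path,
#'   invisibly.
#' @examples
#' m <- parse_flat_text("Z = X AND Y")
#' cat(format_flat_text(m))
#' @export
parse_flat_text <- function(text, name = "flat_text_model") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq == -1L) {
      stop("syntax error on line ", i, ": expected '<target> = <expression>'",
           call. = FALSE)
    }
    target <- trimws(substr(ln, 1L, eq - 1L))
    if (!grepl("^[A-Za-z0-9_]+$", target)) {
      stop("syntax error on line ", i, ": invalid target identifier '",
           target, "'", call. = FALSE)
    }
    if (toupper(target) %in% FLAT_KEYWORDS) {
      stop("syntax error on line ", i, ": reserved word '", target,
           "' cannot be a species name", call. = FALSE)
    }
    if (target %in% names(rules)) {
      stop("duplicate target '", target, "' on line ", i, call. = FALSE)
    }
    rhs <- substr(ln, eq + 1L, nchar(ln))
    rules[[target]] <- parse_expr_tokens(tokenize_flat(rhs, i), i)
  }
  if (length(rules) == 0L) stop("no rules found in flat-text input", call. = FALSE)
  boolean_model(name, rules)
}

#' @rdname parse_flat_text
#' @param model A `boolean_model`.
#' @export
format_flat_text <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  hdr <- paste0("# model: ", model$name)
  ext <- external_species(model)
  hdr <- c(hdr, if (length(ext)) paste0("# external: ", paste(ext, collapse = ", ")))
  body <- vapply(names(model$rules), function(tgt) {
    paste0(tgt, " = ", format(rule_to_expr(model$rules[[tgt]])))
  }, character(1))
  paste0(paste(c(hdr, body), collapse = "\n"), "\n")
}

#' @rdname parse_flat_text
#' @param path File path.
#' @export
write_flat_text <- function(model, path) {
  writeLines(sub("\n$", "", format_flat_text(model)), path)
  invisible(path)
}

#' @rdname parse_flat_text
#' @export
read_flat_text <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(name)) {
    m <- grep("^#\\s*model:", lines, value = TRUE)
    name <- if (length(m)) trimws(sub("^#\\s*model:", "", m[1L])) else
      tools::file_path_sans_ext(basename(path))
  }
  parse_flat_text(lines, name = name)
}
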