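## Atom selection mini-language.
##
## Grammar (case-insensitive keywords):
##   expr      := term { "or" term }
##   term      := factor { "and" factor }
##   factor    := "not" factor | "(" expr ")" | primitive
##   primitive := "chain" <labels> | "resid" <ranges> | "resname" <labels>
##              | "name" <labels> | "element" <labels> | "all" | "none"
## <ranges> are integers, "a:b" or "a-b" spans. Multiple labels/ranges after
## one keyword are OR-ed. Selections resolve deterministically to an ordered
## index list in atom order.

SEL_KEYWORDS <- c("chain", "resid", "resname", "name", "element",
                  "and", "or", "not", "all", "none", "(", ")")

tokenize_selection <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0L || !nzchar(toks[1]))
    stop("empty selection expression")
  toks
}

sel_parse <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_values <- function() {
    vals <- character(0)
    while (!is.na(peek()) && !(tolower(peek()) %in% SEL_KEYWORDS)) {
      vals <- c(vals, take())
    }
    if (length(vals) == 0L) stop("selection keyword needs at least one value")
    vals
  }

  parse_primitive <- function() {
    t <- take()
    if (is.na(t)) stop("malformed selection: unexpected end of expression")
    kw <- tolower(t)
    if (kw == "(") {
      node <- parse_expr()
      if (!is_kw(take(), ")")) stop("malformed selection: missing ')'")
      return(node)
    }
    if (kw == "all")  return(list(op = "all"))
    if (kw == "none") return(list(op = "none"))
    if (kw %in% c("chain", "resname", "name", "element"))
      return(list(op = kw, values = parse_values()))
    if (kw == "resid") {
      vals <- parse_values()
      ranges <- lapply(vals, function(v) {
        m <- regmatches(v, regexec("^(-?[0-9]+)[:-]([0-9]+)$", v))[[1]]
        if (length(m) == 3L) as.integer(m[2:3])
        else if (grepl("^-?[0-9]+$", v)) rep(as.integer(v), 2L)
        else stop("malformed resid range: ", v)
      })
      return(list(op = "resid", ranges = ranges))
    }
    stop("malformed selection near '", t, "'")
  }

  parse_factor <- function() {
    if (is_kw(peek(), "not")) { take(); return(list(op = "not",
                                                   a = parse_factor())) }
    parse_primitive()
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_kw(peek(), "and")) { take()
      node <- list(op = "and", a = node, b = parse_factor()) }
    node
  }
  parse_expr <- function() {
    node <- parse_term()
    while (is_kw(peek(), "or")) { take()
      node <- list(op = "or", a = node, b = parse_term()) }
    node
  }

  root <- parse_expr()
  if (!is.na(peek())) stop("malformed selection: trailing tokens from '",
                           peek(), "'")
  root
}

sel_eval <- function(node, atoms) {
  switch(node$op,
    all  = rep(TRUE, nrow(atoms)),
    none = rep(FALSE, nrow(atoms)),
    not  = !sel_eval(node$a, atoms),
    and  = sel_eval(node$a, atoms) & sel_eval(node$b, atoms),
    or   = sel_eval(node$a, atoms) | sel_eval(node$b, atoms),
    chain   = atoms$chain %in% node$values,
    resname = toupper(atoms$resname) %in% toupper(node$values),
    name    = toupper(atoms$name) %in% toupper(node$values),
    element = toupper(atoms$element) %in% toupper(node$values),
    resid   = Reduce(`|`, lapply(node$ranges, function(r)
                atoms$resid >= r[1] & atoms$resid <= r[2])),
    stop("internal: unknown selection node ", node$op)
  )
}

#' Select atoms by expression
#'
#' Resolves a selection expression (see package vignette for the grammar,
#' e.g. `"chain A and resid 6:156 and name CA"`) against a Structure.
#' The result is deterministic, ordered by atom order, and may be empty.
#'
#' @param structure a Structure.
#' @param expr selection expression string, or a logical/integer vector which
#'   is passed through (validated).
#' @return integer vector of atom indices (1-based, ascending).
#' @export
select_atoms <- function(structure, expr) {
  atoms <- structure$atoms
  if (is.logical(expr)) {
    stopifnot(length(expr) == nrow(atoms))
    return(which(expr))
  }
  if (is.numeric(expr)) {
    idx <- as.integer(expr)
    if (any(idx < 1L | idx > nrow(atoms))) stop("selection index out of range")
    return(sort(unique(idx)))
  }
  node <- sel_parse(tokenize_selection(expr))
  which(sel_eval(node, atoms))
}

#' Extract a sub-structure by selection
#'
#' @param structure a Structure.
#' @param expr selection expression or index vector.
#' @return Structure holding the selected atoms, original order kept.
#' @export
subset_structure <- function(structure, expr) {
  idx <- select_atoms(structure, expr)
  if (length(idx) == 0L) stop("selection resolves to zero atoms")
  new_structure(structure$atoms[idx, , drop = FALSE], title = structure$title)
}
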