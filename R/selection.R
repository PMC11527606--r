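#' @section Selection grammar:
#' Selections are produced by a small query language over atom metadata:
#'
#' ```
#' expr    := term ("or" term)*
#' term    := factor ("and" factor)*
#' factor  := "not" factor | "(" expr ")" | key value+
#' key     := "chain" | "resid" | "resname" | "name"
#' value   := word | integer | integer:integer   (resid ranges)
#' ```
#'
#' The nullary keywords `protein`, `ion` and `ligand` match whole atom
#' classes (e.g. `"protein and resid 2:4"`).
#'
#' Several values after one key are OR-ed (`resid 2 3 4`). Ranges apply
#' to `resid` only. Matching is case-insensitive for names.
#' @name poregate-selection
NULL

SELECTION_KEYS <- c("chain", "resid", "resname", "name")

tokenize_selection <- function(expression) {
  pat <- gregexpr("[()]|[^()[:space:]]+", expression)[[1L]]
  if (pat[1L] == -1L) stop("selection parse error at column 1: empty expression")
  tok <- regmatches(expression, gregexpr("[()]|[^()[:space:]]+", expression))[[1L]]
  data.frame(text = tok, col = as.integer(pat), stringsAsFactors = FALSE)
}

#' Select atoms of a topology
#'
#' Evaluates a selection expression (see the package selection grammar)
#' and returns a deterministic, ascending 0-based atom index list. An
#' empty result is allowed but raises a warning.
#'
#' @param topology a `pg_topology`.
#' @param expression selection query text.
#' @param granularity `"atom"` (exactly the matched atoms) or
#'   `"residue"` (expand to all atoms of every touched residue).
#' @return a `pg_selection`.
#' @export
select_atoms <- function(topology, expression, granularity = c("atom", "residue")) {
  granularity <- match.arg(granularity)
  atoms <- topology$atoms
  toks <- tokenize_selection(expression)
  pos <- 1L

  peek <- function() if (pos <= nrow(toks)) toks$text[pos] else NA_character_
  advance <- function() {
    t <- toks[pos, ]
    pos <<- pos + 1L
    t
  }
  perr <- function(msg, col) {
    stop(sprintf("selection parse error at column %d: %s", col, msg))
  }

  parse_values <- function() {
    vals <- character()
    while (!is.na(peek()) &&
           !(tolower(peek()) %in% c("and", "or", "not", "protein", "ion",
                                    "ligand", SELECTION_KEYS)) &&
           !(peek() %in% c("(", ")"))) {
      vals <- c(vals, advance()$text)
    }
    vals
  }

  eval_primary <- function(key, vals, col) {
    if (!length(vals)) perr(sprintf("keyword '%s' needs a value", key), col)
    switch(key,
      chain = atoms$chain %in% vals,
      resname = toupper(atoms$resname) %in% toupper(vals),
      name = toupper(atoms$name) %in% toupper(vals),
      resid = {
        mask <- rep(FALSE, nrow(atoms))
        for (v in vals) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1L]])
            mask <- mask | (atoms$resid >= ab[1L] & atoms$resid <= ab[2L])
          } else if (grepl("^-?[0-9]+$", v)) {
            mask <- mask | atoms$resid == as.integer(v)
          } else perr(sprintf("bad resid value '%s'", v), col)
        }
        mask
      })
  }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) perr("unexpected end of expression", nchar(expression) + 1L)
    if (tolower(t) == "not") {
      advance()
      return(!parse_factor())
    }
    if (t == "(") {
      open <- advance()
      m <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        perr("unbalanced parenthesis", open$col)
      advance()
      return(m)
    }
    tk <- advance()
    key <- tolower(tk$text)
    if (key == "protein") return(!atoms$is_ion & !atoms$is_ligand)
    if (key == "ion") return(atoms$is_ion)
    if (key == "ligand") return(atoms$is_ligand)
    if (!key %in% SELECTION_KEYS)
      perr(sprintf("unknown keyword '%s'", tk$text), tk$col)
    eval_primary(key, parse_values(), tk$col)
  }

  parse_term <- function() {
    m <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      m <- m & parse_factor()
    }
    m
  }

  parse_expr <- function() {
    m <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      m <- m | parse_term()
    }
    m
  }

  mask <- parse_expr()
  if (pos <= nrow(toks))
    perr(sprintf("unexpected token '%s'", toks$text[pos]), toks$col[pos])
  if (granularity == "residue" && any(mask)) {
    keys <- residue_key(atoms)
    mask <- keys %in% unique(keys[mask])
  }
  idx <- atoms$index[mask]
  if (!length(idx))
    warning("selection '", expression, "' matched no atoms")
  structure(list(expression = expression,
                 atom_indices = sort(as.integer(idx)),
                 granularity = granularity),
            class = "pg_selection")
}

#' @export
print.pg_selection <- function(x, ...) {
  cat(sprintf("<pg_selection> '%s' (%s): %d atoms\n",
              x$expression, x$granularity, length(x$atom_indices)))
  invisible(x)
}

# 1-based row indices into the atom table for a selection.
sel_rows <- function(selection) selection$atom_indices + 1L

# Coerce a selection or raw 0-based index vector to 1-based rows.
as_sel_rows <- function(x) {
  if (inherits(x, "pg_selection")) sel_rows(x) else as.integer(x) + 1L
}
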