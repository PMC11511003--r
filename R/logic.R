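#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Boolean rule expressions ----------------------------------------------------
##
## Rules are stored as small abstract syntax trees: lists with an `op` field,
## one of "var", "const", "not", "and", "or".  "and"/"or" are n-ary.  The text
## dialect is the common rule-file syntax: `!` (NOT) binds tighter than `&`
## (AND), which binds tighter than `|` (OR); parentheses and the constants
## `0`/`1` are allowed.

expr_var   <- function(name) list(op = "var", name = name)
expr_const <- function(value) list(op = "const", value = as.integer(value))
expr_not   <- function(x) list(op = "not", x = x)
expr_and   <- function(args) if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
expr_or    <- function(args) if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)

.tokenize_expr <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_.]*|[01]|[!&|()]|\\s+"
  out <- character(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substr(text, pos, n))
    if (m != 1L) {
      stop(sprintf("syntax error: unexpected character '%s' at position %d",
                   substr(text, pos, pos), pos), call. = FALSE)
    }
    len <- attr(m, "match.length")
    tok <- substr(text, pos, pos + len - 1L)
    if (!grepl("^\\s+$", tok)) out <- c(out, tok)
    pos <- pos + len
  }
  out
}

## Recursive-descent parser over the token vector.  Returns the AST; errors
## mention the offending token so callers can add line context.
parse_expr <- function(text) {
  tokens <- .tokenize_expr(text)
  if (length(tokens) == 0L) stop("syntax error: empty expression", call. = FALSE)
  idx <- 1L
  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NA_character_
  take <- function() {
    tok <- peek()
    if (is.na(tok)) stop("syntax error: unexpected end of expression", call. = FALSE)
    idx <<- idx + 1L
    tok
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      take()
      args <- c(args, list(parse_and()))
    }
    expr_or(args)
  }
  parse_and <- function() {
    args <- list(parse_not())
    while (identical(peek(), "&")) {
      take()
      args <- c(args, list(parse_not()))
    }
    expr_and(args)
  }
  parse_not <- function() {
    if (identical(peek(), "!")) {
      take()
      return(expr_not(parse_not()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- take()
    if (tok == "(") {
      e <- parse_or()
      close <- take()
      if (!identical(close, ")")) {
        stop(sprintf("syntax error: expected ')' but found '%s'", close), call. = FALSE)
      }
      return(e)
    }
    if (tok %in% c("0", "1")) return(expr_const(tok))
    if (grepl("^[A-Za-z_]", tok)) return(expr_var(tok))
    stop(sprintf("syntax error: unexpected token '%s'", tok), call. = FALSE)
  }
  out <- parse_or()
  if (!is.na(peek())) {
    stop(sprintf("syntax error: trailing token '%s'", peek()), call. = FALSE)
  }
  out
}

#' Free identifiers of a rule expression
#'
#' @param expr a parsed rule expression (AST).
#' @return character vector of distinct identifiers, in order of first use.
#' @keywords internal
expr_vars <- function(expr) {
  switch(expr$op,
    var   = expr$name,
    const = character(0),
    "not" = expr_vars(expr$x),
    unique(unlist(lapply(expr$args, expr_vars)))
  )
}

## Evaluate an expression columnwise over a logical/integer matrix whose
## columns are named after network nodes.  Returns a logical vector, one
## entry per row; this is what builds truth tables and transition tables.
eval_expr <- function(expr, values) {
  switch(expr$op,
    var   = as.logical(values[, expr$name]),
    const = rep(as.logical(expr$value), nrow(values)),
    "not" = !eval_expr(expr$x, values),
    "and" = Reduce(`&`, lapply(expr$args, eval_expr, values = values)),
    "or"  = Reduce(`|`, lapply(expr$args, eval_expr, values = values))
  )
}

## Deparse with minimal parentheses (NOT > AND > OR).
deparse_expr <- function(expr) {
  wrap <- function(e, parent) {
    s <- deparse_expr(e)
    needs <- (parent == "not" && e$op %in% c("and", "or")) ||
             (parent == "and" && e$op == "or")
    if (needs) paste0("(", s, ")") else s
  }
  switch(expr$op,
    var   = expr$name,
    const = as.character(expr$value),
    "not" = paste0("!", wrap(expr$x, "not")),
    "and" = paste(vapply(expr$args, wrap, "", parent = "and"), collapse = " & "),
    "or"  = paste(vapply(expr$args, wrap, "", parent = "or"), collapse = " | ")
  )
}

## Reconstruct an expression from an explicit truth table (used to serialize
## perturbed or randomly drawn rules).  `regulators` orders the inputs;
## `tt[i]` is the output for the input combination whose bits encode i-1
## (regulator j at bit j-1).  Sum-of-products over the true rows.
expr_from_tt <- function(regulators, tt) {
  k <- length(regulators)
  stopifnot(length(tt) == 2^k)
  if (all(tt == 0L)) return(expr_const(0L))
  if (all(tt == 1L)) return(expr_const(1L))
  rows <- which(tt == 1L) - 1L
  terms <- lapply(rows, function(r) {
    lits <- lapply(seq_len(k), function(j) {
      if (bitwAnd(bitwShiftR(r, j - 1L), 1L) == 1L) {
        expr_var(regulators[[j]])
      } else {
        expr_not(expr_var(regulators[[j]]))
      }
    })
    expr_and(lits)
  })
  expr_or(terms)
}
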