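## Rule-file reader/writer -----------------------------------------------------
##
## The text format is the widely used "targets, factors" dialect: a header
## line, then one line per node of the form `NODE, <expression>`, with the
## operators `!`, `&`, `|`, parentheses and the constants `0`/`1`.  Reading
## and writing round-trip (truth-table equality per node).

#' Parse a Boolean network from rule-file text
#'
#' @param text a single string, or a character vector of lines, in the
#'   "targets, factors" dialect.  Lines starting with `#` and blank lines are
#'   ignored.
#' @return a [boolean_network()].
#' @examples
#' parse_rules("targets, factors\nA, !B\nB, A")
#' @export
parse_rules <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L || !grepl("^targets\\s*,\\s*factors$", lines[[1L]])) {
    stop("rule file must start with the header line 'targets, factors'", call. = FALSE)
  }
  body <- lines[-1L]
  body_lineno <- lineno[-1L]
  if (length(body) == 0L) stop("rule file declares no rules", call. = FALSE)
  split_at <- regexpr(",", body, fixed = TRUE)
  if (any(split_at < 0L)) {
    stop(sprintf("line %d: expected 'NODE, <expression>'",
                 body_lineno[which(split_at < 0L)[1L]]), call. = FALSE)
  }
  targets <- trimws(substr(body, 1L, split_at - 1L))
  exprs_txt <- trimws(substr(body, split_at + 1L, nchar(body)))
  if (anyDuplicated(targets)) {
    dup <- unique(targets[duplicated(targets)])
    stop(sprintf("duplicate target node(s): %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  exprs <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", targets[[i]])) {
      stop(sprintf("line %d: invalid node name '%s'", body_lineno[[i]], targets[[i]]),
           call. = FALSE)
    }
    exprs[[i]] <- tryCatch(parse_expr(exprs_txt[[i]]), error = function(e) {
      stop(sprintf("line %d (rule for '%s'): %s",
                   body_lineno[[i]], targets[[i]], conditionMessage(e)), call. = FALSE)
    })
  }
  names(exprs) <- targets
  tryCatch(boolean_network(exprs), error = function(e) {
    stop(sprintf("in rule file: %s", conditionMessage(e)), call. = FALSE)
  })
}

#' @rdname parse_rules
#' @param path path to a rule file.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop(sprintf("rule file not found: %s", path), call. = FALSE)
  parse_rules(readLines(path, warn = FALSE))
}

#' Serialize a Boolean network to the rule-file dialect
#'
#' Clamped nodes are written with their constant value so that mutant
#' networks serialize faithfully.
#'
#' @param net a `boolean_network`.
#' @return `format_rules()`: a character scalar; `write_rules()`: the path,
#'   invisibly.
#' @export
format_rules <- function(net) {
  body <- vapply(net$nodes, function(nd) {
    rhs <- if (!is.null(net$clamps) && nd %in% names(net$clamps)) {
      as.character(net$clamps[[nd]])
    } else {
      deparse_expr(net$exprs[[nd]])
    }
    paste0(nd, ", ", rhs)
  }, "")
  paste(c("targets, factors", body), collapse = "\n")
}

#' @rdname format_rules
#' @param path output file path.
#' @export
write_rules <- function(net, path) {
  writeLines(format_rules(net), path)
  invisible(path)
}
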