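## Boolean networks, synchronous dynamics, attractors --------------------------

#' Construct a synchronous Boolean network
#'
#' A network is an ordered set of named nodes, one Boolean rule per node, and
#' an optional clamp map fixing nodes at a constant value (used for in-silico
#' loss-/gain-of-function mutants).  Node order is fixed and defines bit
#' positions in the integer state encoding: node `i` occupies bit `i - 1`.
#'
#' @param rules named character vector or list; one rule expression per node
#'   in the dialect `!`, `&`, `|`, parentheses and the constants `0`/`1`.
#' @param nodes optional node order; defaults to `names(rules)`.
#' @param clamps optional named vector of 0/1 values; clamped nodes ignore
#'   their rule.
#' @return an object of class `boolean_network` with elements `nodes`,
#'   `exprs` (rule ASTs), `regulators` (per-node inputs, in node order),
#'   `tt` (per-node truth tables) and `clamps`.
#' @examples
#' net <- boolean_network(c(A = "!B", B = "A"))
#' step_network(net, c(A = 0, B = 0))
#' @export
boolean_network <- function(rules, nodes = names(rules), clamps = NULL) {
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("every rule must be named after its target node", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop(sprintf("duplicate target node(s): %s",
                 paste(unique(nodes[duplicated(nodes)]), collapse = ", ")),
         call. = FALSE)
  }
  rules <- rules[nodes]
  exprs <- lapply(rules, function(r) if (is.list(r) && !is.null(r$op)) r else parse_expr(as.character(r)))
  names(exprs) <- nodes
  for (nd in nodes) {
    unknown <- setdiff(expr_vars(exprs[[nd]]), nodes)
    if (length(unknown) > 0L) {
      stop(sprintf("rule for '%s' references unknown identifier(s): %s",
                   nd, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  regulators <- lapply(exprs, function(e) nodes[nodes %in% expr_vars(e)])
  tt <- lapply(nodes, function(nd) .truth_table(exprs[[nd]], regulators[[nd]]))
  names(tt) <- nodes
  clamps <- .check_clamps(clamps, nodes)
  structure(
    list(nodes = nodes, exprs = exprs, regulators = regulators, tt = tt,
         clamps = clamps),
    class = "boolean_network"
  )
}

.check_clamps <- function(clamps, nodes) {
  if (is.null(clamps) || length(clamps) == 0L) return(NULL)
  if (is.null(names(clamps)) || any(!nzchar(names(clamps)))) {
    stop("clamps must be a named vector of 0/1 values", call. = FALSE)
  }
  bad <- setdiff(names(clamps), nodes)
  if (length(bad) > 0L) {
    stop(sprintf("clamp refers to unknown node(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  vals <- as.integer(clamps)
  if (any(!vals %in% c(0L, 1L))) stop("clamp values must be 0 or 1", call. = FALSE)
  stats::setNames(vals, names(clamps))
}

## Truth table of one rule: output for every combination of its regulators,
## regulator j at bit j-1 of the row index.
.truth_table <- function(expr, regulators) {
  k <- length(regulators)
  rows <- 2^k
  if (k == 0L) {
    vals <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    vals <- vapply(seq_len(k), function(j) bitwAnd(bitwShiftR(0:(rows - 1L), j - 1L), 1L),
                   integer(rows))
    vals <- matrix(vals, nrow = rows, ncol = k)
  }
  colnames(vals) <- regulators
  as.integer(eval_expr(expr, vals))
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (synchronous update)\n", length(x$nodes)))
  for (nd in x$nodes) {
    cl <- if (!is.null(x$clamps) && nd %in% names(x$clamps)) {
      sprintf("  [clamped to %d]", x$clamps[[nd]])
    } else ""
    cat(sprintf("  %s <- %s%s\n", nd, deparse_expr(x$exprs[[nd]]), cl))
  }
  invisible(x)
}

#' Number of nodes of a Boolean network
#' @param net a `boolean_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

## ---- state encoding ---------------------------------------------------------

#' Convert between bit-vector and integer state encodings
#'
#' Node `i` of the network occupies bit `i - 1` of the unsigned integer code,
#' so the vector/integer round trip is the identity.
#'
#' @param state 0/1 vector of length `n` (named or positional).
#' @param nodes node name vector defining bit order.
#' @return `state_to_int()`: a non-negative integer; `int_to_state()`: a named
#'   0/1 integer vector.
#' @export
state_to_int <- function(state, nodes) {
  state <- .check_state(state, nodes)
  as.integer(sum(as.numeric(state) * 2^(seq_along(nodes) - 1L)))
}

#' @rdname state_to_int
#' @param code integer state code in `[0, 2^n)`.
#' @export
int_to_state <- function(code, nodes) {
  n <- length(nodes)
  stats::setNames(bitwAnd(bitwShiftR(as.integer(code), seq_len(n) - 1L), 1L), nodes)
}

.check_state <- function(state, nodes) {
  n <- length(nodes)
  if (length(state) != n) {
    stop(sprintf("state has length %d but the network has %d nodes", length(state), n),
         call. = FALSE)
  }
  if (!is.null(names(state))) state <- state[nodes]
  state <- as.integer(state)
  if (anyNA(state) || any(!state %in% c(0L, 1L))) {
    stop("state entries must be 0 or 1 for every node", call. = FALSE)
  }
  stats::setNames(state, nodes)
}

## ---- dynamics ---------------------------------------------------------------

#' Advance a network state by one synchronous step
#'
#' All nodes are updated simultaneously from the current state; clamped nodes
#' keep their clamp value regardless of their rule.
#'
#' @param net a `boolean_network`.
#' @param state 0/1 vector of length `n_nodes(net)`.
#' @return the successor state as a named 0/1 integer vector.
#' @export
step_network <- function(net, state) {
  state <- .check_state(state, net$nodes)
  vals <- matrix(state, nrow = 1L, dimnames = list(NULL, net$nodes))
  nxt <- vapply(net$nodes, function(nd) {
    regs <- net$regulators[[nd]]
    idx <- if (length(regs) == 0L) 1L else {
      1L + as.integer(sum(state[regs] * 2^(seq_along(regs) - 1L)))
    }
    net$tt[[nd]][idx]
  }, integer(1L))
  if (!is.null(net$clamps)) nxt[names(net$clamps)] <- net$clamps
  stats::setNames(nxt, net$nodes)
}

.MAX_EXHAUSTIVE_N <- 24L

## Successor codes for all 2^n states, fully vectorized.  Internal engine for
## build_transition_table(), find_attractors() and the robustness module.
.successor_codes <- function(net) {
  n <- length(net$nodes)
  if (n > .MAX_EXHAUSTIVE_N) {
    stop(sprintf("exhaustive enumeration is limited to %d nodes (network has %d)",
                 .MAX_EXHAUSTIVE_N, n), call. = FALSE)
  }
  N <- 2^n
  codes <- 0:(N - 1L)
  succ <- numeric(N)
  node_index <- stats::setNames(seq_len(n), net$nodes)
  for (i in seq_len(n)) {
    nd <- net$nodes[[i]]
    if (!is.null(net$clamps) && nd %in% names(net$clamps)) {
      bit <- rep(net$clamps[[nd]], N)
    } else {
      regs <- node_index[net$regulators[[nd]]]
      if (length(regs) == 0L) {
        bit <- rep(net$tt[[nd]][1L], N)
      } else {
        idx <- 1L
        for (j in seq_along(regs)) {
          idx <- idx + bitwAnd(bitwShiftR(codes, regs[[j]] - 1L), 1L) * 2^(j - 1L)
        }
        bit <- net$tt[[nd]][idx]
      }
    }
    succ <- succ + bit * 2^(i - 1L)
  }
  as.integer(succ)
}

#' Exhaustive synchronous transition table
#'
#' @param net a `boolean_network` with at most 24 nodes.
#' @return an object of class `transition_table`: an integer vector `succ`
#'   with `succ[s + 1]` the successor code of state `s`, plus the node order.
#' @export
build_transition_table <- function(net) {
  structure(list(succ = .successor_codes(net), nodes = net$nodes),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Synchronous transition table: %d nodes, %d states\n",
              length(x$nodes), length(x$succ)))
  invisible(x)
}

## ---- attractors -------------------------------------------------------------

#' Enumerate all attractors and basins of a Boolean network
#'
#' Exhaustive successor-graph traversal with state coloring: each state is
#' visited a constant number of times, every state is assigned to exactly one
#' attractor, and basin sizes therefore partition the `2^n` state space.
#' Cycles are reported with the smallest integer-encoded state first, and
#' attractors are ordered by that smallest state.
#'
#' @param net a `boolean_network` (at most 24 nodes).
#' @return an object of class `attractor_set`: a list with `attractors`
#'   (each a list with integer `states` and `basin`), `nodes` and `n`.
#' @export
find_attractors <- function(net) {
  succ <- .successor_codes(net)
  .attractors_from_succ(succ, net$nodes)
}

.attractors_from_succ <- function(succ, nodes) {
  N <- length(succ)
  color <- integer(N)              # 0 = unvisited, -1 = on current path, k = attractor k
  cycles <- list()
  for (s0 in seq_len(N)) {
    if (color[s0] != 0L) next
    path <- integer(0)
    s <- s0
    while (color[s] == 0L) {
      color[s] <- -1L
      path <- c(path, s)
      s <- succ[s] + 1L
    }
    if (color[s] == -1L) {
      ## new cycle: it starts where the path first revisits itself
      start <- match(s, path)
      cyc <- path[start:length(path)]
      id <- length(cycles) + 1L
      cycles[[id]] <- cyc - 1L
      color[path] <- id
    } else {
      color[path] <- color[s]
    }
  }
  basin <- tabulate(color, nbins = length(cycles))
  ## canonical form: rotate each cycle to its minimal state, order by it
  cycles <- lapply(cycles, function(cyc) {
    m <- which.min(cyc)
    c(cyc[m:length(cyc)], cyc[seq_len(m - 1L)])
  })
  ord <- order(vapply(cycles, min, numeric(1)))
  attractors <- lapply(seq_along(ord), function(j) {
    list(states = cycles[[ord[j]]], basin = basin[ord[j]])
  })
  structure(list(attractors = attractors, nodes = nodes, n = length(nodes)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  lens <- vapply(x$attractors, function(a) length(a$states), integer(1))
  cat(sprintf("Attractor set: %d attractor(s) over %d states (%d fixed point(s), %d cycle(s))\n",
              length(x$attractors), 2^x$n, sum(lens == 1L), sum(lens > 1L)))
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("  [%d] length %d, basin %d: %s\n", i, length(a$states), a$basin,
                paste(a$states, collapse = " -> ")))
  }
  invisible(x)
}

#' Attractor states as a node-by-state matrix
#'
#' @param att an `attractor_set`.
#' @param which attractor index.
#' @return 0/1 integer matrix, one row per node, one column per cycle state.
#' @export
attractor_states <- function(att, which = 1L) {
  a <- att$attractors[[which]]
  m <- vapply(a$states, function(s) int_to_state(s, att$nodes), integer(att$n))
  matrix(m, nrow = att$n, dimnames = list(att$nodes, NULL))
}

#' Tidy an attractor set into a long tibble
#'
#' @param x an `attractor_set`.
#' @param ... unused.
#' @return tibble with columns `attractor`, `length`, `basin`, `phase`,
#'   `node`, `state`.
#' @method tidy attractor_set
#' @export
tidy.attractor_set <- function(x, ...) {
  purrr::imap_dfr(x$attractors, function(a, i) {
    purrr::imap_dfr(a$states, function(s, phase) {
      tibble::tibble(
        attractor = i, length = length(a$states), basin = a$basin,
        phase = phase, node = x$nodes,
        state = as.integer(int_to_state(s, x$nodes))
      )
    })
  })
}

#' One-line summary of an attractor set
#'
#' @param x an `attractor_set`.
#' @param ... unused.
#' @return tibble with attractor counts and basin totals.
#' @method glance attractor_set
#' @export
glance.attractor_set <- function(x, ...) {
  lens <- vapply(x$attractors, function(a) length(a$states), integer(1))
  tibble::tibble(
    n_attractors = length(x$attractors),
    n_fixed_points = sum(lens == 1L),
    n_cycles = sum(lens > 1L),
    max_cycle_length = if (length(lens)) max(lens) else 0L,
    basin_total = sum(vapply(x$attractors, function(a) a$basin, numeric(1))),
    state_space = 2^x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

## Canonical string keys for attractor comparison (identical state cycles).
attractor_keys <- function(att) {
  sort(vapply(att$attractors, function(a) paste(a$states, collapse = "-"), ""))
}

#' Stable content hash of a network's truth tables
#'
#' Ties analysis outputs to the exact rule transcription: two networks hash
#' equally iff they have the same node order, regulator sets, truth tables
#' and clamps.
#'
#' @param net a `boolean_network`.
#' @return a character hash.
#' @export
network_hash <- function(net) {
  rlang::hash(list(net$nodes, net$regulators, net$tt, net$clamps))
}
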