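## Constraint-based rule search ------------------------------------------------
##
## A desk-scale analogue of constraint-based Boolean rule inference: given a
## signed, annotated topology (edge classes MPU/MNU = mandatory positive/
## negative unambiguous, OPPA/ONPA = optional, possibly ambiguous sign) and a
## set of required (and optionally forbidden) fixed-point attractors,
## enumerate all rule assignments consistent with both.  An empty result is a
## valid, reported outcome — for the compiled dehiscence topology and the
## four cell-type fixed points the search is provably empty at the ALC node,
## whose regulators take identical values in the lignification- and
## separation-layer states that must differ in ALC.

.EDGE_CLASSES <- c("MPU", "MNU", "OPPA", "ONPA")

#' Enumerate Boolean functions consistent with edge constraints
#'
#' Enumerates every truth table over `regulators` in which each mandatory
#' regulator (class MPU/MNU) is essential — the output depends on it — and
#' monotone with the required sign; optional regulators (OPPA/ONPA) may be
#' dropped and their signs are unconstrained.  An empty regulator set yields
#' the two constants.
#'
#' @param regulators character vector of regulator names (at most 4, i.e.
#'   at most `2^16` candidate tables).
#' @param classes character vector of edge classes, parallel to
#'   `regulators`; defaults to all-optional.
#' @param required_outputs optional named integer vector mapping truth-table
#'   row indices (1-based) to required outputs; used for fixed-point pruning.
#' @return a list of rule expressions (ASTs), one per admissible truth
#'   table; the table itself is attached as attribute `"tt"`.
#' @export
enumerate_functions <- function(regulators,
                                classes = rep("OPPA", length(regulators)),
                                required_outputs = NULL) {
  k <- length(regulators)
  if (k > 4L) {
    stop("enumerate_functions is limited to 4 regulators (2^16 truth tables)", call. = FALSE)
  }
  if (length(classes) != k || any(!classes %in% .EDGE_CLASSES)) {
    stop(sprintf("edge classes must be one of %s, one per regulator",
                 paste(.EDGE_CLASSES, collapse = "/")), call. = FALSE)
  }
  rows <- 2^k
  n_tables <- 2^rows
  keep <- list()
  for (code in 0:(n_tables - 1L)) {
    tt <- bitwAnd(bitwShiftR(code, 0:(rows - 1L)), 1L)
    ok <- TRUE
    if (!is.null(required_outputs)) {
      idx <- as.integer(names(required_outputs))
      if (any(tt[idx] != required_outputs)) ok <- FALSE
    }
    if (ok) {
      for (j in seq_len(k)) {
        cls <- classes[[j]]
        if (!cls %in% c("MPU", "MNU")) next
        lo <- which(bitwAnd(bitwShiftR(0:(rows - 1L), j - 1L), 1L) == 0L)
        hi <- lo + 2^(j - 1L)
        diff <- tt[hi] - tt[lo]
        essential <- any(diff != 0L)
        mono <- if (cls == "MPU") all(diff >= 0L) else all(diff <= 0L)
        if (!essential || !mono) { ok <- FALSE; break }
      }
    }
    if (ok) keep[[length(keep) + 1L]] <- tt
  }
  lapply(keep, function(tt) {
    e <- expr_from_tt(regulators, tt)
    attr(e, "tt") <- tt
    e
  })
}

#' Search rule assignments consistent with a topology and fixed points
#'
#' Per-node candidate functions are enumerated with
#' [enumerate_functions()] and pruned against every required fixed point
#' that determines the node and its regulators; the surviving assignment
#' space is explored exhaustively and each assembled network is verified by
#' exhaustive fixed-point enumeration (required states must all be fixed
#' points, forbidden states must not).  Partial required states leave
#' unspecified nodes unconstrained.
#'
#' @param topology data frame with columns `regulator`, `target`, `class`
#'   (MPU/MNU/OPPA/ONPA).
#' @param required list of named 0/1 vectors: fixed points every returned
#'   network must possess.  Partial states are allowed.
#' @param forbidden optional list of named complete 0/1 vectors that must
#'   not be fixed points.
#' @param nodes node set (default: all names in the topology and
#'   constraints).
#' @param max_assignments bound on the explored assignment space.
#' @return an object of class `rule_search_result`: `networks` (possibly
#'   empty list of [boolean_network()]s), `candidate_counts`, and
#'   `blocked_node` (the first node with no admissible function, or `NA`).
#' @export
search_networks <- function(topology, required = list(), forbidden = list(),
                            nodes = NULL, max_assignments = 250000) {
  topology <- as.data.frame(topology)
  stopifnot(all(c("regulator", "target", "class") %in% names(topology)))
  if (is.null(nodes)) {
    nodes <- unique(c(topology$regulator, topology$target,
                      unlist(lapply(c(required, forbidden), names))))
  }
  regs_of <- lapply(nodes, function(nd) topology$regulator[topology$target == nd])
  classes_of <- lapply(nodes, function(nd) topology$class[topology$target == nd])
  names(regs_of) <- names(classes_of) <- nodes

  ## local pruning: a required state that fixes a node and all its regulators
  ## pins one truth-table row of that node's function
  candidates <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) {
    regs <- regs_of[[nd]]
    pins <- integer(0)
    for (st in required) {
      if (!nd %in% names(st) || !all(regs %in% names(st))) next
      row <- 1L + if (length(regs)) sum(st[regs] * 2^(seq_along(regs) - 1L)) else 0L
      want <- as.integer(st[[nd]])
      prev <- pins[as.character(row)]
      if (!is.na(prev) && prev != want) {
        ## two required fixed points give the same regulator input but
        ## demand different outputs: no function can satisfy this node
        return(structure(list(networks = list(), candidate_counts = NULL,
                              blocked_node = nd,
                              reason = "conflicting required fixed points"),
                         class = "rule_search_result"))
      }
      pins[as.character(row)] <- want
    }
    candidates[[nd]] <- enumerate_functions(regs, classes_of[[nd]],
                                            required_outputs = if (length(pins)) pins else NULL)
    if (length(candidates[[nd]]) == 0L) {
      return(structure(list(networks = list(),
                            candidate_counts = lengths(candidates),
                            blocked_node = nd,
                            reason = "no admissible function"),
                       class = "rule_search_result"))
    }
  }
  counts <- lengths(candidates)
  if (prod(counts) > max_assignments) {
    stop(sprintf("assignment space too large (%.3g > %g); bounding node: %s (%d candidates)",
                 prod(counts), max_assignments, nodes[which.max(counts)], max(counts)),
         call. = FALSE)
  }

  grid <- do.call(expand.grid, c(lapply(counts, seq_len), list(KEEP.OUT.ATTRS = FALSE)))
  found <- list()
  for (g in seq_len(nrow(grid))) {
    rules <- stats::setNames(lapply(nodes, function(nd) {
      candidates[[nd]][[grid[g, nd]]]
    }), nodes)
    net <- boolean_network(rules)
    if (.satisfies_fixed_points(net, required, forbidden)) {
      found[[length(found) + 1L]] <- net
    }
  }
  structure(list(networks = found, candidate_counts = counts,
                 blocked_node = NA_character_, reason = NULL),
            class = "rule_search_result")
}

## Exhaustive fixed-point check of required (partial ok) / forbidden states.
.satisfies_fixed_points <- function(net, required, forbidden) {
  succ <- .successor_codes(net)
  fixed <- which(succ == (seq_along(succ) - 1L)) - 1L
  n <- length(net$nodes)
  matches <- function(code, st) {
    bits <- int_to_state(code, net$nodes)
    all(bits[names(st)] == st)
  }
  for (st in required) {
    if (!any(vapply(fixed, matches, logical(1), st = st))) return(FALSE)
  }
  for (st in forbidden) {
    if (any(vapply(fixed, matches, logical(1), st = st))) return(FALSE)
  }
  TRUE
}

#' @export
print.rule_search_result <- function(x, ...) {
  if (!is.na(x$blocked_node)) {
    cat(sprintf("Rule search: EMPTY — no admissible function for node '%s' (%s)\n",
                x$blocked_node, x$reason))
  } else {
    cat(sprintf("Rule search: %d consistent rule assignment(s)\n", length(x$networks)))
  }
  invisible(x)
}

#' Edge-constraint view of the compiled interaction catalogue
#'
#' Maps the catalogue's evidence classes onto search classes: well-supported
#' signed records become mandatory unambiguous edges (MPU/MNU), suggested
#' records optional ones (OPPA/ONPA); protein-protein records carry no sign
#' and are excluded.
#'
#' @param interactions catalogue tibble, as from [dz_interactions()].
#' @param initial_only restrict to the initial-model records (default TRUE).
#' @return tibble with columns `regulator`, `target`, `class`.
#' @export
dz_edge_constraints <- function(interactions = dz_interactions(), initial_only = TRUE) {
  df <- dplyr::filter(interactions, .data$evidence %in% c("well_supported", "suggested"))
  if (initial_only) df <- dplyr::filter(df, .data$in_initial_model)
  dplyr::transmute(df,
    regulator = .data$regulator,
    target = .data$target,
    class = dplyr::case_when(
      .data$evidence == "well_supported" & .data$sign == "activation" ~ "MPU",
      .data$evidence == "well_supported" & .data$sign == "repression" ~ "MNU",
      .data$sign == "activation" ~ "OPPA",
      TRUE ~ "ONPA"
    )
  )
}
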