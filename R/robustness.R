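## Robustness analysis ---------------------------------------------------------
##
## Two perturbation regimes, each compared against an ensemble of
## topology-matched random networks (same nodes, same per-node regulator
## sets, uniformly random non-constant truth tables):
##
##  * function perturbation: a fraction of the node rules is altered by
##    flipping one output entry of the truth table; a draw "recovers" when
##    every original attractor (identical state cycle) is still an attractor
##    of the perturbed network.
##  * transition perturbation: a fraction of the state bits is flipped and
##    the normalized Hamming distance between the successors of the original
##    and perturbed states measures how strongly one-step dynamics diverge.
##
## Empirical p-values use the add-one estimator, so they are never zero.

## Evaluation context: per-node truth-table index vectors over the full state
## space.  Shared by all networks with the same regulator wiring, which makes
## ensemble scans cheap.
.succ_context <- function(net) {
  n <- length(net$nodes)
  if (n > .MAX_EXHAUSTIVE_N) {
    stop(sprintf("exhaustive robustness analysis is limited to %d nodes", .MAX_EXHAUSTIVE_N),
         call. = FALSE)
  }
  N <- 2^n
  codes <- 0:(N - 1L)
  node_index <- stats::setNames(seq_len(n), net$nodes)
  idx <- lapply(seq_len(n), function(i) {
    regs <- node_index[net$regulators[[net$nodes[[i]]]]]
    if (length(regs) == 0L) return(rep(1L, N))
    out <- 1L
    for (j in seq_along(regs)) {
      out <- out + bitwAnd(bitwShiftR(codes, regs[[j]] - 1L), 1L) * 2^(j - 1L)
    }
    as.integer(out)
  })
  list(n = n, N = N, idx = idx, weights = 2^(seq_len(n) - 1L))
}

.succ_from_tt <- function(tt, ctx) {
  succ <- numeric(ctx$N)
  for (i in seq_len(ctx$n)) succ <- succ + tt[[i]][ctx$idx[[i]]] * ctx$weights[[i]]
  as.integer(succ)
}

## Attractor cycle keys straight from a successor vector (pointer squaring:
## after ceil(log2 N) compositions every state maps onto its attractor).
.att_keys_from_succ <- function(succ) {
  f <- succ
  steps <- 1L
  N <- length(succ)
  while (steps < N) {
    f <- f[f + 1L]
    steps <- steps * 2L
  }
  reps <- unique(f)
  keys <- character(0)
  seen <- logical(N)
  for (r in reps) {
    if (seen[r + 1L]) next
    cyc <- r
    cur <- succ[r + 1L]
    while (cur != r) {
      cyc <- c(cyc, cur)
      cur <- succ[cur + 1L]
    }
    seen[cyc + 1L] <- TRUE
    m <- which.min(cyc)
    keys <- c(keys, paste(c(cyc[m:length(cyc)], cyc[seq_len(m - 1L)]), collapse = "-"))
  }
  sort(keys)
}

#' Perturb a fraction of a network's Boolean functions
#'
#' Alters `max(1, round(fraction * n))` distinct node functions; each altered
#' function has exactly one uniformly chosen output entry of its truth table
#' flipped.  All other rules are bit-identical.  For the 11- and 12-node
#' dehiscence networks at the standard fraction 0.1 this is a single altered
#' function per draw (the minimum-one convention).
#'
#' @param net a `boolean_network`.
#' @param fraction proportion of node functions to alter (default 0.1).
#' @return the perturbed `boolean_network` (rules re-expressed from the
#'   flipped truth tables).
#' @export
perturb_functions <- function(net, fraction = 0.1) {
  n <- length(net$nodes)
  k <- max(1L, round(fraction * n))
  pick <- sample.int(n, k)
  tt <- net$tt
  for (i in pick) {
    b <- sample.int(length(tt[[i]]), 1L)
    tt[[i]][b] <- 1L - tt[[i]][b]
  }
  .network_from_tt(net, tt)
}

.network_from_tt <- function(net, tt) {
  rules <- stats::setNames(lapply(seq_along(net$nodes), function(i) {
    expr_from_tt(net$regulators[[net$nodes[[i]]]], tt[[i]])
  }), net$nodes)
  boolean_network(rules, clamps = net$clamps)
}

#' Fraction of original attractors recovered by a perturbed network
#'
#' @param original an `attractor_set` of the unperturbed network.
#' @param perturbed_net the perturbed `boolean_network` (same nodes, same
#'   order).
#' @return proportion of original attractors that appear as identical state
#'   cycles among the perturbed network's attractors.
#' @export
attractor_recovery <- function(original, perturbed_net) {
  if (!identical(original$nodes, perturbed_net$nodes)) {
    stop("attractor_recovery requires the same node set and ordering", call. = FALSE)
  }
  keys0 <- attractor_keys(original)
  keys1 <- attractor_keys(find_attractors(perturbed_net))
  mean(keys0 %in% keys1)
}

#' Perturb a fraction of a transition table's entries
#'
#' Selects `round(fraction * 2^n)` state entries without replacement and
#' flips one uniformly chosen bit of each selected successor; all other
#' entries are unchanged.
#'
#' @param table a `transition_table`.
#' @param fraction proportion of the `2^n` entries to alter.
#' @return the perturbed `transition_table`.
#' @export
perturb_transitions <- function(table, fraction = 0.1) {
  n <- length(table$nodes)
  N <- length(table$succ)
  k <- round(fraction * N)
  if (k > 0L) {
    sel <- sample.int(N, k)
    bits <- sample.int(n, k, replace = TRUE)
    table$succ[sel] <- bitwXor(table$succ[sel], bitwShiftL(1L, bits - 1L))
  }
  table
}

#' Normalized Hamming distance between two transition tables
#'
#' The number of differing successor bits divided by `n * 2^n`; symmetric,
#' zero iff the tables are identical, one when every successor bit differs.
#'
#' @param a,b `transition_table` objects over the same state space.
#' @return distance in `[0, 1]`.
#' @export
normalized_hamming <- function(a, b) {
  if (!identical(a$nodes, b$nodes) || length(a$succ) != length(b$succ)) {
    stop("transition tables must share the same node set and state space", call. = FALSE)
  }
  n <- length(a$nodes)
  d <- bitwXor(a$succ, b$succ)
  bits <- 0
  for (j in seq_len(n)) bits <- bits + sum(bitwAnd(bitwShiftR(d, j - 1L), 1L))
  bits / (n * length(a$succ))
}

#' One-step divergence of dynamics under state perturbations
#'
#' Flips `max(1, round(fraction * n))` bits of a state and measures the
#' normalized Hamming distance between the successors of the original and
#' the perturbed state.  With `exact = TRUE` (and a single flipped bit) the
#' full expectation over all states and flip positions is computed; otherwise
#' `replicates` random draws are used.  Canalized regulatory logic damps this
#' divergence well below the topology-matched random expectation.
#'
#' @param net a `boolean_network`.
#' @param fraction proportion of state bits flipped per draw (default 0.1).
#' @param replicates number of random draws when `exact = FALSE`.
#' @param exact compute the exhaustive average (single-bit flips only).
#' @return mean normalized Hamming distance between successor states.
#' @export
transition_sensitivity <- function(net, fraction = 0.1, replicates = 10000L,
                                   exact = FALSE) {
  n <- length(net$nodes)
  flips <- max(1L, round(fraction * n))
  succ <- .successor_codes(net)
  N <- length(succ)
  popbits <- function(x) {
    tot <- 0
    for (j in seq_len(n)) tot <- tot + sum(bitwAnd(bitwShiftR(x, j - 1L), 1L))
    tot
  }
  if (exact) {
    if (flips != 1L) stop("exact mode supports single-bit flips only", call. = FALSE)
    tot <- 0
    for (j in seq_len(n)) {
      sp <- bitwXor(0:(N - 1L), bitwShiftL(1L, j - 1L))
      tot <- tot + popbits(bitwXor(succ, succ[sp + 1L]))
    }
    return(tot / (n * N * n))
  }
  states <- sample.int(N, replicates, replace = TRUE) - 1L
  if (flips == 1L) {
    bits <- sample.int(n, replicates, replace = TRUE)
    pert <- bitwXor(states, bitwShiftL(1L, bits - 1L))
  } else {
    ## flip `flips` distinct bits per draw
    pert <- vapply(states, function(s) {
      Reduce(function(x, b) bitwXor(x, bitwShiftL(1L, b - 1L)), sample.int(n, flips), s)
    }, integer(1))
  }
  popbits(bitwXor(succ[states + 1L], succ[pert + 1L])) / (replicates * n)
}

#' Topology-matched random Boolean network
#'
#' Keeps the node set and every node's regulator set (hence in-degrees and
#' wiring) and draws each truth table's outputs uniformly at random;
#' constant functions are re-drawn.  With `preserve = "in_degree"` only the
#' in-degree sequence is kept and regulator sets are re-drawn at random.
#'
#' @param net the template `boolean_network`.
#' @param preserve `"regulators"` (default) or `"in_degree"`.
#' @return a random `boolean_network` with matched topology.
#' @export
random_network_like <- function(net, preserve = c("regulators", "in_degree")) {
  preserve <- match.arg(preserve)
  regulators <- net$regulators
  if (preserve == "in_degree") {
    regulators <- lapply(net$regulators, function(r) {
      k <- length(r)
      net$nodes[net$nodes %in% sample(net$nodes, k)]
    })
    names(regulators) <- net$nodes
  }
  rules <- stats::setNames(lapply(net$nodes, function(nd) {
    L <- 2^length(regulators[[nd]])
    repeat {
      v <- sample(c(0L, 1L), L, replace = TRUE)
      if (L == 1L || length(unique(v)) > 1L) break
    }
    expr_from_tt(regulators[[nd]], v)
  }), net$nodes)
  boolean_network(rules)
}

## Random truth tables for a fixed evaluation context (fast ensemble path).
.random_tt_like <- function(net) {
  lapply(net$nodes, function(nd) {
    L <- 2^length(net$regulators[[nd]])
    repeat {
      v <- sample(c(0L, 1L), L, replace = TRUE)
      if (L == 1L || length(unique(v)) > 1L) break
    }
    v
  })
}

## Recovery fraction for one network given its truth tables: `replicates`
## single-function bit-flip draws against the network's own attractor keys.
.recovery_draws <- function(tt, ctx, keys0, succ0, replicates, fraction) {
  n <- ctx$n
  k_alter <- max(1L, round(fraction * n))
  hits <- logical(replicates)
  for (r in seq_len(replicates)) {
    pick <- sample.int(n, k_alter)
    if (k_alter == 1L && !is.null(succ0)) {
      ## only one bit column changes: patch the successor vector in place
      i <- pick
      b <- sample.int(length(tt[[i]]), 1L)
      sel <- ctx$idx[[i]] == b
      delta <- (1L - 2L * tt[[i]][b]) * ctx$weights[[i]]
      succ <- succ0
      succ[sel] <- succ[sel] + delta
    } else {
      tt2 <- tt
      for (i in pick) {
        b <- sample.int(length(tt2[[i]]), 1L)
        tt2[[i]][b] <- 1L - tt2[[i]][b]
      }
      succ <- .succ_from_tt(tt2, ctx)
    }
    hits[r] <- all(keys0 %in% .att_keys_from_succ(succ))
  }
  mean(hits)
}

#' Robustness of a network's attractors against an ensemble of random nulls
#'
#' Runs one of the two perturbation analyses on the focal network and on an
#' ensemble of topology-matched random networks, and reports the focal
#' statistic, the ensemble distribution and an empirical (add-one) p-value.
#'
#' * `mode = "functions"`: per draw, one node function is altered by a
#'   truth-table bit flip (`max(1, round(fraction * n))` functions); the
#'   statistic is the fraction of draws recovering *all* original attractors
#'   (the mean per-draw proportion of recovered attractors is also reported).
#'   Each ensemble network is scored against its own attractors.
#' * `mode = "transitions"`: the statistic is the exhaustive mean normalized
#'   Hamming distance between the successors of a state and of the state
#'   with `max(1, round(fraction * n))` flipped bit(s)
#'   (see [transition_sensitivity()]); smaller means more robust.
#'
#' @param net the focal `boolean_network`.
#' @param mode `"functions"` or `"transitions"`.
#' @param fraction proportion perturbed (default 0.1).
#' @param ensemble_size number of random networks (default 1000).
#' @param replicates perturbation draws for the focal network (default
#'   10000 in function mode).
#' @param ensemble_replicates draws per ensemble network (default 100).
#' @param seed integer seed driving every random draw of the analysis.
#' @return an object of class `robustness_summary`.
#' @export
run_robustness <- function(net, mode = c("functions", "transitions"),
                           fraction = 0.1, ensemble_size = 1000L,
                           replicates = 10000L, ensemble_replicates = 100L,
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction <= 1, ensemble_size >= 1L)
  set.seed(seed)
  ctx <- .succ_context(net)
  n <- ctx$n
  flips <- max(1L, round(fraction * n))
  if (mode == "functions") {
    succ0 <- .succ_from_tt(net$tt, ctx)
    keys0 <- .att_keys_from_succ(succ0)
    focal <- .recovery_draws(net$tt, ctx, keys0, succ0, replicates, fraction)
    ensemble <- vapply(seq_len(ensemble_size), function(e) {
      tte <- .random_tt_like(net)
      se <- .succ_from_tt(tte, ctx)
      .recovery_draws(tte, ctx, .att_keys_from_succ(se), se, ensemble_replicates, fraction)
    }, numeric(1))
    p <- (1 + sum(ensemble >= focal)) / (ensemble_size + 1)
  } else {
    exact <- flips == 1L
    sens <- function(succ) {
      tot <- 0
      for (j in seq_len(n)) {
        sp <- bitwXor(0:(ctx$N - 1L), bitwShiftL(1L, j - 1L))
        d <- bitwXor(succ, succ[sp + 1L])
        for (b in seq_len(n)) tot <- tot + sum(bitwAnd(bitwShiftR(d, b - 1L), 1L))
      }
      tot / (n * ctx$N * n)
    }
    if (!exact) {
      sens <- function(succ) {
        states <- sample.int(ctx$N, replicates, replace = TRUE) - 1L
        pert <- states
        for (i in seq_len(replicates)) {
          bits <- sample.int(n, flips)
          pert[i] <- Reduce(function(x, b) bitwXor(x, bitwShiftL(1L, b - 1L)), bits, pert[i])
        }
        d <- bitwXor(succ[states + 1L], succ[pert + 1L])
        tot <- 0
        for (b in seq_len(n)) tot <- tot + sum(bitwAnd(bitwShiftR(d, b - 1L), 1L))
        tot / (replicates * n)
      }
    }
    focal <- sens(.succ_from_tt(net$tt, ctx))
    ensemble <- vapply(seq_len(ensemble_size), function(e) {
      sens(.succ_from_tt(.random_tt_like(net), ctx))
    }, numeric(1))
    p <- (1 + sum(ensemble <= focal)) / (ensemble_size + 1)
  }
  structure(
    list(mode = mode, fraction = fraction, flips = flips,
         focal = focal, ensemble = ensemble,
         ensemble_size = ensemble_size, replicates = replicates,
         ensemble_replicates = ensemble_replicates,
         p_value = p, seed = seed, hash = network_hash(net)),
    class = "robustness_summary"
  )
}

#' @export
print.robustness_summary <- function(x, ...) {
  lab <- if (x$mode == "functions") "attractor recovery" else "successor Hamming distance"
  cat(sprintf("Robustness analysis (%s perturbation, fraction %.2f, seed %d)\n",
              sub("s$", "", x$mode), x$fraction, x$seed))
  cat(sprintf("  focal %s: %.4f\n", lab, x$focal))
  cat(sprintf("  ensemble (%d nets): median %.4f, mean %.4f, sd %.4f\n",
              x$ensemble_size, stats::median(x$ensemble), mean(x$ensemble),
              stats::sd(x$ensemble)))
  cat(sprintf("  empirical p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' @method tidy robustness_summary
#' @export
tidy.robustness_summary <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(network = "focal", value = x$focal),
    tibble::tibble(network = sprintf("random_%04d", seq_along(x$ensemble)),
                   value = x$ensemble)
  ) |>
    dplyr::mutate(mode = x$mode, fraction = x$fraction, seed = x$seed)
}

#' @method glance robustness_summary
#' @export
glance.robustness_summary <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, fraction = x$fraction,
    focal = x$focal,
    ensemble_median = stats::median(x$ensemble),
    ensemble_mean = mean(x$ensemble),
    ensemble_sd = stats::sd(x$ensemble),
    p_value = x$p_value,
    ensemble_size = x$ensemble_size,
    seed = x$seed
  )
}

#' Histogram of the random-network ensemble with the focal value marked
#'
#' @param object a `robustness_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot robustness_summary
#' @export
autoplot.robustness_summary <- function(object, ...) {
  df <- tibble::tibble(value = object$ensemble)
  xlab <- if (object$mode == "functions") {
    "fraction of original attractors recovered"
  } else {
    "normalized Hamming distance of successor states"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$focal, colour = "red", linewidth = 1) +
    ggplot2::labs(x = xlab, y = "random networks",
                  title = sprintf("%s perturbation (p = %.3g)", object$mode, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
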