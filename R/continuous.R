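## Boolean -> continuous conversion --------------------------------------------
##
## Synchronous Boolean updating can produce artifactual cyclic attractors:
## simultaneous switching lets the system revisit configurations that a
## continuous system would pass through transiently.  To distinguish such
## artifacts from genuine oscillations, the Boolean model is embedded in a
## continuous dynamical system:
##
##   dx_i/dt = sigma_h( omega_i(x) ) - gamma_i * x_i,   x in [0,1]^n
##
## where omega_i is the fuzzy-logic relaxation of node i's rule
## (NOT x -> 1 - x, AND -> min, OR -> max), and sigma_h is the sigmoid
## 1 / (1 + exp(-h (w - 1/2))) normalized so that sigma_h(0) = 0 and
## sigma_h(1) = 1.  On Boolean corner states omega_i reproduces the rule's
## truth table, so for steep gain and unit decay every Boolean fixed point
## has a continuous counterpart at the corresponding corner.

fuzzy_eval <- function(expr, x) {
  switch(expr$op,
    var   = x[[expr$name]],
    const = as.numeric(expr$value),
    "not" = 1 - fuzzy_eval(expr$x, x),
    "and" = do.call(pmin, lapply(expr$args, fuzzy_eval, x = x)),
    "or"  = do.call(pmax, lapply(expr$args, fuzzy_eval, x = x))
  )
}

.sigmoid_norm <- function(w, h) {
  g <- function(u) 1 / (1 + exp(-h * (u - 0.5)))
  (g(w) - g(0)) / (g(1) - g(0))
}

#' Convert a Boolean network to a continuous dynamical system
#'
#' @param net a `boolean_network`.  Clamped nodes (constant rules) stay at
#'   their clamp value.
#' @param h sigmoid gain (steepness), scalar or per-node vector; must be
#'   positive.  Default 10 (strongly saturating).
#' @param gamma decay rate, scalar or per-node vector; must be positive.
#'   Default 1 (unit decay, the standard normalization).
#' @return an object of class `continuous_system`.
#' @export
continuize <- function(net, h = 10, gamma = 1) {
  n <- length(net$nodes)
  h <- rep_len(h, n)
  gamma <- rep_len(gamma, n)
  if (any(h <= 0) || any(gamma <= 0)) {
    stop("gain h and decay gamma must be positive", call. = FALSE)
  }
  structure(
    list(net = net, nodes = net$nodes, h = h, gamma = gamma),
    class = "continuous_system"
  )
}

#' @export
print.continuous_system <- function(x, ...) {
  cat(sprintf("Continuous system: %d nodes, gain h in [%g, %g], decay gamma in [%g, %g]\n",
              length(x$nodes), min(x$h), max(x$h), min(x$gamma), max(x$gamma)))
  invisible(x)
}

## Right-hand side of the ODE system.
.cs_deriv <- function(system, x) {
  x <- stats::setNames(pmin(pmax(as.numeric(x), 0), 1), system$nodes)
  xs <- as.list(x)
  w <- vapply(system$nodes, function(nd) fuzzy_eval(system$net$exprs[[nd]], xs), numeric(1))
  .sigmoid_norm(w, system$h) - system$gamma * x
}

#' Integrate a continuous system
#'
#' Stiff-safe numerical integration (deSolve's `lsoda`) from an initial
#' point in the unit hypercube.  A steady state is declared when the maximal
#' rate of change stays below `tol` over the sustained tail of the
#' trajectory; non-convergence within `t_max` is reported, not raised.
#'
#' @param system a `continuous_system`.
#' @param x0 initial state in `[0,1]^n` (named or positional).
#' @param t_max integration horizon in time units (default 100).
#' @param tol steady-state tolerance on `max |dx/dt|` (default 1e-6).
#' @param n_steps number of saved trajectory points.
#' @return a list of class `cs_trajectory`: `trajectory` (tibble, time by
#'   node), `steady_state` (named vector or `NULL`), `residual`,
#'   `converged`, and `shadow` (thresholded 0/1 state, `x > 0.5`).
#' @export
integrate_system <- function(system, x0, t_max = 100, tol = 1e-6, n_steps = 200L) {
  n <- length(system$nodes)
  if (length(x0) != n) stop("x0 must have one entry per node", call. = FALSE)
  if (!is.null(names(x0))) x0 <- x0[system$nodes]
  x0 <- pmin(pmax(as.numeric(x0), 0), 1)
  times <- seq(0, t_max, length.out = n_steps + 1L)
  rhs <- function(t, y, parms) list(.cs_deriv(system, y))
  sol <- deSolve::ode(y = stats::setNames(x0, system$nodes), times = times,
                      func = rhs, parms = NULL, method = "lsoda")
  traj <- tibble::as_tibble(as.data.frame(sol))
  final <- as.numeric(sol[nrow(sol), -1L])
  resid <- max(abs(.cs_deriv(system, final)))
  ## sustained window: the residual must also be below tol at 90% of t_max
  near_end <- as.numeric(sol[max(1L, floor(0.9 * nrow(sol))), -1L])
  converged <- resid < tol && max(abs(.cs_deriv(system, near_end))) < tol
  shadow <- stats::setNames(as.integer(final > 0.5), system$nodes)
  structure(
    list(trajectory = traj,
         steady_state = if (converged) stats::setNames(final, system$nodes) else NULL,
         residual = resid, converged = converged, shadow = shadow),
    class = "cs_trajectory"
  )
}

#' @export
print.cs_trajectory <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Converged to a steady state (residual %.2e); Boolean shadow: %s\n",
                x$residual, paste(x$shadow, collapse = "")))
  } else {
    cat(sprintf("No steady state within the horizon (final residual %.2e)\n", x$residual))
  }
  invisible(x)
}

#' Resolve cyclic attractors through the continuous embedding
#'
#' For each cyclic attractor of the Boolean network, integrates the
#' continuous system from the exact corner embedding of every cycle state
#' and from a jittered replicate (each coordinate moved 0.01 into the
#' interior) to separate knife-edge from robust convergence.  Reports
#' whether all trajectories reach a common steady state and which cell-type
#' profile its Boolean shadow matches.  Networks with only fixed points
#' yield an empty report.
#'
#' @param net a `boolean_network`.
#' @param attractors optional precomputed `attractor_set`.
#' @param profiles reference profiles for shadow classification.
#' @param h,gamma,tol,t_max continuous-model parameters (see [continuize()]
#'   and [integrate_system()]).
#' @param jitter interior offset of the jittered replicate (default 0.01).
#' @return a tibble with one row per cyclic attractor: `attractor`,
#'   `cycle_length`, `n_starts`, `all_converged`, `common_steady`,
#'   `shadow` (bit string or `NA`), `profile`.
#' @export
resolve_cyclic_attractors <- function(net, attractors = NULL,
                                      profiles = dz_profiles(),
                                      h = 10, gamma = 1, tol = 1e-6,
                                      t_max = 100, jitter = 0.01) {
  if (is.null(attractors)) attractors <- find_attractors(net)
  system <- continuize(net, h = h, gamma = gamma)
  cyclic <- which(vapply(attractors$attractors, function(a) length(a$states) > 1L, logical(1)))
  purrr::map_dfr(cyclic, function(i) {
    a <- attractors$attractors[[i]]
    starts <- list()
    for (s in a$states) {
      corner <- as.numeric(int_to_state(s, net$nodes))
      starts <- c(starts, list(corner, corner + jitter * (1 - 2 * corner)))
    }
    runs <- lapply(starts, function(x0) {
      integrate_system(system, x0, t_max = t_max, tol = tol)
    })
    conv <- vapply(runs, function(r) r$converged, logical(1))
    shadows <- vapply(runs, function(r) paste(r$shadow, collapse = ""), "")
    common <- all(conv) && length(unique(shadows[conv])) == 1L
    shadow <- if (common) shadows[[1L]] else NA_character_
    prof <- if (common) {
      st <- stats::setNames(as.integer(strsplit(shadow, "")[[1L]]), net$nodes)
      match_profile(st, profiles)
    } else {
      NA_character_
    }
    tibble::tibble(attractor = i, cycle_length = length(a$states),
                   n_starts = length(starts), all_converged = all(conv),
                   common_steady = common, shadow = shadow, profile = prof)
  })
}
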