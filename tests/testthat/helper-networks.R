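# Shared fixtures: toy networks, random network generator, and an
# independent brute-force attractor oracle (plain step iteration from every
# start state until revisit; no shared code with the traversal under test).

toy_identity <- function() boolean_network(c(A = "A"))
toy_negation <- function() boolean_network(c(A = "!A"))
toy_toggle   <- function() boolean_network(c(A = "!B", B = "!A"))

# Random network: random regulator sets (up to max_k) and random
# non-degenerate truth tables.  Caller controls the RNG seed.
rand_net <- function(n, max_k = 3L) {
  nodes <- paste0("N", seq_len(n))
  rules <- stats::setNames(lapply(seq_len(n), function(i) {
    k <- sample(0:min(max_k, n), 1L)
    regs <- sample(nodes, k)
    tt <- sample(c(0L, 1L), 2^k, replace = TRUE)
    podnet:::expr_from_tt(regs, tt)
  }), nodes)
  boolean_network(rules)
}

# Oracle: for every start state iterate step_network() until a state repeats;
# the suffix from the first repeat is the attractor cycle.  Returns canonical
# cycle keys and basin sizes keyed by cycle.
brute_attractors <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  N <- 2^n
  basin <- list()
  for (s0 in 0:(N - 1L)) {
    seen <- integer(0)
    s <- s0
    while (!(s %in% seen)) {
      seen <- c(seen, s)
      s <- state_to_int(step_network(net, int_to_state(s, nodes)), nodes)
    }
    cyc <- seen[which(seen == s):length(seen)]
    m <- which.min(cyc)
    cyc <- c(cyc[m:length(cyc)], cyc[seq_len(m - 1L)])
    key <- paste(cyc, collapse = "-")
    basin[[key]] <- (basin[[key]] %||% 0L) + 1L
  }
  keys <- sort(names(basin))
  list(keys = keys, basins = unlist(basin)[keys])
}

att_keys <- function(att) {
  sort(vapply(att$attractors, function(a) paste(a$states, collapse = "-"), ""))
}

att_basins_by_key <- function(att) {
  keys <- vapply(att$attractors, function(a) paste(a$states, collapse = "-"), "")
  b <- stats::setNames(vapply(att$attractors, function(a) a$basin, numeric(1)), keys)
  b[sort(keys)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
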