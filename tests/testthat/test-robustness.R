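# Function/transition perturbations, random ensembles, recovery statistics.

test_that("function perturbation alters exactly the stated number of rules by one bit", {
  net <- dz_network("final")
  # compare truth tables as functions over the original regulator sets
  # (a flipped table may simplify, e.g. to a constant, when re-expressed)
  tt_over <- function(p, nd) podnet:::.truth_table(p$exprs[[nd]], net$regulators[[nd]])
  set.seed(1)
  for (rep in 1:10) {
    pert <- perturb_functions(net, fraction = 0.1)   # round(1.2) = 1 function
    flips <- vapply(net$nodes, function(nd) sum(tt_over(pert, nd) != net$tt[[nd]]),
                    integer(1))
    expect_identical(sum(flips > 0L), 1L)
    expect_identical(max(flips), 1L)                 # exactly one output bit
  }
  # minimum-one convention at fraction -> 0
  pert <- perturb_functions(net, fraction = 1e-9)
  expect_identical(sum(vapply(net$nodes, function(nd) {
    any(tt_over(pert, nd) != net$tt[[nd]])
  }, logical(1))), 1L)
  # fraction 0.5 on 12 nodes alters 6 distinct functions
  pert <- perturb_functions(net, fraction = 0.5)
  expect_identical(sum(vapply(net$nodes, function(nd) {
    any(tt_over(pert, nd) != net$tt[[nd]])
  }, logical(1))), 6L)
})

test_that("a perturbed one-node identity rule is a single-bit flip", {
  set.seed(2)
  net <- toy_identity()
  pert <- perturb_functions(net, fraction = 1)
  over_a <- podnet:::.truth_table(pert$exprs$A, "A")
  expect_true(identical(over_a, c(1L, 1L)) || identical(over_a, c(0L, 0L)))
})

test_that("attractor recovery is 1 for an unperturbed network and 0 for a disjoint one", {
  net <- toy_identity()
  att <- find_attractors(net)
  expect_identical(attractor_recovery(att, net), 1)
  # the negation rule has only the 2-cycle: no overlap with the fixed points
  expect_identical(attractor_recovery(att, toy_negation()), 0)
  expect_error(attractor_recovery(att, toy_toggle()), "same node set")
})

test_that("recovery of single bit flips matches the brute-force oracle", {
  net <- toy_toggle()
  att <- find_attractors(net)
  keys0 <- att_keys(att)
  # enumerate all single-bit truth-table flips and score recovery two ways
  for (nd in net$nodes) {
    for (b in seq_along(net$tt[[nd]])) {
      tt <- net$tt
      tt[[nd]][b] <- 1L - tt[[nd]][b]
      pert <- podnet:::.network_from_tt(net, tt)
      expect_identical(attractor_recovery(att, pert),
                       mean(keys0 %in% brute_attractors(pert)$keys))
    }
  }
})

test_that("transition-table perturbation alters the stated entries by one bit each", {
  net <- dz_network("final")
  tab <- build_transition_table(net)
  set.seed(3)
  pert <- perturb_transitions(tab, fraction = 0.1)
  d <- bitwXor(tab$succ, pert$succ)
  changed <- which(d != 0L)
  expect_identical(length(changed), 410L)   # round(0.1 * 4096) entries
  popc <- vapply(d[changed], function(x) sum(bitwAnd(bitwShiftR(x, 0:11), 1L)), integer(1))
  expect_true(all(popc == 1L))
  # null perturbation leaves the table identical, at distance zero
  none <- perturb_transitions(tab, fraction = 0)
  expect_identical(none$succ, tab$succ)
  expect_identical(normalized_hamming(tab, none), 0)
})

test_that("normalized Hamming distance behaves as a metric on tables", {
  tab <- build_transition_table(toy_toggle())
  expect_identical(normalized_hamming(tab, tab), 0)
  comp <- tab
  comp$succ <- bitwXor(tab$succ, 3L)    # complement both successor bits
  expect_identical(normalized_hamming(tab, comp), 1)
  one <- tab
  one$succ[1] <- bitwXor(one$succ[1], 1L)
  expect_identical(normalized_hamming(tab, one), 1 / 8)
  expect_identical(normalized_hamming(one, tab), 1 / 8)
  expect_error(normalized_hamming(tab, build_transition_table(toy_identity())),
               "same node set")
})

test_that("random topology-matched networks keep regulator sets and vary by seed", {
  net <- dz_network("final")
  set.seed(4); r1 <- random_network_like(net)
  set.seed(5); r2 <- random_network_like(net)
  expect_identical(r1$regulators, net$regulators)
  expect_identical(r2$regulators, net$regulators)
  expect_false(identical(r1$tt, r2$tt))
  # no constant functions for nodes with regulators
  for (nd in net$nodes) {
    if (length(r1$regulators[[nd]]) > 0L) expect_gt(length(unique(r1$tt[[nd]])), 1L)
  }
  set.seed(6)
  rd <- random_network_like(net, preserve = "in_degree")
  expect_identical(lengths(rd$regulators), lengths(net$regulators))
})

test_that("one-step transition sensitivity: exact expectation and sampling agree", {
  net <- dz_network("final")
  exact <- transition_sensitivity(net, fraction = 0.1, exact = TRUE)
  set.seed(8)
  sampled <- transition_sensitivity(net, fraction = 0.1, replicates = 20000L)
  expect_gt(exact, 0)
  expect_lt(exact, 0.5)
  expect_lt(abs(sampled - exact), 0.01)
})

test_that("mean sensitivity is non-decreasing in the perturbed fraction", {
  set.seed(9)
  for (rep in 1:5) {
    net <- rand_net(6, max_k = 3)
    d1 <- transition_sensitivity(net, fraction = 1 / 6, replicates = 4000L)
    d3 <- transition_sensitivity(net, fraction = 3 / 6, replicates = 4000L)
    d6 <- transition_sensitivity(net, fraction = 1, replicates = 4000L)
    expect_lte(d1, d3 + 0.03)   # Monte-Carlo slack
    expect_lte(d3, d6 + 0.03)
  }
})

test_that("robustness summaries are seed-reproducible and well-formed", {
  net <- dz_network("final")
  a <- run_robustness(net, "functions", ensemble_size = 20, replicates = 200,
                      ensemble_replicates = 20, seed = 123)
  b <- run_robustness(net, "functions", ensemble_size = 20, replicates = 200,
                      ensemble_replicates = 20, seed = 123)
  expect_identical(glance(a), glance(b))
  expect_true(a$focal >= 0 && a$focal <= 1)
  expect_true(all(a$ensemble >= 0 & a$ensemble <= 1))
  expect_true(a$p_value > 0 && a$p_value <= 1)

  tr <- run_robustness(net, "transitions", ensemble_size = 25, seed = 99)
  tr2 <- run_robustness(net, "transitions", ensemble_size = 25, seed = 99)
  expect_identical(tr$focal, tr2$focal)
  expect_identical(tr$ensemble, tr2$ensemble)
  expect_identical(tr$focal, transition_sensitivity(net, exact = TRUE))
  td <- tidy(tr)
  expect_identical(nrow(td), 26L)
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("the dehiscence model is more robust than its random ensemble", {
  net <- dz_network("final")
  fun <- run_robustness(net, "functions", ensemble_size = 60, replicates = 400,
                        ensemble_replicates = 40, seed = 2024)
  expect_gt(fun$focal, stats::median(fun$ensemble))
  tr <- run_robustness(net, "transitions", ensemble_size = 60, seed = 2024)
  expect_lt(tr$focal, mean(tr$ensemble))
  expect_lt(tr$p_value, 0.05)
})
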