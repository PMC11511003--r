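# Boolean -> continuous embedding and cyclic-attractor resolution.

test_that("continuization validates parameters and reproduces rules on corners", {
  expect_error(continuize(toy_identity(), h = 0), "positive")
  expect_error(continuize(toy_identity(), gamma = -1), "positive")
  set.seed(12)
  for (rep in 1:10) {
    net <- rand_net(sample(2:5, 1))
    for (draw in 1:6) {
      s <- stats::setNames(sample(0:1, n_nodes(net), replace = TRUE), net$nodes)
      nxt <- step_network(net, s)
      w <- vapply(net$nodes, function(nd) {
        podnet:::fuzzy_eval(net$exprs[[nd]], as.list(as.numeric(s)) |>
                              stats::setNames(net$nodes))
      }, numeric(1))
      expect_identical(as.integer(w), unname(nxt))   # omega restricted to corners = rule
    }
  }
})

test_that("a constant-on rule reaches the saturated steady state", {
  sys <- continuize(boolean_network(c(A = "1")), h = 10, gamma = 1)
  run <- integrate_system(sys, c(A = 0), t_max = 60, tol = 1e-6)
  expect_true(run$converged)
  expect_equal(unname(run$steady_state), 1, tolerance = 1e-4)
})

test_that("self-activation is bistable with an unstable threshold between the corners", {
  # the normalized sigmoid pins 0 and 1 as steady states of x' = sigma(x) - x;
  # at steep gain they are both attracting and the interior point x = 1/2 is
  # the unstable separatrix (1-D bifurcation checked by integrating across it)
  net <- boolean_network(c(A = "A"))
  steep <- continuize(net, h = 10)
  lo <- integrate_system(steep, c(A = 0.05), t_max = 100)
  hi <- integrate_system(steep, c(A = 0.95), t_max = 100)
  expect_true(lo$converged && hi$converged)
  expect_identical(unname(lo$shadow), 0L)
  expect_identical(unname(hi$shadow), 1L)
  above <- integrate_system(steep, c(A = 0.55), t_max = 100)
  below <- integrate_system(steep, c(A = 0.45), t_max = 100)
  expect_identical(unname(above$shadow), 1L)
  expect_identical(unname(below$shadow), 0L)
})

test_that("trajectories remain inside the unit hypercube", {
  set.seed(13)
  for (rep in 1:5) {
    net <- rand_net(4)
    sys <- continuize(net)
    x0 <- stats::setNames(stats::runif(4), net$nodes)
    run <- integrate_system(sys, x0, t_max = 30)
    vals <- as.matrix(run$trajectory[, -1])
    expect_true(all(vals >= -1e-6 & vals <= 1 + 1e-6))
  }
})

test_that("Boolean fixed points are corner steady states of the embedding", {
  for (net in list(toy_identity(), toy_toggle(), dz_network("final"))) {
    att <- find_attractors(net)
    sys <- continuize(net, h = 10, gamma = 1)
    for (a in att$attractors) {
      if (length(a$states) > 1L) next
      corner <- as.numeric(int_to_state(a$states, net$nodes))
      run <- integrate_system(sys, corner, t_max = 60)
      expect_true(run$converged)
      expect_identical(unname(run$shadow), as.integer(corner))
    }
  }
})

test_that("two-node mutual repression resolves to one of its corner states", {
  sys <- continuize(toy_toggle(), h = 10)
  run <- integrate_system(sys, c(A = 0.9, B = 0.1), t_max = 100)
  expect_true(run$converged)
  expect_true(identical(unname(run$shadow), c(1L, 0L)) ||
              identical(unname(run$shadow), c(0L, 1L)))
})

test_that("networks with only fixed points yield an empty resolution report", {
  rep <- resolve_cyclic_attractors(dz_network("final"))
  expect_identical(nrow(rep), 0L)
})

test_that("cyclic attractors of the compiled and mutant models are resolved", {
  # the compiled initial network has synchronous 2-cycles
  ini <- dz_network("initial")
  rep <- resolve_cyclic_attractors(ini, profiles = dz_profiles(c("V", "VM", "R")))
  expect_gt(nrow(rep), 0L)
  expect_true(all(rep$cycle_length > 1L))
  expect_true(all(rep$n_starts == 2L * rep$cycle_length))
  # SHP overexpression produces a cycle on the extended model
  shp <- apply_perturbation(dz_network("final"), perturbation(c(SHP = 1)))
  rep2 <- resolve_cyclic_attractors(shp)
  expect_gt(nrow(rep2), 0L)
  expect_true(is.logical(rep2$all_converged))
})

test_that("a pure synchronous oscillator without stabilizing structure is flagged", {
  # A <-> B rotation: the continuous embedding stalls on the diagonal saddle,
  # not on any Boolean corner, so no corner profile is reported
  net <- boolean_network(c(A = "B", B = "!A"))
  rep <- resolve_cyclic_attractors(net, profiles = list(ON = c(A = 1, B = 1)))
  expect_identical(nrow(rep), 1L)
  expect_true(is.na(rep$profile) || rep$profile != "ON")
})
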