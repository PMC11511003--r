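# Constraint-based rule enumeration and network search.

test_that("single mandatory regulators admit exactly the monotone essential rule", {
  pos <- enumerate_functions("X", "MPU")
  expect_length(pos, 1L)
  expect_identical(attr(pos[[1]], "tt"), c(0L, 1L))       # identity
  neg <- enumerate_functions("X", "MNU")
  expect_length(neg, 1L)
  expect_identical(attr(neg[[1]], "tt"), c(1L, 0L))       # negation
})

test_that("an empty regulator set admits only the constants", {
  fns <- enumerate_functions(character(0))
  expect_length(fns, 2L)
  tts <- lapply(fns, attr, "tt")
  expect_setequal(vapply(tts, paste, "", collapse = ""), c("0", "1"))
})

test_that("optional regulators may be dropped, mandatory ones may not", {
  # two regulators: one mandatory positive, one optional
  fns <- enumerate_functions(c("X", "Y"), c("MPU", "OPPA"))
  tts <- vapply(fns, function(f) paste(attr(f, "tt"), collapse = ""), "")
  expect_true("0101" %in% tts)     # f = X alone (Y dropped)
  expect_false("0011" %in% tts)    # f = Y alone would make X non-essential
  expect_false("0000" %in% tts)
  # every admitted table is monotone increasing in X
  for (tt in lapply(fns, attr, "tt")) {
    expect_true(all(tt[c(2L, 4L)] - tt[c(1L, 3L)] >= 0L))
    expect_true(any(tt[c(2L, 4L)] != tt[c(1L, 3L)]))
  }
  expect_error(enumerate_functions(paste0("X", 1:5)), "limited to 4")
})

test_that("toggle topology with the two polarized fixed points recovers mutual repression", {
  topo <- data.frame(regulator = c("B", "A"), target = c("A", "B"),
                     class = c("MNU", "MNU"))
  res <- search_networks(topo, required = list(c(A = 1, B = 0), c(A = 0, B = 1)))
  expect_length(res$networks, 1L)
  net <- res$networks[[1]]
  expect_identical(net$tt$A, c(1L, 0L))
  expect_identical(net$tt$B, c(1L, 0L))
  # completeness against a brute-force scan over all 1-input rule pairs
  brute <- list()
  for (ca in 0:3) {
    for (cb in 0:3) {
      tta <- bitwAnd(bitwShiftR(ca, 0:1), 1L)
      ttb <- bitwAnd(bitwShiftR(cb, 0:1), 1L)
      cand <- boolean_network(list(A = podnet:::expr_from_tt("B", tta),
                                   B = podnet:::expr_from_tt("A", ttb)))
      fixed <- with(list(s = podnet:::.successor_codes(cand)), which(s == 0:3) - 1L)
      mono_ok <- all(diff(tta) <= 0) && any(diff(tta) != 0) &&
                 all(diff(ttb) <= 0) && any(diff(ttb) != 0)
      if (mono_ok && all(c(1L, 2L) %in% fixed)) {
        brute[[length(brute) + 1L]] <- list(tta, ttb)
      }
    }
  }
  expect_length(brute, length(res$networks))
})

test_that("a self-activating node pinned to both polarities must be the identity", {
  topo <- data.frame(regulator = "A", target = "A", class = "OPPA")
  res <- search_networks(topo, required = list(c(A = 0), c(A = 1)))
  expect_length(res$networks, 1L)
  expect_identical(res$networks[[1]]$tt$A, c(0L, 1L))
})

test_that("returned assignments always satisfy the constraints (soundness)", {
  topo <- data.frame(regulator = c("A", "B", "A"), target = c("B", "A", "A"),
                     class = c("OPPA", "ONPA", "OPPA"))
  required <- list(c(A = 1, B = 1))
  forbidden <- list(c(A = 0, B = 1))
  res <- search_networks(topo, required = required, forbidden = forbidden)
  expect_gt(length(res$networks), 0L)
  for (net in res$networks) {
    att <- find_attractors(net)
    fixed <- vapply(Filter(function(a) length(a$states) == 1L, att$attractors),
                    function(a) a$states, integer(1))
    expect_true(state_to_int(c(A = 1, B = 1), net$nodes) %in% fixed)
    expect_false(state_to_int(c(A = 0, B = 1), net$nodes) %in% fixed)
  }
})

test_that("the compiled topology cannot realize the four cell-type fixed points", {
  # ALC's regulators (IND, SHP, FUL) take identical values in the LL and SL
  # profiles, which nevertheless require different ALC outputs: the search
  # is provably empty at that node.
  constraints <- dz_edge_constraints()
  profiles <- dz_profiles()
  nodes <- dz_network("initial")$nodes
  required <- lapply(profiles, function(p) p[names(p) %in% nodes])
  res <- search_networks(constraints, required = required, nodes = nodes,
                         max_assignments = 1)   # pruning must settle it before assembly
  expect_length(res$networks, 0L)
  expect_identical(res$blocked_node, "ALC")
})
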