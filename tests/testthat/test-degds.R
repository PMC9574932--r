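lib <- builtin_library()
h2co <- fixture_systems("h2co")$graph

test_that("mechanism propagation applies events left to right", {
  expect_identical(propagate_mechanism(h2co, mechanism(list(), 3))$adjacency,
                   h2co$adjacency)
  m1 <- mechanism(list(reaction_event(lib$dissociation, c(1, 3))), 2)
  out <- propagate_mechanism(h2co, m1)
  expect_setequal(vapply(split_molecules(out),
                         function(m) molecular_formula(m$graph),
                         character(1)), c("CHO", "H"))
})

test_that("a mechanism followed by its inverse restores the start graph", {
  set.seed(23)
  for (rep in 1:8) {
    g <- random_valid_graph(c("C", "C", "O", "H", "H", "H"))
    # build a random clean mechanism by sampling valid events
    evs <- list()
    cur <- g
    for (step in 1:3) {
      cand <- all_matching_events_for_test(cur, lib)
      if (length(cand) == 0L) break
      ok <- FALSE
      for (ev in sample(cand)) {
        res <- apply_event(cur, ev, enforce_valence = TRUE)
        if (!is_rejection(res)) {
          evs[[length(evs) + 1L]] <- ev
          cur <- res
          ok <- TRUE
          break
        }
      }
      if (!ok) break
    }
    if (length(evs) == 0L) next
    mech <- mechanism(evs, length(evs))
    fwd <- propagate_mechanism(g, mech)
    expect_false(is_propagation_failure(fwd))
    back <- propagate_mechanism(fwd, reverse_mechanism(mech),
                                enforce_valence = FALSE)
    expect_identical(back$adjacency, g$adjacency)
  }
})

test_that("propagation failures carry the failing step index", {
  bad <- mechanism(list(reaction_event(lib$dissociation, c(1, 3)),
                        reaction_event(lib$dissociation, c(1, 3))), 2)
  res <- propagate_mechanism(h2co, bad)
  expect_true(is_propagation_failure(res))
  expect_equal(res$step, 2L)
  expect_equal(res$reason, "pattern_mismatch")
})

test_that("element-wise cost counts differing bonds once and sees labels", {
  expect_equal(cost_elementwise(h2co, h2co), 0)
  one_off <- graph_from_bonds(c("C", "O", "H", "H"),
                              list(c(1, 2), c(1, 3)))
  expect_equal(cost_elementwise(h2co, one_off), 1)
  # a permuted isomorphic copy scores positive: the element-wise cost is
  # not permutation invariant
  perm <- c(2, 1, 3, 4)  # C/O swap changes the matrix but not the graph
  permuted <- molecular_graph(h2co$atoms[perm, , drop = FALSE],
                              h2co$adjacency[perm, perm])
  expect_gt(cost_elementwise(permuted, h2co), 0)
  expect_error(cost_elementwise(h2co, molecular_graph("H")), "atom count")
})

test_that("spectral product cost is permutation invariant with size penalty", {
  spec <- cost_spec("product_spectral", fixture_systems("h2o")$graph)
  sys <- graph_from_bonds(c("H", "O", "H", "C", "O"),
                          list(c(1, 2), c(2, 3), c(4, 5)))  # H2O + CO
  expect_equal(cost_product(sys, spec), 0)
  set.seed(31)
  for (i in 1:25) {
    p <- sample(5)
    permuted <- molecular_graph(sys$atoms[p, , drop = FALSE],
                                sys$adjacency[p, p])
    expect_equal(cost_product(permuted, spec), 0)
  }
  # no molecule with the right atom count -> penalty
  expect_equal(cost_product(fixture_systems("h2co")$graph, spec), 1e6)
  # {HCO, H} vs H2 target: 1-atom and 3-atom molecules never match n = 2
  hco_h <- graph_from_bonds(c("C", "O", "H", "H"), list(c(1, 2), c(1, 3)))
  h2 <- graph_from_bonds(c("H", "H"), list(c(1, 2)))
  expect_equal(cost_product(hco_h, cost_spec("product_spectral", h2)), 1e6)
})

test_that("spectral cost of a wrong-bonding same-size molecule is positive", {
  spec <- cost_spec("product_spectral", fixture_systems("h2o")$graph)
  hoh_chain <- graph_from_bonds(c("H", "O", "H"), list(c(1, 2)))  # OH + H
  expect_equal(cost_product(hoh_chain, spec), 1e6)  # two molecules, sizes 2+1
  oho <- graph_from_bonds(c("O", "H", "H"), list(c(1, 2), c(2, 3)))
  # H-bridged chain has same size but different spectrum
  expect_gt(cost_product(oho, spec), 0)
})

test_that("annealing finds the identity mechanism when target equals reactants", {
  spec <- cost_spec("elementwise", h2co)
  found <- anneal_search(h2co, spec, lib, n_r = 2,
                         anneal_config(rng_seed = 1, max_restarts = 1))
  expect_length(found, 1L)
  expect_equal(mechanism_length(found[[1]]), 0L)
})

test_that("annealing solves water formation and mechanisms re-propagate to zero", {
  reactants <- fixture_systems("h2_plus_o")$graph
  target <- fixture_systems("h2o")$graph
  spec <- cost_spec("product_spectral", target)
  # existence confirmed by exhaustive enumeration up to 2 steps
  expect_true(exhaustive_mechanism_exists(reactants, lib, spec, 2L))
  found <- anneal_search(reactants, spec, lib, n_r = 3,
                         anneal_config(rng_seed = 2, max_restarts = 5),
                         n_mechs = 2)
  expect_gte(length(found), 1L)
  for (mech in found) {
    final <- propagate_mechanism(reactants, mech)
    expect_false(is_propagation_failure(final))
    expect_equal(cost_product(final, spec), 0)
  }
})

test_that("annealing respects elementwise targets with fixed atom indexing", {
  target <- graph_from_bonds(c("C", "O", "H", "H"),
                             list(c(1, 2), c(3, 4)))  # CO + H2
  spec <- cost_spec("elementwise", target)
  found <- anneal_search(h2co, spec, lib, n_r = 3,
                         anneal_config(rng_seed = 3, max_restarts = 5))
  expect_gte(length(found), 1L)
  final <- propagate_mechanism(h2co, found[[1]])
  expect_identical(final$adjacency, target$adjacency)
})

test_that("roughness ranking orders mechanisms by (max rise, RMS step)", {
  m <- list(mechanism(list(), 2), mechanism(list(), 2),
            mechanism(list(), 2))
  energies <- list(c(0, 50, -100),    # A = 50, B = sqrt(mean(50^2,150^2))
                   c(0, -20, -40),    # downhill: A = 0, barrierless
                   c(0, 0, 0))        # flat: A = 0, B = 0
  tab <- rank_mechanisms(m, energies)
  expect_equal(tab$A[tab$mechanism == 1], 50)
  expect_equal(tab$B[tab$mechanism == 1], sqrt(mean(c(50, -150)^2)))
  expect_equal(tab$B[tab$mechanism == 1], 111.8034, tolerance = 1e-6)
  expect_equal(tab$A[tab$mechanism == 2], 0)
  expect_true(tab$barrierless[tab$mechanism == 2])
  expect_false(tab$barrierless[tab$mechanism == 1])
  expect_equal(tab$A[tab$mechanism == 3], 0)
  expect_equal(tab$B[tab$mechanism == 3], 0)
  # flat and downhill both have A = 0; B breaks the tie (flat first)
  expect_equal(tab$mechanism, c(3, 2, 1))
})

test_that("ranking rejects energy vectors inconsistent with step counts", {
  ev <- reaction_event(lib$dissociation, c(1, 3))
  m <- mechanism(list(ev), 1)
  expect_error(rank_mechanisms(list(m), list(c(0, -10, -20))), "energies")
})
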