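test_that("bond classification follows the covalent-radius cutoff rule", {
  # two identical atoms with radius 0.5 A, alpha = 1.2 -> cutoff 1.2 A
  atoms <- atom_spec(c("C", "C"), radii = c(C = 0.5))
  near <- geometry(atoms, rbind(c(0, 0, 0), c(1.0, 0, 0)))
  far <- geometry(atoms, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(adjacency_from_geometry(near, alpha = 1.2)$adjacency[1, 2], 1L)
  expect_equal(adjacency_from_geometry(far, alpha = 1.2)$adjacency[1, 2], 0L)
})

test_that("coincident atoms raise a degenerate-geometry error", {
  gm <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(adjacency_from_geometry(gm), "degenerate")
})

test_that("formaldehyde geometry maps to the C-O, C-H, C-H bonding graph", {
  fx <- fixture_systems("h2co")
  # independent recomputation: pairwise distances vs tabulated cutoffs
  d <- as.matrix(dist(fx$geometry$coords))
  r <- fx$geometry$atoms$covalent_radius
  expected <- (d < 1.15 * outer(r, r, `+`)) * 1L
  diag(expected) <- 0L
  dimnames(expected) <- NULL
  g <- adjacency_from_geometry(fx$geometry, alpha = 1.15)
  expect_identical(g$adjacency, expected)
  expect_identical(g$adjacency, fx$graph$adjacency)
})

test_that("derived adjacency is symmetric with zero diagonal on random geometries", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:7, 1)
    gm <- geometry(sample(c("C", "H", "O", "N"), n, replace = TRUE),
                   matrix(runif(3 * n, 0, 4), n, 3))
    g <- adjacency_from_geometry(gm)
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0L))
  }
})

test_that("split_molecules finds connected components and partitions atoms", {
  h2co <- fixture_systems("h2co")$graph
  expect_length(split_molecules(h2co), 1L)
  expect_equal(n_atoms(split_molecules(h2co)[[1]]$graph), 4L)

  # break one C-H bond: HCO + H
  lib <- builtin_library()
  broken <- apply_event(h2co, reaction_event(lib$dissociation, c(1, 3)))
  mols <- split_molecules(broken)
  expect_length(mols, 2L)
  expect_setequal(vapply(mols, function(m) molecular_formula(m$graph),
                         character(1)), c("CHO", "H"))

  edgeless <- molecular_graph(c("H", "H", "H"))
  expect_length(split_molecules(edgeless), 3L)
})

test_that("split_molecules indices reassemble the original adjacency", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_valid_graph(sample(c("C", "H", "H", "O", "H", "C"),
                                   sample(3:6, 1)))
    mols <- split_molecules(g)
    all_idx <- sort(unlist(lapply(mols, `[[`, "indices")))
    expect_identical(all_idx, seq_len(n_atoms(g)))
    for (m in mols) {
      expect_identical(m$graph$adjacency,
                       g$adjacency[m$indices, m$indices, drop = FALSE])
    }
  }
})

test_that("canonical keys are permutation invariant and separate isomers", {
  h2co <- fixture_systems("h2co")$graph
  set.seed(3)
  for (i in 1:20) {
    expect_identical(canonical_key(random_permutation_of_graph(h2co)),
                     canonical_key(h2co))
  }
  # H2CO vs HCOH: same composition, different connectivity
  hcoh <- graph_from_bonds(c("C", "O", "H", "H"),
                           list(c(1, 2), c(1, 3), c(2, 4)))
  expect_false(identical(canonical_key(h2co), canonical_key(hcoh)))
})

test_that("key equality matches brute-force isomorphism on small labeled graphs", {
  # exhaustive over all 64 graphs for two element multisets on 4 atoms
  for (symbols in list(c("C", "O", "H", "H"), c("H", "H", "H", "H"))) {
    graphs <- lapply(all_adjacencies(4L), function(a)
      molecular_graph(symbols, a))
    keys <- vapply(graphs, function(g) as.character(canonical_key(g)),
                   character(1))
    for (i in seq_along(graphs)) {
      for (j in seq_len(i - 1L)) {
        iso <- brute_force_isomorphic(symbols, graphs[[i]]$adjacency,
                                      symbols, graphs[[j]]$adjacency)
        expect_identical(keys[i] == keys[j], iso)
      }
    }
  }
  # randomized 5-6 atom pairs
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(5:6, 1)
    symbols <- sample(c("C", "H", "O"), n, replace = TRUE)
    a1 <- all_adjacencies(n)[[sample.int(2^(n * (n - 1) / 2), 1)]]
    a2 <- if (runif(1) < 0.5) {
      p <- sample(n)
      list(symbols[p], a1[p, p])
    } else {
      list(symbols, all_adjacencies(n)[[sample.int(2^(n * (n - 1) / 2), 1)]])
    }
    k1 <- canonical_key(molecular_graph(symbols, a1))
    k2 <- canonical_key(molecular_graph(a2[[1]], a2[[2]]))
    iso <- brute_force_isomorphic(symbols, a1, a2[[1]], a2[[2]])
    expect_identical(identical(k1, k2), iso)
  }
})

test_that("valence vectors are adjacency row sums", {
  h2co <- fixture_systems("h2co")$graph
  expect_identical(valence_vector(h2co), c(3L, 1L, 1L, 1L))
  expect_identical(valence_vector(molecular_graph("H")), 0L)
  k4 <- molecular_graph(rep("C", 4), matrix(1L, 4, 4) - diag(4L))
  expect_identical(valence_vector(k4), rep(3L, 4))
})

test_that("valence constraints accept valid graphs and report violations", {
  ok <- graph_from_bonds(c("C", "O", "H", "H"),
                         list(c(1, 2), c(1, 3), c(1, 4)),
                         valence_ranges = list(H = c(0, 1), O = c(1, 2),
                                               C = c(1, 4)))
  expect_true(check_valences(ok)$ok)

  # formaldehyde minus the C-O bond: O coordination drops to zero
  no_co <- graph_from_bonds(c("C", "O", "H", "H"),
                            list(c(1, 3), c(1, 4)),
                            valence_ranges = list(O = c(1, 2)))
  chk <- check_valences(no_co)
  expect_false(chk$ok)
  expect_equal(chk$violations$atom, 2L)
  expect_equal(chk$violations$valence, 0L)

  # a lone H atom is fine when the H range includes zero
  expect_true(check_valences(molecular_graph("H"))$ok)
})

test_that("mass-weighted spectra have closed-form values on tiny systems", {
  m_h <- atom_spec("H")$mass
  expect_equal(mass_weighted_spectrum(molecular_graph("H")), m_h)
  h2 <- graph_from_bonds(c("H", "H"), list(c(1, 2)))
  expect_equal(mass_weighted_spectrum(h2), c(m_h - 1, m_h + 1))
})

test_that("mass-weighted spectra are permutation invariant and conserve trace", {
  set.seed(5)
  for (i in 1:15) {
    g <- random_valid_graph(sample(c("C", "H", "O", "N"),
                                   sample(2:6, 1), replace = TRUE))
    s <- mass_weighted_spectrum(g)
    expect_equal(sum(s), sum(g$atoms$mass))
    expect_equal(mass_weighted_spectrum(random_permutation_of_graph(g)), s)
  }
})

test_that("bonding-arrangement counts follow 2^(N(N-1)/2)", {
  expect_equal(count_bonding_arrangements(1), 1)
  expect_equal(count_bonding_arrangements(3), 8)
  expect_equal(count_bonding_arrangements(4), 64)
})
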