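test_that("the Eyring prefactor and exponential dependence are correct", {
  # kB*T/h at 300 K from CODATA constants
  expect_equal(tst_rate(rate_params(300, 0)), 6.25099e12,
               tolerance = 1e-5)
  expect_lt(tst_rate(rate_params(300, 100)), tst_rate(rate_params(300, 50)))
  # closed-form rate ratio for a 10 kJ/mol barrier difference
  ratio <- tst_rate(rate_params(300, 10)) / tst_rate(rate_params(300, 20))
  expect_equal(ratio, exp(10 / (8.314462618e-3 * 300)), tolerance = 1e-12)
})

test_that("relative rates reproduce the 5 kJ/mol error example", {
  expect_equal(round(relative_rate(5, 300), 2), 0.13)
  expect_equal(relative_rate(0, 300), 1.0)
  expect_equal(relative_rate(-5, 300), 7.4227, tolerance = 1e-4)
  # exact reciprocal identity
  set.seed(2)
  for (x in runif(10, -30, 30)) {
    expect_equal(relative_rate(x) * relative_rate(-x), 1.0,
                 tolerance = 1e-12)
  }
})

test_that("transmission coefficients scale the TST rate linearly", {
  expect_equal(corrected_rate(rate_params(300, 12, 1)),
               tst_rate(rate_params(300, 12)))
  expect_equal(corrected_rate(rate_params(300, 12, 0.5)),
               0.5 * tst_rate(rate_params(300, 12)))
  expect_equal(corrected_rate(rate_params(300, 0, 0.25)), 1.5627e12,
               tolerance = 1e-4)
  expect_error(rate_params(300, 0, 1.5), "transmission")
})

test_that("kinetic networks validate species references", {
  expect_error(kinetic_crn("A", list(list(reactants = c(Z = 1),
                                          products = c(A = 1), rate = 1)),
                           c(A = 1)),
               "unknown species")
})

test_that("an empty reaction set gives constant trajectories", {
  net <- kinetic_crn(c("A", "B"), list(), c(A = 10, B = 3))
  res <- ssa_simulate(net, t_end = 5, rng_seed = 1)
  tr <- res$trajectories[[1]]
  expect_equal(nrow(tr$counts), 1L)
  expect_equal(unname(tr$counts[1, ]), c(10, 3))
})

test_that("first-order decay matches the analytic mean within 3 SE", {
  net <- kinetic_crn(c("A", "B"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 1)),
                     c(A = 500, B = 0))
  res <- ssa_simulate(net, t_end = 2.5, rng_seed = 42, n_replicas = 200)
  for (t in c(0.5, 1, 2)) {
    counts <- ssa_counts_at(res, t, "A")
    expected <- 500 * exp(-t)
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  }
})

test_that("bimolecular SSA means track the mass-action ODE at high copy number", {
  skip_if_not_installed("deSolve")
  k <- 5e-4
  net <- kinetic_crn(c("A", "B", "C"),
                     list(list(reactants = c(A = 1, B = 1),
                               products = c(C = 1), rate = k)),
                     c(A = 400, B = 300, C = 0))
  res <- ssa_simulate(net, t_end = 10, rng_seed = 7, n_replicas = 100)
  ode <- deSolve::ode(y = c(A = 400, B = 300, C = 0),
                      times = c(0, 2, 5, 10),
                      func = function(t, y, p) {
                        r <- k * y["A"] * y["B"]
                        list(c(-r, -r, r))
                      }, parms = NULL)
  for (row in 2:4) {
    t <- ode[row, "time"]
    counts <- ssa_counts_at(res, t, "A")
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - ode[row, "A"]), 4 * se + 2)
  }
})

test_that("species changes equal stoichiometry times firings exactly", {
  net <- kinetic_crn(c("A", "B", "C"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 2),
                          list(reactants = c(B = 2), products = c(C = 1),
                               rate = 0.01)),
                     c(A = 80, B = 0, C = 0))
  res <- ssa_simulate(net, t_end = 4, rng_seed = 5, n_replicas = 5)
  for (tr in res$trajectories) {
    final <- tr$counts[nrow(tr$counts), ]
    expect_identical(unname(final),
                     unname(net$init_counts +
                              as.integer(tr$firings %*% net$stoich)))
  }
})

test_that("an irreversible reaction run to completion fires once per molecule", {
  net <- kinetic_crn(c("A", "B"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 1)),
                     c(A = 100, B = 0))
  res <- ssa_simulate(net, t_end = 1000, rng_seed = 3)
  expect_equal(res$trajectories[[1]]$firings, 100L)
})

test_that("reversible net flux vanishes at equilibrium", {
  net <- kinetic_crn(c("A", "B"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 1),
                          list(reactants = c(B = 1), products = c(A = 1),
                               rate = 1)),
                     c(A = 200, B = 200))
  res <- ssa_simulate(net, t_end = 5, rng_seed = 11, n_replicas = 40)
  fl <- reactive_flux(res)
  expect_equal(fl$reverse_of, c(2L, 1L))
  # net flux per trajectory is O(sqrt(total firings)); total ~ 2000
  expect_lt(abs(fl$net_flux[1]), 3 * sqrt(mean(fl$firings)))
})

test_that("parallel channels carry flux in proportion to their rates", {
  net <- kinetic_crn(c("A", "B", "C"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 1),
                          list(reactants = c(A = 1), products = c(C = 1),
                               rate = 9)),
                     c(A = 2000))
  res <- ssa_simulate(net, t_end = 100, rng_seed = 13, n_replicas = 20)
  fl <- reactive_flux(res)
  expect_equal(fl$firings[2] / fl$firings[1], 9, tolerance = 0.15)
  # the dominant channel defines the minimal sub-network
  expect_true(2L %in% fl$minimal)
})

test_that("SSA runs are seed-reproducible and export CSV", {
  net <- kinetic_crn(c("A", "B"),
                     list(list(reactants = c(A = 1), products = c(B = 1),
                               rate = 1)),
                     c(A = 50))
  a <- ssa_simulate(net, 2, rng_seed = 9)
  b <- ssa_simulate(net, 2, rng_seed = 9)
  expect_identical(a$trajectories[[1]]$times, b$trajectories[[1]]$times)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(a, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("time", "A", "B"))
  expect_equal(nrow(tab), length(a$trajectories[[1]]$times))
})
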