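# Transition-state-theory rate utilities and exact stochastic
# microkinetics (Gillespie direct method) with reactive-flux accounting.

# CODATA 2018 constants
.kB <- 1.380649e-23      # J/K
.h <- 6.62607015e-34     # J*s
.R_kJ <- 8.314462618e-3  # kJ/(mol*K)

#' TST rate parameters
#'
#' @param temperature Temperature (K, > 0).
#' @param activation_free_energy Activation free energy ΔG‡ (kJ/mol).
#' @param transmission_coefficient Transmission coefficient α(T) in
#'   (0, 1]; 1 is the standard TST assumption (no recrossing).
#' @return A `rate_params` list.
#' @export
rate_params <- function(temperature = 300, activation_free_energy = 0,
                        transmission_coefficient = 1) {
  stopifnot(temperature > 0,
            transmission_coefficient > 0, transmission_coefficient <= 1)
  structure(list(temperature = temperature,
                 activation_free_energy = activation_free_energy,
                 transmission_coefficient = transmission_coefficient),
            class = "rate_params")
}

#' Transition-state-theory rate constant
#'
#' Eyring form with the first-order prefactor convention:
#' `k = (kB*T/h) * exp(-dG / (R*T))` in 1/s.  Bimolecular rates need the
#' standard stochastic mass-action volume conversion before use as SSA
#' propensity constants.
#'
#' @param p A [rate_params()].
#' @return Rate constant (1/s); positive and monotone decreasing in the
#'   activation free energy.
#' @examples
#' tst_rate(rate_params(300, 0))   # kB*T/h at 300 K, about 6.25e12 /s
#' @export
tst_rate <- function(p) {
  (.kB * p$temperature / .h) *
    exp(-p$activation_free_energy / (.R_kJ * p$temperature))
}

#' Relative rate for an activation-energy error
#'
#' `exp(-ddG / (R*T))`: the factor by which a rate computed from an
#' activation free energy differing by `ddG` from the reference value
#' deviates from the reference rate.  A +5 kJ/mol error at 300 K gives
#' 0.13; the same error with opposite sign gives ~7.42.
#'
#' @param ddG Activation-free-energy difference (kJ/mol).
#' @param T Temperature (K, > 0).
#' @return Dimensionless ratio; `relative_rate(x) * relative_rate(-x)`
#'   is exactly 1.
#' @export
relative_rate <- function(ddG, T = 300) {
  stopifnot(T > 0)
  exp(-ddG / (.R_kJ * T))
}

#' Recrossing-corrected rate constant
#'
#' `k = alpha(T) * k_TST(T)`: the transmission coefficient scales the
#' TST rate down for dynamical recrossing of the dividing surface.
#'
#' @param p A [rate_params()].
#' @return Rate constant (1/s); equals [tst_rate()] when the
#'   transmission coefficient is 1.
#' @export
corrected_rate <- function(p) {
  p$transmission_coefficient * tst_rate(p)
}

#' Define a stochastic kinetic network
#'
#' @param species Character vector of species names.
#' @param reactions List of reactions; each a list with `reactants` and
#'   `products` (named non-negative integer vectors of stoichiometric
#'   counts over `species`) and `rate` (stochastic rate constant, whose
#'   units presume copy numbers — convert bimolecular macroscopic
#'   constants by the reaction volume first).
#' @param init_counts Named integer vector of initial copy numbers.
#' @return A `kinetic_crn`.
#' @examples
#' net <- kinetic_crn(c("A", "B"),
#'                    list(list(reactants = c(A = 1), products = c(B = 1),
#'                              rate = 1)),
#'                    c(A = 100, B = 0))
#' @export
kinetic_crn <- function(species, reactions, init_counts) {
  stopifnot(is.character(species), !anyDuplicated(species))
  m <- length(reactions)
  n <- length(species)
  nu_in <- matrix(0L, m, n, dimnames = list(NULL, species))
  nu_out <- matrix(0L, m, n, dimnames = list(NULL, species))
  rates <- numeric(m)
  for (i in seq_len(m)) {
    rx <- reactions[[i]]
    for (side in c("reactants", "products")) {
      v <- rx[[side]]
      if (length(v) > 0L) {
        bad <- setdiff(names(v), species)
        if (length(bad) > 0L) {
          stop("reaction ", i, " references unknown species: ",
               paste(bad, collapse = ", "))
        }
        stopifnot(all(v >= 0), all(v == round(v)))
      }
    }
    if (length(rx$reactants) > 0L) nu_in[i, names(rx$reactants)] <- as.integer(rx$reactants)
    if (length(rx$products) > 0L) nu_out[i, names(rx$products)] <- as.integer(rx$products)
    stopifnot(rx$rate >= 0)
    rates[i] <- rx$rate
  }
  x0 <- integer(n)
  names(x0) <- species
  x0[names(init_counts)] <- as.integer(init_counts)
  stopifnot(all(x0 >= 0))
  structure(list(species = species, nu_in = nu_in, nu_out = nu_out,
                 stoich = nu_out - nu_in, rates = rates,
                 init_counts = x0),
            class = "kinetic_crn")
}

# Mass-action propensities: rate * number of distinct reactant
# combinations, prod_s choose(x_s, nu_s).
propensities <- function(net, x) {
  m <- nrow(net$nu_in)
  a <- net$rates
  for (i in seq_len(m)) {
    need <- net$nu_in[i, ]
    nz <- which(need > 0L)
    if (length(nz) > 0L) {
      a[i] <- a[i] * prod(choose(x[nz], need[nz]))
    }
  }
  a
}

#' Read a kinetic network from JSON
#'
#' Schema: `{"species": [...], "reactions": [{"reactants": {"A": 1},
#' "products": {"B": 1}, "rate": 1.0}, ...], "init_counts": {"A": 500}}`.
#'
#' @param input File path or JSON string.
#' @return A [kinetic_crn()].
#' @export
kinetic_crn_from_json <- function(input) {
  doc <- jsonlite::fromJSON(input, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  for (f in c("species", "reactions", "init_counts")) {
    if (is.null(doc[[f]])) stop("kinetic CRN JSON: missing field '", f, "'")
  }
  reactions <- lapply(doc$reactions, function(rx) {
    list(reactants = unlist(rx$reactants), products = unlist(rx$products),
         rate = rx$rate)
  })
  kinetic_crn(as.character(unlist(doc$species)), reactions,
              unlist(doc$init_counts))
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' @param net A [kinetic_crn()].
#' @param t_end Simulated time horizon.
#' @param rng_seed Integer seed; per-replica seeds are drawn from a
#'   parent stream seeded with it (consecutive integer seeds would give
#'   correlated Mersenne-Twister streams).
#' @param n_replicas Number of independent trajectories.
#' @return An `ssa_result`: list of trajectories, each with `times`
#'   (event times, starting at 0), `counts` (per-event species counts,
#'   one row per recorded time) and `firings` (total firings per
#'   reaction).  Copy-number changes equal stoichiometry times firings
#'   exactly.
#' @export
ssa_simulate <- function(net, t_end, rng_seed = 1L, n_replicas = 1L) {
  stopifnot(inherits(net, "kinetic_crn"), t_end > 0, n_replicas >= 1L)
  m <- nrow(net$nu_in)
  replica_seeds <- with_rng_seed(rng_seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            n_replicas))
  trajs <- lapply(seq_len(n_replicas), function(rep) {
    with_rng_seed(replica_seeds[[rep]], {
      x <- net$init_counts
      t <- 0
      cap <- 1024L
      times <- numeric(cap)
      counts <- matrix(0L, cap, length(x))
      k <- 1L
      times[1L] <- 0
      counts[1L, ] <- x
      firings <- integer(m)
      repeat {
        a <- propensities(net, x)
        a0 <- sum(a)
        if (a0 <= 0) break
        t <- t + stats::rexp(1L, a0)
        if (t > t_end) break
        j <- sample.int(m, 1L, prob = a)
        x <- x + net$stoich[j, ]
        firings[j] <- firings[j] + 1L
        k <- k + 1L
        if (k > cap) {
          cap <- cap * 2L
          length(times) <- cap
          counts <- rbind(counts, matrix(0L, cap - nrow(counts),
                                         ncol(counts)))
        }
        times[k] <- t
        counts[k, ] <- x
      }
      colnames(counts) <- net$species
      list(times = times[seq_len(k)],
           counts = counts[seq_len(k), , drop = FALSE],
           firings = firings)
    })
  })
  structure(list(trajectories = trajs, net = net, t_end = t_end),
            class = "ssa_result")
}

#' Species counts at given times
#'
#' Piecewise-constant (last-event) interpolation of SSA trajectories.
#'
#' @param result An [ssa_simulate()] result.
#' @param times Numeric vector of query times.
#' @param species Species name.
#' @return Matrix (replicas x times) of copy numbers.
#' @export
ssa_counts_at <- function(result, times, species) {
  t(vapply(result$trajectories, function(tr) {
    idx <- findInterval(times, tr$times)
    tr$counts[pmax(idx, 1L), species]
  }, numeric(length(times))))
}

#' Write one SSA trajectory as CSV
#'
#' @param result An [ssa_simulate()] result.
#' @param path Output path.
#' @param replica Trajectory index.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path, replica = 1L) {
  tr <- result$trajectories[[replica]]
  utils::write.csv(data.frame(time = tr$times, tr$counts,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Reactive flux through each reaction
#'
#' Averages firing counts over replicas, nets forward and backward
#' firings for reversible pairs (reactions whose reactant and product
#' stoichiometries are mutually swapped), and extracts the sub-network
#' of reactions whose absolute net flux exceeds a fraction of the
#' dominant one — the "minimal CRN" carrying the bulk of the reactive
#' traffic.
#'
#' @param result An [ssa_simulate()] result.
#' @param fraction Keep reactions with `|net flux| >= fraction * max
#'   |net flux|`; default 0.1.
#' @return A list with `firings` (mean per-reaction firing counts),
#'   `reverse_of` (pairing index, NA for irreversible reactions),
#'   `net_flux` (mean forward-minus-reverse firings, reported on the
#'   forward member of each pair) and `minimal` (indices of the
#'   retained sub-network).
#' @export
reactive_flux <- function(result, fraction = 0.1) {
  net <- result$net
  m <- nrow(net$nu_in)
  fir <- rowMeans(vapply(result$trajectories, `[[`, numeric(m), "firings"))
  reverse_of <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (!is.na(reverse_of[i])) next
    for (j in seq_len(m)) {
      if (i != j && is.na(reverse_of[j]) &&
          identical(net$nu_in[i, ], net$nu_out[j, ]) &&
          identical(net$nu_out[i, ], net$nu_in[j, ])) {
        reverse_of[i] <- j
        reverse_of[j] <- i
        break
      }
    }
  }
  net_flux <- fir
  for (i in seq_len(m)) {
    if (!is.na(reverse_of[i])) net_flux[i] <- fir[i] - fir[reverse_of[i]]
  }
  dominant <- max(abs(net_flux))
  minimal <- if (dominant > 0) which(abs(net_flux) >= fraction * dominant)
             else integer(0)
  list(firings = fir, reverse_of = reverse_of, net_flux = net_flux,
       minimal = minimal)
}
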