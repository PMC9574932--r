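# Double-ended graph-driven search (DEGDS): a mechanism is an ordered
# sequence of at most N_r reaction events (identity steps fill unused
# slots, keeping the search space fixed-dimensional); the sequence is
# optimized by simulated annealing against a cost that vanishes exactly
# when the propagated graph reaches the target.

#' Construct a mechanism
#'
#' @param events List of `reaction_event`s and/or `NULL`s (identity
#'   steps); shorter lists are padded with identities up to `n_r_max`.
#' @param n_r_max Maximum number of elementary steps N_r.
#' @return An object of class `mechanism`.
#' @export
mechanism <- function(events = list(), n_r_max = max(1L, length(events))) {
  stopifnot(n_r_max >= 1L, length(events) <= n_r_max)
  for (ev in events) {
    if (!is.null(ev) && !inherits(ev, "reaction_event")) {
      stop("mechanism events must be reaction_event objects or NULL")
    }
  }
  length(events) <- n_r_max
  structure(list(events = events, n_r_max = as.integer(n_r_max)),
            class = "mechanism")
}

#' Number of non-identity steps in a mechanism
#' @param mech A `mechanism`.
#' @return Integer.
#' @export
mechanism_length <- function(mech) {
  sum(!vapply(mech$events, is.null, logical(1)))
}

#' @export
print.mechanism <- function(x, ...) {
  cat("<mechanism> ", mechanism_length(x), " step(s) (N_r = ", x$n_r_max,
      ")\n", sep = "")
  for (ev in x$events) {
    if (!is.null(ev)) {
      cat("  ", ev$class_ref$name, "(",
          paste(ev$atom_indices, collapse = ", "), ")\n", sep = "")
    }
  }
  invisible(x)
}

# Canonical string for deduplication: identity steps dropped, each event
# as class(orbit-canonical tuple).
mechanism_signature <- function(mech) {
  paste(vapply(Filter(Negate(is.null), mech$events), function(ev) {
    canon <- orbit_representative(ev$atom_indices,
                                  ev$class_ref$automorphisms)
    paste0(ev$class_ref$name, "(", paste(canon, collapse = ","), ")")
  }, character(1)), collapse = ";")
}

#' Invert a mechanism
#'
#' Reverses the step order and swaps every class's before/after pattern;
#' propagating a mechanism and then its inverse restores the starting
#' graph.
#'
#' @param mech A `mechanism`.
#' @return The inverse `mechanism`.
#' @export
reverse_mechanism <- function(mech) {
  evs <- Filter(Negate(is.null), mech$events)
  inv <- lapply(rev(evs), function(ev) {
    reaction_event(reverse_class(ev$class_ref), ev$atom_indices)
  })
  mechanism(inv, mech$n_r_max)
}

#' Propagate a mechanism from a starting graph
#'
#' Applies the events left to right; identity steps leave the graph
#' unchanged.  A step whose pattern no longer matches, or whose product
#' violates valence constraints, stops propagation and yields a failure
#' value carrying the failing step index — not an exception, since
#' failed sequences are ordinary visitors during a search.
#'
#' @param g0 Starting `molecular_graph`.
#' @param mech A `mechanism`.
#' @param enforce_valence Check each step's product against valence
#'   constraints.
#' @return The final `molecular_graph`, or a `propagation_failure` with
#'   fields `step`, `reason` (`"pattern_mismatch"` or `"valence"`) and
#'   `graph` (last valid graph).
#' @export
propagate_mechanism <- function(g0, mech, enforce_valence = TRUE) {
  propagate_events(g0, mech$events, enforce_valence)
}

# Events-list propagation core shared by the public wrapper and the
# annealing hot loop.
propagate_events <- function(g0, events, enforce_valence = TRUE) {
  g <- g0
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (is.null(ev)) next
    if (!tuple_matches(g, ev$class_ref, ev$atom_indices)) {
      return(structure(list(step = i, reason = "pattern_mismatch",
                            graph = g),
                       class = "propagation_failure"))
    }
    res <- apply_event(g, ev, enforce_valence)
    if (is_rejection(res)) {
      return(structure(list(step = i, reason = "valence", graph = g,
                            violations = res$violations),
                       class = "propagation_failure"))
    }
    g <- res
  }
  g
}

#' Is a value a propagation failure?
#' @param x Any value.
#' @return Logical.
#' @export
is_propagation_failure <- function(x) inherits(x, "propagation_failure")

#' Intermediate graphs along a mechanism
#'
#' @param g0 Starting graph.
#' @param mech A `mechanism`.
#' @return List of graphs, one per non-identity step (reactants not
#'   included); errors if the mechanism does not propagate cleanly.
#' @export
mechanism_intermediates <- function(g0, mech) {
  g <- g0
  out <- list()
  for (ev in Filter(Negate(is.null), mech$events)) {
    g <- apply_event(g, ev, enforce_valence = TRUE)
    if (is_rejection(g)) stop("mechanism does not propagate cleanly")
    out[[length(out) + 1L]] <- g
  }
  out
}

#' Cost specification for double-ended search
#'
#' Two modes. `"elementwise"` compares the whole-system adjacency matrix
#' entry by entry against a full target graph (each unordered pair
#' counted once); it is cheap but requires the target atom indexing to
#' be fixed in advance and scores permuted copies of the product as
#' nonzero.  `"product_spectral"` scans the molecules of the propagated
#' graph for one matching a single target molecule by the eigenvalue
#' spectrum of the mass-weighted bonding graph; molecules with the wrong
#' atom count contribute the penalty `delta_penalty`, and the cost is
#' the minimum over molecules — zero for any isomorphic copy of the
#' target regardless of atom indexing.
#'
#' @param mode `"elementwise"` or `"product_spectral"`.
#' @param target Target `molecular_graph`: the full system graph for
#'   elementwise mode, a single connected molecule for spectral mode.
#' @param delta_penalty Penalty assigned when no molecule has the target
#'   atom count (amu^2 units); must exceed any achievable spectral
#'   distance on the system.  Default 1e6.
#' @param zero_tol Spectral distances below this value (amu^2) are
#'   snapped to exactly zero; distances between spectra of isomorphic
#'   graphs are pure eigenvalue roundoff (~1e-25), while genuinely
#'   different small graphs sit many orders of magnitude above the
#'   default of 1e-9.
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(mode = c("elementwise", "product_spectral"), target,
                      delta_penalty = 1e6, zero_tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "molecular_graph"), delta_penalty > 0,
            zero_tol >= 0)
  spectrum <- NULL
  if (mode == "product_spectral") {
    if (max(connected_components(target$adjacency)) != 1L) {
      stop("product_spectral target must be a single connected molecule")
    }
    spectrum <- mass_weighted_spectrum(target)
  }
  structure(list(mode = mode, target = target,
                 delta_penalty = delta_penalty, zero_tol = zero_tol,
                 target_spectrum = spectrum),
            class = "cost_spec")
}

#' Element-wise graph distance
#'
#' Sum of squared adjacency differences over unordered atom pairs; zero
#' exactly for identical matrices.  Not permutation invariant: an
#' atom-relabeled copy of the target scores positive.
#'
#' @param g,target `molecular_graph`s over the same atom list/order.
#' @return Non-negative scalar.
#' @export
cost_elementwise <- function(g, target) {
  if (n_atoms(g) != n_atoms(target)) {
    stop("graphs must have the same atom count")
  }
  d <- g$adjacency - target$adjacency
  sum(d[upper.tri(d)]^2)
}

#' Permutation-invariant spectral product cost
#'
#' For every molecule in `g` with the same atom count as the target, the
#' squared distance between sorted mass-weighted spectra is evaluated;
#' molecules of any other size contribute `delta_penalty`.  The cost is
#' the minimum over molecules, and is zero for any permuted isomorphic
#' copy of the target.  (Cospectral non-isomorphic impostors also score
#' zero here; [anneal_search()] guards against them by an explicit
#' isomorphism check before accepting a solution.)
#'
#' @param g A `molecular_graph` (whole system).
#' @param spec A [cost_spec()] with mode `"product_spectral"`.
#' @return Non-negative scalar (at most `delta_penalty`).
#' @export
cost_product <- function(g, spec) {
  stopifnot(inherits(spec, "cost_spec"), spec$mode == "product_spectral")
  if (n_atoms(g) == 0L) return(spec$delta_penalty)
  n_target <- n_atoms(spec$target)
  comp <- connected_components(g$adjacency)
  masses <- g$atoms$mass
  best <- spec$delta_penalty
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) != n_target) next
    d <- sum((component_spectrum(g$adjacency, masses, idx) -
                spec$target_spectrum)^2)
    if (d <= spec$zero_tol) d <- 0
    if (d < best) best <- d
  }
  best
}

# Mass-weighted spectrum of one connected component without building an
# intermediate graph object (hot path of the spectral cost).
component_spectrum <- function(adj, masses, idx) {
  m <- adj[idx, idx, drop = FALSE]
  storage.mode(m) <- "double"
  diag(m) <- masses[idx]
  sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
}

# Unified mechanism cost: propagate, then score.  Propagation failures
# cost the penalty value so they are never preferred over any valid
# sequence.
events_cost <- function(g0, events, spec) {
  g <- propagate_events(g0, events, enforce_valence = TRUE)
  if (is_propagation_failure(g)) return(spec$delta_penalty * 2)
  if (spec$mode == "elementwise") cost_elementwise(g, spec$target)
  else cost_product(g, spec)
}

mechanism_cost <- function(g0, mech, spec) {
  events_cost(g0, mech$events, spec)
}

# For a zero-cost state in spectral mode, confirm a genuinely isomorphic
# product molecule exists (cospectral impostors are rejected).
solution_verified <- function(g0, events, spec) {
  g <- propagate_events(g0, events, enforce_valence = TRUE)
  if (is_propagation_failure(g)) return(FALSE)
  if (spec$mode == "elementwise") {
    return(cost_elementwise(g, spec$target) == 0)
  }
  n_target <- n_atoms(spec$target)
  comp <- connected_components(g$adjacency)
  masses <- g$atoms$mass
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) != n_target) next
    d <- sum((component_spectrum(g$adjacency, masses, idx) -
                spec$target_spectrum)^2)
    if (d <= spec$zero_tol &&
        graphs_isomorphic(induced_subgraph_mg(g, idx), spec$target)) {
      return(TRUE)
    }
  }
  FALSE
}

# Constraint-guided sampler for one tuple matching rc$before on `graph`:
# slots are placed one by one, each drawn from the atoms consistent with
# the pattern relative to already-placed slots.  Returns NULL when no
# match is found within `ntry` attempts.  Not uniform over matches; used
# only as a proposal distribution.
sample_match <- function(graph, rc, active_atoms = NULL, ntry = 30L) {
  n <- n_atoms(graph)
  pool <- if (is.null(active_atoms)) seq_len(n) else as.integer(active_atoms)
  if (length(pool) < rc$arity) return(NULL)
  for (try in seq_len(ntry)) {
    idx <- integer(0)
    ok <- TRUE
    for (s in seq_len(rc$arity)) {
      cand <- setdiff(pool, idx)
      f <- if (is.null(rc$element_filters)) NULL else rc$element_filters[[s]]
      if (!is.null(f)) cand <- cand[graph$atoms$symbol[cand] %in% f]
      if (length(idx) > 0L) {
        for (t in seq_along(idx)) {
          need <- rc$before[s, t]
          cand <- cand[graph$adjacency[cand, idx[t]] == need]
          if (length(cand) == 0L) break
        }
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      idx <- c(idx, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    if (ok && tuple_matches(graph, rc, idx)) return(idx)
  }
  NULL
}

#' Simulated-annealing configuration for mechanism search
#'
#' @param t_init,t_final Initial/final annealing temperatures (cost
#'   units, > 0).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param steps_per_temp Metropolis proposals per temperature.
#' @param move_weights Probabilities of the four move types: resample a
#'   step's class, resample a step's atom tuple, swap two steps,
#'   set/unset an identity step.
#' @param rng_seed Integer seed.
#' @param max_restarts Maximum number of independent annealing runs.
#' @return An `anneal_config` list.
#' @export
anneal_config <- function(t_init = 20, t_final = 0.02, cooling = 0.95,
                          steps_per_temp = 40L,
                          move_weights = c(class = 0.3, tuple = 0.4,
                                           swap = 0.15, identity = 0.15),
                          rng_seed = 1L, max_restarts = 10L) {
  stopifnot(t_init > 0, t_final > 0, t_final <= t_init,
            cooling > 0, cooling < 1, steps_per_temp >= 1L,
            length(move_weights) == 4L, all(move_weights >= 0),
            max_restarts >= 1L)
  structure(list(t_init = t_init, t_final = t_final, cooling = cooling,
                 steps_per_temp = as.integer(steps_per_temp),
                 move_weights = move_weights / sum(move_weights),
                 rng_seed = as.integer(rng_seed),
                 max_restarts = as.integer(max_restarts)),
            class = "anneal_config")
}

# Propose a modification of `mech` (list of events, possibly NULL).
# Returns the new events list or NULL when the move could not be built.
propose_move <- function(g0, events, classes, weights, active_atoms) {
  n_r <- length(events)
  move <- sample(c("class", "tuple", "swap", "identity"), 1L,
                 prob = weights)
  pos <- sample.int(n_r, 1L)
  # graph reached just before step `pos`
  g <- g0
  if (pos > 1L) {
    g <- propagate_events(g0, events[seq_len(pos - 1L)],
                          enforce_valence = TRUE)
    if (is_propagation_failure(g)) return(NULL)
  }
  new_events <- events
  if (move == "swap") {
    if (n_r < 2L) return(NULL)
    pos2 <- sample(setdiff(seq_len(n_r), pos), 1L)
    new_events[c(pos, pos2)] <- new_events[c(pos2, pos)]
    return(new_events)
  }
  if (move == "identity" && !is.null(events[[pos]])) {
    new_events[pos] <- list(NULL)
    return(new_events)
  }
  # class / tuple resample, or filling an identity slot: draw an event
  # valid on the graph at this position
  rc <- if (move == "tuple" && !is.null(events[[pos]])) {
    events[[pos]]$class_ref
  } else {
    classes[[sample.int(length(classes), 1L)]]
  }
  idx <- sample_match(g, rc, active_atoms)
  if (is.null(idx)) return(NULL)
  new_events[[pos]] <- reaction_event(rc, idx)
  new_events
}

#' Double-ended mechanism search by simulated annealing
#'
#' Optimizes a fixed-length sequence of reaction events (identity steps
#' allowed) connecting the reactant graph to the target defined by
#' `spec`, using Metropolis-accepted random sequence edits under a
#' geometric cooling schedule.  Independent restarts (fresh seeds
#' derived from `cfg$rng_seed`) run until `n_mechs` distinct zero-cost
#' mechanisms are collected or `cfg$max_restarts` runs are exhausted.
#' Every returned mechanism is re-verified by propagation plus cost
#' evaluation (including the isomorphism guard in spectral mode).
#'
#' @param reactants Valence-valid starting `molecular_graph`.
#' @param spec A [cost_spec()].
#' @param classes Reaction-class list.
#' @param n_r Maximum number of elementary steps N_r.
#' @param cfg An [anneal_config()].
#' @param n_mechs Number of distinct mechanisms requested.
#' @param active_atoms Optional reactive atom subset.
#' @return List of `mechanism`s (possibly empty), with attribute
#'   `"diagnostics"`: per-restart best-cost traces.
#' @examples
#' h2o_sys <- graph_from_bonds(c("O", "H", "H"), list(c(2, 3)))
#' target <- graph_from_bonds(c("O", "H", "H"), list(c(1, 2), c(1, 3)))
#' found <- anneal_search(h2o_sys, cost_spec("product_spectral", target),
#'                        builtin_library(), n_r = 2,
#'                        anneal_config(rng_seed = 3, max_restarts = 3))
#' length(found) > 0
#' @export
anneal_search <- function(reactants, spec, classes, n_r = 4L,
                          cfg = anneal_config(), n_mechs = 1L,
                          active_atoms = NULL) {
  stopifnot(n_r >= 1L, n_mechs >= 1L)
  chk <- check_valences(reactants)
  if (!chk$ok) stop("reactant graph violates valence constraints")
  classes <- unname(classes)
  with_rng_seed(cfg$rng_seed, {
    found <- list()
    signatures <- character(0)
    diagnostics <- list()
    for (restart in seq_len(cfg$max_restarts)) {
      events <- vector("list", n_r)   # all-identity start
      cur_cost <- events_cost(reactants, events, spec)
      best_cost <- cur_cost
      trace <- cur_cost
      temp <- cfg$t_init
      solved <- cur_cost == 0 && solution_verified(reactants, events, spec)
      while (!solved && temp >= cfg$t_final) {
        for (s in seq_len(cfg$steps_per_temp)) {
          cand <- propose_move(reactants, events, classes,
                               cfg$move_weights, active_atoms)
          if (is.null(cand)) next
          cand_cost <- events_cost(reactants, cand, spec)
          if (cand_cost <= cur_cost ||
              stats::runif(1) < exp((cur_cost - cand_cost) / temp)) {
            events <- cand
            cur_cost <- cand_cost
            if (cur_cost < best_cost) best_cost <- cur_cost
            if (cur_cost == 0) {
              if (solution_verified(reactants, events, spec)) {
                solved <- TRUE
                break
              }
              # cospectral impostor: keep searching away from it
              cur_cost <- spec$delta_penalty
            }
          }
        }
        trace <- c(trace, best_cost)
        temp <- temp * cfg$cooling
      }
      diagnostics[[restart]] <- list(best_cost = best_cost, trace = trace,
                                     solved = solved)
      if (solved) {
        mech <- mechanism(events, n_r)
        sig <- mechanism_signature(mech)
        if (!sig %in% signatures) {
          signatures <- c(signatures, sig)
          found[[length(found) + 1L]] <- mech
          if (length(found) >= n_mechs) break
        }
      }
    }
    attr(found, "diagnostics") <- diagnostics
    found
  })
}

#' Rank mechanisms by energy-landscape roughness
#'
#' Given one energy per intermediate (starting with the reactant state;
#' kJ/mol, user-supplied or from any external evaluator), two
#' descriptors summarize how rough a mechanism's energy profile is:
#' `A`, the maximum step-to-step energy increase (0 for downhill or flat
#' profiles), and `B`, the root-mean-square step energy change.  A
#' mechanism is flagged barrierless when no intermediate lies above the
#' reactant energy by more than `tol`.  Mechanisms are ranked ascending
#' by `(A, B)`, ties broken by mechanism length (shorter first).
#'
#' @param mechs List of `mechanism`s.
#' @param step_energies List of numeric vectors; element `i` holds the
#'   energies of mechanism `i`'s states, length `mechanism_length + 1`
#'   (reactants first).
#' @param tol Barrierless tolerance (kJ/mol).
#' @return A data frame with columns `mechanism` (input index), `A`,
#'   `B`, `barrierless`, `n_steps`, ordered by rank.
#' @examples
#' m <- mechanism(list(), 2)
#' rank_mechanisms(list(m), list(c(0, -10, -30)))
#' @export
rank_mechanisms <- function(mechs, step_energies, tol = 1e-6) {
  stopifnot(length(mechs) == length(step_energies))
  rows <- lapply(seq_along(mechs), function(i) {
    e <- step_energies[[i]]
    n_steps <- length(e) - 1L
    expected <- mechanism_length(mechs[[i]])
    if (expected > 0L && n_steps != expected) {
      stop("mechanism ", i, ": ", length(e), " energies supplied but ",
           expected, " steps require ", expected + 1L)
    }
    d <- diff(e)
    data.frame(mechanism = i,
               A = if (length(d) == 0L) 0 else max(0, max(d)),
               B = if (length(d) == 0L) 0 else sqrt(mean(d^2)),
               barrierless = all(e - e[1] <= tol),
               n_steps = n_steps)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$A, tab$B, tab$n_steps), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
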