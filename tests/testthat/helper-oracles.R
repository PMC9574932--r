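# Brute-force oracles kept independent of the implementation paths they
# check.

# Are two element-labeled graphs isomorphic?  Tries every atom
# permutation that preserves element labels (feasible up to ~6 atoms).
brute_force_isomorphic <- function(symbols1, adj1, symbols2, adj2) {
  n <- length(symbols1)
  if (n != length(symbols2)) return(FALSE)
  if (!identical(sort(symbols1), sort(symbols2))) return(FALSE)
  perms <- all_permutations(n)
  for (p in perms) {
    if (identical(symbols1[p], symbols2) &&
        identical(adj1[p, p, drop = FALSE], adj2)) {
      return(TRUE)
    }
  }
  FALSE
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, pos)
  }
  out
}

# All binary symmetric zero-diagonal matrices on n atoms.
all_adjacencies <- function(n) {
  npair <- n * (n - 1L) / 2L
  lapply(seq_len(2^npair) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npair)]
    m <- matrix(0L, n, n)
    m[upper.tri(m)] <- bits
    m + t(m)
  })
}

# Exhaustive enumeration of all mechanisms of length <= max_steps over a
# class library, returning TRUE as soon as one reaches the target
# defined by `spec` (verified by an independent final-state check:
# element-wise equality for elementwise mode, label-aware isomorphism of
# some product molecule for spectral mode).
exhaustive_mechanism_exists <- function(g0, classes, spec, max_steps) {
  reaches_target <- function(g) {
    if (spec$mode == "elementwise") {
      return(identical(g$adjacency, spec$target$adjacency))
    }
    for (mol in split_molecules(g)) {
      if (n_atoms(mol$graph) == n_atoms(spec$target) &&
          brute_force_isomorphic(mol$graph$atoms$symbol,
                                 mol$graph$adjacency,
                                 spec$target$atoms$symbol,
                                 spec$target$adjacency)) {
        return(TRUE)
      }
    }
    FALSE
  }
  frontier <- list(g0)
  if (reaches_target(g0)) return(TRUE)
  for (depth in seq_len(max_steps)) {
    nxt <- list()
    for (g in frontier) {
      for (rc in classes) {
        for (t in enumerate_matches(g, rc)) {
          res <- apply_event(g, reaction_event(rc, t),
                             enforce_valence = TRUE)
          if (is_rejection(res)) next
          if (reaches_target(res)) return(TRUE)
          nxt[[length(nxt) + 1L]] <- res
        }
      }
    }
    frontier <- nxt
  }
  FALSE
}

# Random valence-valid molecular graph on the given element symbols,
# built by random valid association events from the edgeless graph.
random_valid_graph <- function(symbols, n_events = 6L) {
  g <- molecular_graph(symbols)
  lib <- builtin_library()
  for (i in seq_len(n_events)) {
    matches <- enumerate_matches(g, lib$association)
    if (length(matches) == 0L) break
    t <- matches[[sample.int(length(matches), 1L)]]
    res <- apply_event(g, reaction_event(lib$association, t),
                       enforce_valence = TRUE)
    if (!is_rejection(res)) g <- res
  }
  g
}

# All (class, tuple) events applicable to a graph.
all_matching_events_for_test <- function(g, classes) {
  out <- list()
  for (rc in classes) {
    for (t in enumerate_matches(g, rc)) {
      out[[length(out) + 1L]] <- reaction_event(rc, t)
    }
  }
  out
}

random_permutation_of_graph <- function(g) {
  p <- sample(n_atoms(g))
  molecular_graph(g$atoms[p, , drop = FALSE],
                  g$adjacency[p, p, drop = FALSE])
}
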