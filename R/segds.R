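# Single-ended graph-driven search (SEGDS): grow a CRN from reactants by
# repeatedly applying randomly selected reaction classes to randomly
# selected atom tuples, subject to valence constraints.

#' Configuration for single-ended exploration
#'
#' @param n_iterations Number of exploration iterations (>= 1).
#' @param max_events_per_step Maximum chained events applied per
#'   iteration before returning to node selection (default 1).
#' @param active_atoms Optional atom-index subset; only tuples drawn
#'   entirely from these atoms react, all other bonding is frozen.
#' @param rng_seed Integer seed; runs are reproducible given the seed.
#' @return An `explore_config` list.
#' @export
explore_config <- function(n_iterations = 200L, max_events_per_step = 1L,
                           active_atoms = NULL, rng_seed = 1L) {
  stopifnot(n_iterations >= 1L, max_events_per_step >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 max_events_per_step = as.integer(max_events_per_step),
                 active_atoms = active_atoms,
                 rng_seed = as.integer(rng_seed)),
            class = "explore_config")
}

# Evaluate `expr` under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# All (class, tuple) events whose before pattern matches `graph`.
all_matching_events <- function(graph, classes, active_atoms = NULL) {
  out <- list()
  for (rc in classes) {
    for (t in enumerate_matches(graph, rc, active_atoms)) {
      out[[length(out) + 1L]] <- reaction_event(rc, t)
    }
  }
  out
}

#' Single-ended graph-driven exploration
#'
#' At every iteration a known system state is chosen uniformly at
#' random, then a valence-valid reaction event uniformly at random among
#' all events applicable to it (pattern matches are tried in random
#' order and valence-rejected ones skipped); the resulting product state
#' and the connecting reaction are added to the network.  Node and edge
#' sets grow monotonically; states with no valid event simply contribute
#' nothing for that iteration, so exploration restarts from some other
#' known state (initially, the reactants).
#'
#' @param reactants A valence-valid `molecular_graph` of the full
#'   reactant system.
#' @param classes Reaction-class list, e.g. [builtin_library()].
#' @param cfg An [explore_config()].
#' @return A `crn` whose nodes all pass [check_valences()] and whose
#'   edges each correspond to exactly one applied event.  A per-iteration
#'   node/edge count trace is attached as attribute `"trace"`.
#' @examples
#' h2 <- graph_from_bonds(c("H", "H", "H", "H"),
#'                        list(c(1, 2), c(3, 4)))
#' net <- explore_single_ended(h2, builtin_library(),
#'                             explore_config(50, rng_seed = 7))
#' crn_summary(net)$n_nodes
#' @export
explore_single_ended <- function(reactants, classes,
                                 cfg = explore_config()) {
  stopifnot(inherits(reactants, "molecular_graph"))
  chk <- check_valences(reactants)
  if (!chk$ok) stop("reactant graph violates valence constraints")
  with_rng_seed(cfg$rng_seed, {
    crn <- crn_new()
    crn <- crn_add_node(crn, reactants)
    trace <- data.frame(iteration = integer(0), n_nodes = integer(0),
                        n_edges = integer(0))
    for (it in seq_len(cfg$n_iterations)) {
      key <- sample(names(crn$nodes), 1L)
      g <- crn$nodes[[key]]$graph
      for (sub in seq_len(cfg$max_events_per_step)) {
        events <- all_matching_events(g, classes, cfg$active_atoms)
        if (length(events) == 0L) break
        product <- NULL
        for (ev in sample(events)) {
          res <- apply_event(g, ev, enforce_valence = TRUE)
          if (!is_rejection(res)) {
            product <- res
            crn <- crn_add_edge(crn, g, product, ev)
            break
          }
        }
        if (is.null(product)) break
        g <- product
      }
      trace[nrow(trace) + 1L, ] <- c(it, length(crn$nodes),
                                     length(crn$edges))
    }
    attr(crn, "trace") <- trace
    crn
  })
}
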