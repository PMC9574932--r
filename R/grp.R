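# Graph-restraining potential (GRP): an artificial energy surface whose
# minima are exactly the geometries consistent with a target bonding
# graph.  Implemented as flat-bottom quadratic wells: a bonded pair is
# penalized only beyond (1 - margin) of its bonding cutoff, a nonbonded
# pair only below (1 + margin) of it, so any zero-energy configuration
# classifies strictly (never marginally) under the cutoff rule.

#' GRP parameters
#'
#' @param k_bond Force constant for stretched bonded pairs
#'   (energy/Angstrom^2).
#' @param k_rep Force constant for overlapping nonbonded pairs.
#' @param margin Fractional buffer on the bonding cutoff, in (0, 0.5);
#'   default 0.1.
#' @param alpha Cutoff scaling used for bond classification (matches
#'   [adjacency_from_geometry()]).
#' @param max_iter Maximum optimizer iterations per attempt.
#' @param grad_tol Convergence threshold on the gradient max-norm.
#' @param rng_seed Seed for random initialization/restarts.
#' @param max_restarts Maximum number of randomized restarts.
#' @return A `grp_params` list.
#' @export
grp_params <- function(k_bond = 1, k_rep = 1, margin = 0.1, alpha = 1.15,
                       max_iter = 500L, grad_tol = 1e-6, rng_seed = 1L,
                       max_restarts = 20L) {
  stopifnot(k_bond > 0, k_rep > 0, margin > 0, margin < 0.5, alpha > 0,
            max_iter >= 1L, grad_tol > 0, max_restarts >= 1L)
  structure(list(k_bond = k_bond, k_rep = k_rep, margin = margin,
                 alpha = alpha, max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, rng_seed = as.integer(rng_seed),
                 max_restarts = as.integer(max_restarts)),
            class = "grp_params")
}

#' GRP energy and gradient
#'
#' @param geom A [geometry()].
#' @param target A `molecular_graph` over the same atom list.
#' @param params A [grp_params()].
#' @return List with `energy` (non-negative scalar; zero exactly when
#'   every bonded pair lies inside and every nonbonded pair outside its
#'   buffered cutoff) and `gradient` (N x 3 matrix, the exact derivative
#'   of the energy).
#' @export
grp_energy_gradient <- function(geom, target, params = grp_params()) {
  n <- nrow(geom$atoms)
  if (n != n_atoms(target)) stop("geometry and target atom counts differ")
  if (!identical(geom$atoms$symbol, target$atoms$symbol)) {
    stop("geometry and target element lists differ")
  }
  coords <- geom$coords
  radii <- geom$atoms$covalent_radius
  energy <- 0
  grad <- matrix(0, n, 3)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dvec <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(dvec^2))
      r_safe <- max(r, 1e-8)
      rcut <- params$alpha * (radii[i] + radii[j])
      if (target$adjacency[i, j] == 1L) {
        bound <- (1 - params$margin) * rcut
        if (r > bound) {
          energy <- energy + 0.5 * params$k_bond * (r - bound)^2
          f <- params$k_bond * (r - bound) / r_safe
          grad[i, ] <- grad[i, ] + f * dvec
          grad[j, ] <- grad[j, ] - f * dvec
        }
      } else {
        bound <- (1 + params$margin) * rcut
        if (r < bound) {
          energy <- energy + 0.5 * params$k_rep * (bound - r)^2
          f <- -params$k_rep * (bound - r) / r_safe
          grad[i, ] <- grad[i, ] + f * dvec
          grad[j, ] <- grad[j, ] - f * dvec
        }
      }
    }
  }
  list(energy = energy, gradient = grad)
}

#' Back-transform a bonding graph into 3D coordinates
#'
#' Minimizes the GRP from a warm-start or random initialization until
#' the resulting geometry's recomputed adjacency equals the target graph
#' and the gradient max-norm is below `grad_tol`; randomized restarts
#' (fresh random placements) are taken on failure.  The round-trip
#' `adjacency_from_geometry(embed_graph(G)) == G` holds whenever the
#' embedding reports success.
#'
#' @param target A valence-valid `molecular_graph`.
#' @param init Optional starting [geometry()] (warm start).
#' @param params A [grp_params()].
#' @return On success, a [geometry()] with attribute `"embed_info"`
#'   (restarts used, optimizer evaluation counts, final energy).  On
#'   failure after all restarts, an `embedding_failure` object carrying
#'   the best-effort geometry and diagnostics — never a silently wrong
#'   geometry.
#' @examples
#' h2o <- graph_from_bonds(c("O", "H", "H"), list(c(1, 2), c(1, 3)))
#' gm <- embed_graph(h2o, params = grp_params(rng_seed = 1))
#' identical(adjacency_from_geometry(gm)$adjacency, h2o$adjacency)
#' @export
embed_graph <- function(target, init = NULL, params = grp_params()) {
  n <- n_atoms(target)
  box <- 1.5 * n   # cube edge: 1.5 Angstrom per atom per axis
  with_rng_seed(params$rng_seed, {
    best <- NULL
    best_energy <- Inf
    counts_total <- c(0, 0)
    for (attempt in seq_len(params$max_restarts)) {
      x0 <- if (attempt == 1L && !is.null(init)) {
        as.vector(init$coords)
      } else {
        stats::runif(3L * n, 0, box)
      }
      fn <- function(x) {
        gm <- geometry(target$atoms, matrix(x, n, 3))
        grp_energy_gradient(gm, target, params)$energy
      }
      gr <- function(x) {
        gm <- geometry(target$atoms, matrix(x, n, 3))
        as.vector(grp_energy_gradient(gm, target, params)$gradient)
      }
      opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = params$max_iter,
                                         factr = 10))
      counts_total <- counts_total + opt$counts
      gm <- geometry(target$atoms, matrix(opt$par, n, 3))
      eg <- grp_energy_gradient(gm, target, params)
      grad_norm <- max(abs(eg$gradient))
      recomputed <- tryCatch(
        adjacency_from_geometry(gm, alpha = params$alpha),
        error = function(e) NULL)
      if (!is.null(recomputed) &&
          identical(recomputed$adjacency, target$adjacency) &&
          grad_norm < params$grad_tol) {
        attr(gm, "embed_info") <- list(restarts = attempt,
                                       counts = counts_total,
                                       energy = eg$energy)
        return(gm)
      }
      if (eg$energy < best_energy) {
        best_energy <- eg$energy
        best <- gm
      }
    }
    structure(list(geometry = best, energy = best_energy,
                   restarts = params$max_restarts,
                   message = "no GRP minimum consistent with the target graph found"),
              class = "embedding_failure")
  })
}

#' Is a value an embedding failure?
#' @param x Any value.
#' @return Logical.
#' @export
is_embedding_failure <- function(x) inherits(x, "embedding_failure")

#' Geometries for every intermediate of a mechanism
#'
#' Applies the mechanism step by step and embeds each intermediate graph
#' with the GRP, seeding every embedding from the previous step's
#' geometry (warm start), so consecutive structures stay spatially
#' continuous.
#'
#' @param g0 Starting graph; `geom0` must be consistent with it.
#' @param geom0 Starting [geometry()].
#' @param mech A `mechanism` propagating cleanly from `g0`.
#' @param params A [grp_params()].
#' @return List of geometries, one per non-identity step.  If a step
#'   fails to embed, the list is truncated and carries attributes
#'   `"failure_index"` and `"failure"`.
#' @export
mechanism_geometries <- function(g0, geom0, mech, params = grp_params()) {
  check0 <- adjacency_from_geometry(geom0, alpha = params$alpha)
  if (!identical(check0$adjacency, g0$adjacency)) {
    stop("geom0 is not consistent with g0 under the cutoff rule")
  }
  out <- list()
  g <- g0
  geom <- geom0
  events <- Filter(Negate(is.null), mech$events)
  if (length(events) == 0L) return(list(geom0))
  for (k in seq_along(events)) {
    g_next <- apply_event(g, events[[k]], enforce_valence = TRUE)
    if (is_rejection(g_next)) stop("mechanism does not propagate cleanly")
    emb <- embed_graph(g_next, init = geom, params = params)
    if (is_embedding_failure(emb)) {
      attr(out, "failure_index") <- k
      attr(out, "failure") <- emb
      return(out)
    }
    out[[length(out) + 1L]] <- emb
    g <- g_next
    geom <- emb
  }
  out
}
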