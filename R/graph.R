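# Molecular bonding graphs: construction from geometry, species identity,
# valence accounting and spectral descriptors.
#
# A bonding graph is a symmetric binary adjacency matrix over an ordered
# atom list: entry (i, j) is 1 exactly when atoms i and j are closer than
# alpha * (R_i + R_j), with R the covalent radii.  The graph discretizes
# chemical space: differently bonded species have different graphs, while
# conformers (e.g. cis/trans isomers sharing one connectivity) collapse
# onto a single graph.

#' Construct a molecular bonding graph
#'
#' @param atoms Either a character vector of element symbols or an atom
#'   specification data frame from [atom_spec()].
#' @param adjacency N x N binary symmetric matrix with zero diagonal (or
#'   `NULL` for an edgeless graph).
#' @param ... Passed to [atom_spec()] when `atoms` is a symbol vector.
#' @return An object of class `molecular_graph` with fields `atoms` (the
#'   atom specification data frame) and `adjacency` (integer matrix).
#' @examples
#' g <- molecular_graph(c("H", "H"), matrix(c(0, 1, 1, 0), 2))
#' valence_vector(g)
#' @export
molecular_graph <- function(atoms, adjacency = NULL, ...) {
  if (is.character(atoms)) atoms <- atom_spec(atoms, ...)
  n <- nrow(atoms)
  if (is.null(adjacency)) adjacency <- matrix(0L, n, n)
  adjacency <- as_adjacency(adjacency, n)
  structure(list(atoms = atoms, adjacency = adjacency),
            class = "molecular_graph")
}

# Validate and coerce an adjacency matrix to integer 0/1, symmetric,
# zero-diagonal.
as_adjacency <- function(m, n) {
  m <- as.matrix(m)
  if (nrow(m) != n || ncol(m) != n) stop("adjacency must be ", n, " x ", n)
  if (any(!m %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  storage.mode(m) <- "integer"
  if (any(m != t(m))) stop("adjacency must be symmetric")
  if (any(diag(m) != 0L)) stop("adjacency diagonal must be zero")
  dimnames(m) <- NULL
  m
}

#' Construct a molecular graph from a 1-based bond list
#'
#' @param symbols Character vector of element symbols.
#' @param bonds List (or 2-column matrix) of 1-based atom-index pairs.
#' @param ... Passed to [atom_spec()].
#' @return A `molecular_graph`.
#' @examples
#' h2o <- graph_from_bonds(c("O", "H", "H"), list(c(1, 2), c(1, 3)))
#' @export
graph_from_bonds <- function(symbols, bonds = list(), ...) {
  n <- length(symbols)
  adj <- matrix(0L, n, n)
  if (is.matrix(bonds)) bonds <- asplit(bonds, 1)
  for (b in bonds) {
    stopifnot(length(b) == 2L, all(b >= 1), all(b <= n), b[1] != b[2])
    adj[b[1], b[2]] <- adj[b[2], b[1]] <- 1L
  }
  molecular_graph(symbols, adj, ...)
}

#' @export
print.molecular_graph <- function(x, ...) {
  n <- nrow(x$atoms)
  cat("<molecular_graph> ", n, " atoms [",
      paste(x$atoms$symbol, collapse = " "), "], ",
      sum(x$adjacency) / 2L, " bonds\n", sep = "")
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

#' Construct a molecular geometry
#'
#' @param atoms Element symbols or an [atom_spec()] data frame.
#' @param coords N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param ... Passed to [atom_spec()].
#' @return An object of class `geometry`.
#' @export
geometry <- function(atoms, coords, ...) {
  if (is.character(atoms)) atoms <- atom_spec(atoms, ...)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != nrow(atoms)) {
    stop("coords must be an N x 3 matrix matching the atom list")
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry> ", nrow(x$atoms), " atoms [",
      paste(x$atoms$symbol, collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' Derive the bonding graph from a geometry
#'
#' Two atoms are bonded exactly when their distance is below
#' `alpha * (R_i + R_j)`, with `R` the covalent radii.  `alpha` absorbs
#' the spread of real bond lengths around the radius sum; values around
#' 1.1-1.2 classify ordinary covalent structures robustly.
#'
#' @param geom A [geometry()].
#' @param alpha Dimensionless cutoff scaling factor (> 0); default 1.15.
#' @return A `molecular_graph` over the same atom list.
#' @examples
#' gm <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' adjacency_from_geometry(gm)$adjacency
#' @export
adjacency_from_geometry <- function(geom, alpha = 1.15) {
  stopifnot(inherits(geom, "geometry"), alpha > 0)
  n <- nrow(geom$atoms)
  d <- as.matrix(stats::dist(geom$coords))
  if (n > 1L && any(d[upper.tri(d)] == 0)) {
    stop("degenerate geometry: coincident atoms (zero interatomic distance)")
  }
  r <- geom$atoms$covalent_radius
  cutoff <- alpha * outer(r, r, `+`)
  adj <- (d < cutoff) * 1L
  diag(adj) <- 0L
  molecular_graph(geom$atoms, adj)
}

#' Split a system graph into its molecules
#'
#' Molecules are the connected components of the bonding graph.  The
#' original atom indices of each component are returned so that
#' system-level and molecule-level bookkeeping can be interconverted.
#'
#' @param graph A `molecular_graph` (possibly many molecules).
#' @return A list with one element per molecule, each a list with
#'   `graph` (the induced subgraph) and `indices` (original 1-based atom
#'   indices, ascending).  The index sets partition the atoms.
#' @export
split_molecules <- function(graph) {
  comp <- connected_components(graph$adjacency)
  lapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    list(graph = induced_subgraph_mg(graph, idx), indices = idx)
  })
}

# Component labels (1, 2, ...) in order of first atom occurrence.
# Plain BFS over the adjacency matrix: this sits inside the annealing
# hot loop, where building an igraph object per call would dominate.
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] == 1L & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

induced_subgraph_mg <- function(graph, idx) {
  molecular_graph(graph$atoms[idx, , drop = FALSE],
                  graph$adjacency[idx, idx, drop = FALSE])
}

#' Per-atom coordination numbers
#'
#' @param graph A `molecular_graph`.
#' @return Integer vector of row sums of the adjacency matrix.
#' @export
valence_vector <- function(graph) {
  as.integer(rowSums(graph$adjacency))
}

#' Check a graph against its per-element valence constraints
#'
#' Coordination numbers outside the allowed per-element range mark
#' nonphysical bonding; products failing this check are rejected during
#' searches without any energy evaluation.
#'
#' @param graph A `molecular_graph`.
#' @return A list with `ok` (logical) and `violations` (data frame with
#'   columns `atom`, `symbol`, `valence`, `v_min`, `v_max`; zero rows
#'   when `ok`).
#' @examples
#' h <- molecular_graph("H")
#' check_valences(h)$ok   # a lone H atom is allowed by default
#' @export
check_valences <- function(graph) {
  v <- valence_vector(graph)
  bad <- which(v < graph$atoms$v_min | v > graph$atoms$v_max)
  list(ok = length(bad) == 0L,
       violations = data.frame(atom = bad,
                               symbol = graph$atoms$symbol[bad],
                               valence = v[bad],
                               v_min = graph$atoms$v_min[bad],
                               v_max = graph$atoms$v_max[bad]))
}

#' Eigenvalue spectrum of the mass-weighted bonding graph
#'
#' The mass-weighted matrix is the adjacency matrix with the atomic
#' masses on the diagonal, `M = A + diag(m)`.  Its sorted eigenvalue
#' spectrum is invariant under atom permutation and sensitive to both
#' connectivity and element composition, which makes it a
#' permutation-invariant molecular descriptor (up to the usual caveat of
#' cospectral non-isomorphic graphs).
#'
#' @param graph A `molecular_graph`.
#' @return Numeric vector of eigenvalues in ascending order (length N).
#'   Their sum equals the total mass (trace conservation).
#' @export
mass_weighted_spectrum <- function(graph) {
  m <- graph$adjacency
  storage.mode(m) <- "double"
  diag(m) <- graph$atoms$mass
  sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
}

#' Number of conceivable bonding arrangements of N atoms
#'
#' Each unordered atom pair is independently bonded or not, giving
#' `2^(N(N-1)/2)` binary adjacency matrices — the raw size of discrete
#' chemical space before any valence filtering.
#'
#' @param n_atoms Integer >= 1.
#' @return The count as a double (exact up to 2^53).
#' @examples
#' count_bonding_arrangements(3)  # 8
#' @export
count_bonding_arrangements <- function(n_atoms) {
  stopifnot(n_atoms >= 1)
  2^(n_atoms * (n_atoms - 1) / 2)
}

# igraph view of a molecular graph, with element symbols as vertex colors
# (integer codes) for label-aware isomorphism machinery.
as_igraph_mg <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected")
  igraph::V(g)$color <- match(graph$atoms$symbol, supported_elements())
  g
}

#' Canonical species key
#'
#' A string identifier that is equal for any two atom-permuted copies of
#' the same element-labeled bonding graph and distinct for non-isomorphic
#' graphs.  Canonicalization uses BLISS canonical vertex ordering with
#' element labels as vertex colors; the key string is the element
#' sequence plus the upper-triangle bond bits in canonical order.
#'
#' @param graph A `molecular_graph`.
#' @return A single character string (class `species_key`).
#' @export
canonical_key <- function(graph) {
  n <- n_atoms(graph)
  if (n == 1L) {
    return(structure(paste0(graph$atoms$symbol, "|"), class = "species_key"))
  }
  ig <- as_igraph_mg(graph)
  perm <- igraph::canonical_permutation(
    ig, colors = igraph::V(ig)$color)$labeling
  ord <- order(perm)
  adj <- graph$adjacency[ord, ord, drop = FALSE]
  bits <- adj[upper.tri(adj)]
  structure(paste0(paste(graph$atoms$symbol[ord], collapse = ""), "|",
                   paste(bits, collapse = "")),
            class = "species_key")
}

#' Test two molecular graphs for element-labeled isomorphism
#'
#' VF2 isomorphism with element symbols as vertex colors.  Used, in
#' particular, as the exactness guard behind spectral product matching,
#' where cospectral non-isomorphic pairs must be told apart.
#'
#' @param g1,g2 `molecular_graph` objects.
#' @return Logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2)) return(FALSE)
  if (!identical(sort(g1$atoms$symbol), sort(g2$atoms$symbol))) return(FALSE)
  i1 <- as_igraph_mg(g1)
  i2 <- as_igraph_mg(g2)
  igraph::is_isomorphic_to(i1, i2, method = "vf2",
                           vertex.color1 = igraph::V(i1)$color,
                           vertex.color2 = igraph::V(i2)$color)
}

#' Molecular formula of a graph or atom set
#'
#' @param graph A `molecular_graph`.
#' @return Hill-ordered formula string (C first, H second, rest
#'   alphabetical), e.g. `"CH2O"`.
#' @export
molecular_formula <- function(graph) {
  syms <- graph$atoms$symbol
  cnt <- table(syms)
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (cnt[[s]] == 1L) s else paste0(s, cnt[[s]])
  }, character(1)), collapse = "")
}
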