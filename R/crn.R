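# Chemical reaction network container and serialization.
#
# Nodes are unique system bonding graphs keyed by their canonical species
# key; edges are elementary reactions (one applied reaction event)
# between node keys.  Species-level views are derived on demand by
# splitting system graphs into molecules, so both bookkeeping
# conventions (whole-system states vs individual species) are available
# from one store.

CRN_SCHEMA <- "grds-crn/1"

#' Create an empty chemical reaction network
#'
#' @return An object of class `crn` with empty node and edge sets.
#' @export
crn_new <- function() {
  structure(list(nodes = list(), edges = list()), class = "crn")
}

#' Add a system graph as a CRN node
#'
#' @param crn A `crn`.
#' @param graph A `molecular_graph` (whole system, possibly several
#'   molecules).
#' @param geometry Optional [geometry()] annotation.
#' @param free_energy Optional scalar free energy annotation (kJ/mol).
#' @return The updated `crn`; adding an already-known species is a
#'   no-op that preserves existing annotations.
#' @export
crn_add_node <- function(crn, graph, geometry = NULL, free_energy = NULL) {
  key <- as.character(canonical_key(graph))
  if (is.null(crn$nodes[[key]])) {
    crn$nodes[[key]] <- list(graph = graph, geometry = geometry,
                             free_energy = free_energy)
  }
  crn
}

#' Add an elementary reaction as a CRN edge
#'
#' Both endpoint graphs are added as nodes if absent.  Edges are
#' deduplicated by (reactant key, product key, class name): symmetric
#' events (e.g. breaking either of two equivalent C-H bonds) register as
#' one reaction.
#'
#' @param crn A `crn`.
#' @param from_graph,to_graph Reactant and product system graphs.
#' @param event The `reaction_event` transforming one into the other.
#' @param barrier,rate Optional kinetic annotations.
#' @return The updated `crn`.
#' @export
crn_add_edge <- function(crn, from_graph, to_graph, event,
                         barrier = NULL, rate = NULL) {
  crn <- crn_add_node(crn, from_graph)
  crn <- crn_add_node(crn, to_graph)
  from <- as.character(canonical_key(from_graph))
  to <- as.character(canonical_key(to_graph))
  id <- paste(from, to, event$class_ref$name, sep = " :: ")
  known <- vapply(crn$edges, `[[`, character(1), "id")
  if (!id %in% known) {
    crn$edges[[length(crn$edges) + 1L]] <-
      list(id = id, from = from, to = to,
           class = event$class_ref$name,
           atoms = event$atom_indices, barrier = barrier, rate = rate)
  }
  crn
}

#' @export
print.crn <- function(x, ...) {
  cat("<crn> ", length(x$nodes), " system states, ", length(x$edges),
      " reactions\n", sep = "")
  invisible(x)
}

#' Summarize a CRN
#'
#' @param crn A `crn`.
#' @return A list with `n_nodes`, `n_edges`, `species` (data frame of
#'   node keys with the molecular formulas of their constituent
#'   molecules) and `degree` (per-node in/out degree table).  Invariant
#'   under node insertion order.
#' @export
crn_summary <- function(crn) {
  keys <- sort(names(crn$nodes))
  species <- data.frame(
    key = keys,
    n_atoms = vapply(keys, function(k) n_atoms(crn$nodes[[k]]$graph),
                     integer(1)),
    molecules = vapply(keys, function(k) {
      mols <- split_molecules(crn$nodes[[k]]$graph)
      paste(sort(vapply(mols, function(m) molecular_formula(m$graph),
                        character(1))), collapse = " + ")
    }, character(1)),
    row.names = NULL)
  from <- vapply(crn$edges, `[[`, character(1), "from")
  to <- vapply(crn$edges, `[[`, character(1), "to")
  degree <- data.frame(
    key = keys,
    out_degree = vapply(keys, function(k) sum(from == k), integer(1)),
    in_degree = vapply(keys, function(k) sum(to == k), integer(1)),
    row.names = NULL)
  list(n_nodes = length(crn$nodes), n_edges = length(crn$edges),
       species = species, degree = degree)
}

#' Serialize a CRN to JSON
#'
#' The document is versioned (`schema` field) and deterministically
#' ordered (nodes by key, edges by id), so serialization is reproducible
#' and round-trips losslessly.
#'
#' @param crn A `crn`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
crn_to_json <- function(crn, path = NULL) {
  node_keys <- sort(names(crn$nodes))
  nodes <- lapply(node_keys, function(k) {
    nd <- crn$nodes[[k]]
    ut <- which(upper.tri(nd$graph$adjacency) & nd$graph$adjacency == 1L,
                arr.ind = TRUE)
    entry <- list(atoms = nd$graph$atoms$symbol,
                  bonds = unname(lapply(seq_len(nrow(ut)),
                                        function(i) as.integer(ut[i, ]))))
    if (!is.null(nd$geometry)) entry$coords <- unname(nd$geometry$coords)
    if (!is.null(nd$free_energy)) entry$free_energy <- nd$free_energy
    entry
  })
  names(nodes) <- node_keys
  edge_ids <- vapply(crn$edges, `[[`, character(1), "id")
  edges <- lapply(crn$edges[order(edge_ids)], function(e) {
    entry <- list(from = e$from, to = e$to, class = e$class,
                  atoms = e$atoms)
    if (!is.null(e$barrier)) entry$barrier <- e$barrier
    if (!is.null(e$rate)) entry$rate <- e$rate
    entry
  })
  doc <- list(schema = CRN_SCHEMA, nodes = nodes, edges = edges)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a CRN from JSON
#'
#' @param input File path or JSON string.
#' @param ... Passed to [atom_spec()] (e.g. valence overrides).
#' @return A `crn`.
#' @export
crn_from_json <- function(input, ...) {
  doc <- jsonlite::fromJSON(input, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(doc$schema) || doc$schema != CRN_SCHEMA) {
    stop("CRN parse error: field 'schema' missing or not '", CRN_SCHEMA, "'")
  }
  if (is.null(doc$nodes)) stop("CRN parse error: field 'nodes' missing")
  crn <- crn_new()
  lib <- builtin_library()
  for (key in names(doc$nodes)) {
    nd <- doc$nodes[[key]]
    if (is.null(nd$atoms)) {
      stop("CRN parse error: node '", key, "' lacks field 'atoms'")
    }
    g <- graph_from_bonds(as.character(unlist(nd$atoms)),
                          lapply(nd$bonds, as.integer), ...)
    geom <- NULL
    if (!is.null(nd$coords)) {
      geom <- geometry(g$atoms,
                       do.call(rbind, lapply(nd$coords, as.numeric)))
    }
    crn$nodes[[key]] <- list(graph = g, geometry = geom,
                             free_energy = nd$free_energy)
  }
  for (e in doc$edges) {
    for (f in c("from", "to", "class", "atoms")) {
      if (is.null(e[[f]])) stop("CRN parse error: edge lacks field '", f, "'")
    }
    if (is.null(crn$nodes[[e$from]]) || is.null(crn$nodes[[e$to]])) {
      stop("CRN parse error: edge references unknown node '",
           if (is.null(crn$nodes[[e$from]])) e$from else e$to, "'")
    }
    crn$edges[[length(crn$edges) + 1L]] <-
      list(id = paste(e$from, e$to, e$class, sep = " :: "),
           from = e$from, to = e$to, class = e$class,
           atoms = as.integer(unlist(e$atoms)),
           barrier = e$barrier, rate = e$rate)
  }
  crn
}

#' Export a CRN to GraphML for visualization
#'
#' Read-only convenience view (JSON is the authoritative format): nodes
#' carry the species-composition string, edges the class name.
#'
#' @param crn A `crn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
crn_to_graphml <- function(crn, path) {
  keys <- sort(names(crn$nodes))
  g <- igraph::make_empty_graph(n = length(keys), directed = TRUE)
  igraph::V(g)$name <- keys
  igraph::V(g)$composition <- vapply(keys, function(k) {
    mols <- split_molecules(crn$nodes[[k]]$graph)
    paste(sort(vapply(mols, function(m) molecular_formula(m$graph),
                      character(1))), collapse = " + ")
  }, character(1))
  for (e in crn$edges) {
    g <- igraph::add_edges(g, c(match(e$from, keys), match(e$to, keys)),
                           class = e$class)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
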