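# File formats: XYZ geometries and bonding-graph JSON.
# All on-disk atom indices are 1-based; coordinates are in Angstrom.

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom-count line, comment line, then `symbol x y z`
#' records.  Multi-frame files are supported via `frame`.
#'
#' @param path File path.
#' @param frame 1-based frame index for multi-frame files.
#' @param ... Passed to [atom_spec()].
#' @return A [geometry()].
#' @export
read_xyz <- function(path, frame = 1L, ...) {
  lines <- readLines(path)
  pos <- 1L
  fr <- 0L
  while (pos <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[[pos]])) {
      stop("malformed XYZ: expected atom count at line ", pos)
    }
    n <- as.integer(trimws(lines[[pos]]))
    fr <- fr + 1L
    if (fr == frame) {
      body <- lines[(pos + 2L):(pos + 1L + n)]
      toks <- strsplit(trimws(body), "\\s+")
      syms <- vapply(toks, `[[`, character(1), 1L)
      xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
      return(geometry(syms, xyz, ...))
    }
    pos <- pos + 2L + n
  }
  stop("frame ", frame, " not found in ", path)
}

#' Write geometries to an XYZ file
#'
#' @param geoms A [geometry()] or a list of them (multi-frame output).
#' @param path File path.
#' @param comment Comment line(s), recycled over frames.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geoms, path, comment = "") {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  comment <- rep_len(comment, length(geoms))
  out <- unlist(lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    c(as.character(nrow(g$atoms)), comment[[i]],
      sprintf("%-3s %15.8f %15.8f %15.8f", g$atoms$symbol,
              g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a bonding graph from JSON
#'
#' Schema: `{"atoms": ["C", "O", ...], "bonds": [[1, 2], ...]}` with
#' 1-based bond indices.
#'
#' @param path File path (or JSON string).
#' @param ... Passed to [atom_spec()].
#' @return A `molecular_graph`.
#' @export
graph_from_json <- function(path, ...) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(doc$atoms)) stop("graph JSON: missing required field 'atoms'")
  bonds <- doc$bonds
  if (is.null(bonds) || length(bonds) == 0L) {
    bonds <- list()
  } else if (is.matrix(bonds)) {
    bonds <- asplit(bonds, 1)
  }
  graph_from_bonds(as.character(doc$atoms), bonds, ...)
}

#' Serialize a bonding graph to JSON
#'
#' @param graph A `molecular_graph`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
graph_to_json <- function(graph, path = NULL) {
  ut <- which(upper.tri(graph$adjacency) & graph$adjacency == 1L,
              arr.ind = TRUE)
  doc <- list(atoms = graph$atoms$symbol,
              bonds = unname(lapply(seq_len(nrow(ut)),
                                    function(i) as.integer(ut[i, ]))))
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
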