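# Reaction classes: before/after bonding patterns on small atom tuples.
#
# Applying a class to a tuple of atoms whose induced sub-adjacency equals
# the `before` pattern replaces that block with the `after` pattern,
# leaving every other entry untouched.  Combined with valence constraints
# this is the elementary move that generates new product graphs.

#' Define a reaction class
#'
#' @param name Class name (unique within a library).
#' @param before,after k x k binary symmetric zero-diagonal pattern
#'   matrices describing the bonding among the k participating atoms
#'   before and after the reaction; they must differ.
#' @param element_filters Optional list of length k; each entry `NULL`
#'   (any element) or a character vector of allowed element symbols for
#'   that slot.
#' @return An object of class `reaction_class`.
#' @examples
#' assoc <- reaction_class("association",
#'                         before = matrix(0, 2, 2),
#'                         after  = matrix(c(0, 1, 1, 0), 2))
#' @export
reaction_class <- function(name, before, after, element_filters = NULL) {
  k <- nrow(as.matrix(before))
  if (!k %in% 2:4) stop("reaction class arity must be 2, 3 or 4")
  before <- as_adjacency(before, k)
  after <- as_adjacency(after, k)
  if (identical(before, after)) stop("before and after patterns must differ")
  if (!is.null(element_filters)) {
    stopifnot(length(element_filters) == k)
  }
  structure(list(name = name, arity = k, before = before, after = after,
                 element_filters = element_filters,
                 automorphisms = pattern_automorphisms(before, after,
                                                       element_filters)),
            class = "reaction_class")
}

#' @export
print.reaction_class <- function(x, ...) {
  cat("<reaction_class> ", x$name, " (arity ", x$arity, "): bonds ",
      pattern_bond_string(x$before), " -> ", pattern_bond_string(x$after),
      "\n", sep = "")
  invisible(x)
}

pattern_bond_string <- function(m) {
  ut <- which(upper.tri(m) & m == 1L, arr.ind = TRUE)
  if (nrow(ut) == 0L) return("{}")
  paste0("{", paste(sprintf("%d-%d", ut[, 1], ut[, 2]), collapse = ","), "}")
}

# Slot permutations leaving before, after and filters invariant.  Tuples
# equivalent under such a permutation describe the same physical event
# (e.g. the two mirror orders of an association pair) and are
# deduplicated during enumeration.
pattern_automorphisms <- function(before, after, filters) {
  k <- nrow(before)
  perms <- permutations_of(k)
  keep <- vapply(perms, function(p) {
    identical(before[p, p], before) && identical(after[p, p], after) &&
      (is.null(filters) || identical(filters[p], filters))
  }, logical(1))
  perms[keep]
}

# All permutations of 1:k (k <= 4 here, at most 24).
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Swap the before/after patterns of a class
#'
#' Every class is invertible: the reverse class applied to the same atom
#' tuple undoes the original event.
#'
#' @param rc A `reaction_class`.
#' @return The inverse `reaction_class`.
#' @export
reverse_class <- function(rc) {
  reaction_class(paste0(rc$name, "_rev"), rc$after, rc$before,
                 rc$element_filters)
}

#' Built-in reaction-class library
#'
#' The default library covers single-bond association/dissociation, the
#' diatomic dissociation/association pair (two bonds to a common atom
#' exchanged against one bond between its neighbours, e.g. H2 elimination
#' from formaldehyde), and a single-atom transfer class.  This is the
#' smallest set under which hydrogen-transfer chemistry is expressible;
#' further classes can be supplied via [reaction_classes_from_config()].
#'
#' @return Named list of `reaction_class` objects.
#' @examples
#' names(builtin_library())
#' @export
builtin_library <- function() {
  z2 <- matrix(0L, 2, 2)
  b2 <- matrix(c(0L, 1L, 1L, 0L), 2)
  # 3-atom patterns, slots (i, j, k)
  two_to_center <- matrix(0L, 3, 3)       # i-j and i-k bonded
  two_to_center[1, 2] <- two_to_center[2, 1] <- 1L
  two_to_center[1, 3] <- two_to_center[3, 1] <- 1L
  pair_jk <- matrix(0L, 3, 3)             # j-k bonded only
  pair_jk[2, 3] <- pair_jk[3, 2] <- 1L
  bond_ij <- matrix(0L, 3, 3)
  bond_ij[1, 2] <- bond_ij[2, 1] <- 1L
  bond_ik <- matrix(0L, 3, 3)
  bond_ik[1, 3] <- bond_ik[3, 1] <- 1L
  classes <- list(
    reaction_class("dissociation", before = b2, after = z2),
    reaction_class("association", before = z2, after = b2),
    reaction_class("diatomic_dissociation",
                   before = two_to_center, after = pair_jk),
    reaction_class("diatomic_association",
                   before = pair_jk, after = two_to_center),
    reaction_class("atom_transfer", before = bond_ij, after = bond_ik)
  )
  stats::setNames(classes, vapply(classes, `[[`, character(1), "name"))
}

#' Load reaction classes from a YAML or JSON config
#'
#' Each entry gives `name`, `arity`, `before`/`after` as lists of 1-based
#' slot-index bond pairs, and optionally `element_filters` as a list of
#' per-slot allowed-element vectors (use `~`/`null` for unconstrained
#' slots).
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Named list of `reaction_class` objects.
#' @export
reaction_classes_from_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  classes <- lapply(doc, function(e) {
    k <- e$arity
    mk <- function(bonds) {
      m <- matrix(0L, k, k)
      for (b in bonds) {
        m[b[[1]], b[[2]]] <- m[b[[2]], b[[1]]] <- 1L
      }
      m
    }
    filt <- e$element_filters
    if (!is.null(filt)) {
      filt <- lapply(filt, function(f) if (is.null(f)) NULL else
        as.character(unlist(f)))
    }
    reaction_class(e$name, mk(e$before), mk(e$after), filt)
  })
  stats::setNames(classes, vapply(classes, `[[`, character(1), "name"))
}

#' A reaction event: a class applied to a concrete atom tuple
#'
#' @param class_ref A `reaction_class`.
#' @param atom_indices Ordered tuple of distinct 1-based atom indices,
#'   length equal to the class arity.
#' @return An object of class `reaction_event`.
#' @export
reaction_event <- function(class_ref, atom_indices) {
  atom_indices <- as.integer(atom_indices)
  stopifnot(inherits(class_ref, "reaction_class"),
            length(atom_indices) == class_ref$arity,
            !anyDuplicated(atom_indices), all(atom_indices >= 1L))
  structure(list(class_ref = class_ref, atom_indices = atom_indices),
            class = "reaction_event")
}

#' @export
print.reaction_event <- function(x, ...) {
  cat("<reaction_event> ", x$class_ref$name, "(",
      paste(x$atom_indices, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Does the induced sub-adjacency of `idx` equal the class pattern, and do
# the elements satisfy the slot filters?
tuple_matches <- function(graph, rc, idx) {
  if (any(idx > n_atoms(graph))) return(FALSE)
  if (!identical(graph$adjacency[idx, idx, drop = FALSE], rc$before)) {
    return(FALSE)
  }
  if (!is.null(rc$element_filters)) {
    for (s in seq_len(rc$arity)) {
      f <- rc$element_filters[[s]]
      if (!is.null(f) && !(graph$atoms$symbol[idx[s]] %in% f)) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate all atom tuples matching a reaction class
#'
#' Returns every tuple of distinct atoms whose induced sub-adjacency
#' equals the class's `before` pattern and whose elements pass the slot
#' filters.  Tuples equivalent under a symmetry of the pattern (e.g. the
#' two orders of an association pair) are reported once, by their
#' lexicographically smallest representative; ordering of the result is
#' deterministic (lexicographic).
#'
#' @param graph A `molecular_graph`.
#' @param rc A `reaction_class`.
#' @param active_atoms Optional integer vector; when given, only tuples
#'   drawn entirely from this atom subset are returned.
#' @return List of integer tuples (possibly empty).
#' @export
enumerate_matches <- function(graph, rc, active_atoms = NULL) {
  n <- n_atoms(graph)
  pool <- if (is.null(active_atoms)) seq_len(n) else
    sort(as.integer(active_atoms))
  if (length(pool) < rc$arity) return(list())
  combos <- utils::combn(pool, rc$arity, simplify = FALSE)
  out <- list()
  seen <- character(0)
  perms <- permutations_of(rc$arity)
  for (cmb in combos) {
    for (p in perms) {
      idx <- cmb[p]
      if (!tuple_matches(graph, rc, idx)) next
      canon <- orbit_representative(idx, rc$automorphisms)
      key <- paste(canon, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- canon
      }
    }
  }
  # deterministic lexicographic ordering of the deduplicated tuples
  if (length(out) > 1L) {
    keys <- vapply(out, function(t) paste(sprintf("%06d", t), collapse = ","),
                   character(1))
    out <- out[order(keys)]
  }
  out
}

orbit_representative <- function(idx, autos) {
  reps <- vapply(autos, function(p) paste(sprintf("%06d", idx[p]),
                                          collapse = ","), character(1))
  best <- which(reps == min(reps))[1L]
  idx[autos[[best]]]
}

#' Apply a reaction event to a graph
#'
#' Replaces the sub-adjacency on the event's atom tuple with the class's
#' `after` pattern.  When `enforce_valence` is set and the product fails
#' [check_valences()], a rejection value (class `reaction_rejection`)
#' carrying the violations is returned instead of a graph — rejection is
#' an ordinary outcome of a search step, not an error.
#'
#' @param graph A `molecular_graph`.
#' @param ev A `reaction_event` whose tuple matches the class's `before`
#'   pattern on `graph` (otherwise an error is raised).
#' @param enforce_valence Check the product against valence constraints.
#' @return The product `molecular_graph`, or a `reaction_rejection`.
#' @export
apply_event <- function(graph, ev, enforce_valence = TRUE) {
  rc <- ev$class_ref
  idx <- ev$atom_indices
  if (!tuple_matches(graph, rc, idx)) {
    stop("event ", rc$name, "(", paste(idx, collapse = ","),
         ") does not match the graph's bonding pattern")
  }
  adj <- graph$adjacency
  adj[idx, idx] <- rc$after
  # the edit preserves symmetry/binarity by construction, so skip the
  # full constructor validation (this sits in the search hot loop)
  out <- structure(list(atoms = graph$atoms, adjacency = adj),
                   class = "molecular_graph")
  if (enforce_valence) {
    chk <- check_valences(out)
    if (!chk$ok) {
      return(structure(list(event = ev, graph = out,
                            violations = chk$violations),
                       class = "reaction_rejection"))
    }
  }
  out
}

#' Is a value a valence rejection?
#'
#' @param x Any value.
#' @return Logical.
#' @export
is_rejection <- function(x) inherits(x, "reaction_rejection")

#' @export
print.reaction_rejection <- function(x, ...) {
  cat("<reaction_rejection> ", x$event$class_ref$name, "(",
      paste(x$event$atom_indices, collapse = ", "), "): valence violation at atom(s) ",
      paste(x$violations$atom, collapse = ", "), "\n", sep = "")
  invisible(x)
}
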