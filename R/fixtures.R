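# Built-in test systems: small molecules and reactant sets used
# throughout the examples, tests and vignette.  Graphs are defined by
# bond lists; geometries (where provided) are idealized equilibrium
# structures built from standard bond lengths and angles.

#' Built-in molecular fixtures
#'
#' Returns named input systems: formaldehyde (graph + geometry), water,
#' benzene and its interstellar precursors (ethynyl radical, acetylene,
#' 1,3-butadiene), the hydroformylation reactant set
#' \{HCo(CO)4, H2, CO, C2H4\} with its propanal product, and small
#' abstract systems (H2 + O atom, a three-hydrogen system).
#'
#' @param name Fixture name; call without arguments to list all names.
#' @return With no `name`: character vector of fixture names.  With a
#'   `name`: a list with `graph` (a `molecular_graph`) and `geometry`
#'   (a [geometry()] or `NULL`).
#' @examples
#' fixture_systems()
#' fixture_systems("h2co")$graph
#' @export
fixture_systems <- function(name = NULL) {
  builders <- list(
    h2co = fixture_h2co,
    h2o = fixture_h2o,
    benzene = fixture_benzene,
    c2h = fixture_c2h,
    c2h2 = fixture_c2h2,
    butadiene = fixture_butadiene,
    benzene_reactants = fixture_benzene_reactants,
    hydroformylation_reactants = fixture_hydroformylation_reactants,
    propanal = fixture_propanal,
    h2_plus_o = fixture_h2_plus_o,
    h3_system = fixture_h3_system
  )
  if (is.null(name)) return(names(builders))
  if (!name %in% names(builders)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

# Formaldehyde, atoms ordered C, O, H, H.  C=O 1.205 A, C-H 1.111 A,
# H-C-H 116.1 deg.
fixture_h2co <- function() {
  g <- graph_from_bonds(c("C", "O", "H", "H"),
                        list(c(1, 2), c(1, 3), c(1, 4)))
  half <- 116.13 / 2 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(0, 0, 1.205),
                  c(1.111 * sin(half), 0, -1.111 * cos(half)),
                  c(-1.111 * sin(half), 0, -1.111 * cos(half)))
  list(graph = g, geometry = geometry(g$atoms, coords))
}

# Water: O-H 0.9572 A, H-O-H 104.52 deg.
fixture_h2o <- function() {
  g <- graph_from_bonds(c("O", "H", "H"), list(c(1, 2), c(1, 3)))
  half <- 104.52 / 2 * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(0.9572 * sin(half), 0.9572 * cos(half), 0),
                  c(-0.9572 * sin(half), 0.9572 * cos(half), 0))
  list(graph = g, geometry = geometry(g$atoms, coords))
}

# Benzene: carbons 1-6 on a ring of radius 1.397 A, hydrogens 7-12
# radially at 1.397 + 1.086 A.
fixture_benzene <- function() {
  ang <- (0:5) * pi / 3
  coords <- rbind(cbind(1.397 * cos(ang), 1.397 * sin(ang), 0),
                  cbind(2.483 * cos(ang), 2.483 * sin(ang), 0))
  bonds <- c(lapply(1:6, function(i) c(i, i %% 6L + 1L)),
             lapply(1:6, function(i) c(i, i + 6L)))
  g <- graph_from_bonds(rep(c("C", "H"), each = 6), bonds)
  list(graph = g, geometry = geometry(g$atoms, coords))
}

# Ethynyl radical C2H: H-C-C chain.
fixture_c2h <- function() {
  list(graph = graph_from_bonds(c("C", "C", "H"), list(c(1, 2), c(1, 3))),
       geometry = NULL)
}

# Acetylene: H-C-C-H.
fixture_c2h2 <- function() {
  list(graph = graph_from_bonds(c("C", "C", "H", "H"),
                                list(c(1, 2), c(1, 3), c(2, 4))),
       geometry = NULL)
}

# 1,3-butadiene CH2=CH-CH=CH2 (binary adjacency: a C4 chain).
fixture_butadiene <- function() {
  bonds <- list(c(1, 2), c(2, 3), c(3, 4),
                c(1, 5), c(1, 6), c(2, 7), c(3, 8), c(4, 9), c(4, 10))
  list(graph = graph_from_bonds(c(rep("C", 4), rep("H", 6)), bonds),
       geometry = NULL)
}

# Benzene-formation reactant system: 1,3-butadiene + C2H radical
# (13 atoms; benzene formation sheds one hydrogen).
fixture_benzene_reactants <- function() {
  bonds <- list(c(1, 2), c(2, 3), c(3, 4),                  # C4 chain
                c(1, 5), c(1, 6), c(2, 7), c(3, 8), c(4, 9), c(4, 10),
                c(11, 12), c(11, 13))                       # C2H
  list(graph = graph_from_bonds(c(rep("C", 4), rep("H", 6),
                                  "C", "C", "H"), bonds),
       geometry = NULL)
}

# Hydroformylation reactant system: HCo(CO)4 + H2 + CO + C2H4.
# Atoms: 1 Co, 2 hydride H, 3-6 carbonyl C, 7-10 carbonyl O,
# 11-12 H2, 13 C + 14 O (free CO), 15-16 ethene C, 17-20 ethene H.
fixture_hydroformylation_reactants <- function() {
  bonds <- c(list(c(1, 2)),
             lapply(3:6, function(c) c(1, c)),
             lapply(3:6, function(c) c(c, c + 4L)),
             list(c(11, 12), c(13, 14), c(15, 16),
                  c(15, 17), c(15, 18), c(16, 19), c(16, 20)))
  syms <- c("Co", "H", rep("C", 4), rep("O", 4), "H", "H", "C", "O",
            "C", "C", rep("H", 4))
  list(graph = graph_from_bonds(syms, bonds), geometry = NULL)
}

# Propanal CH3-CH2-CHO, the hydroformylation product molecule.
fixture_propanal <- function() {
  bonds <- list(c(1, 2), c(2, 3), c(3, 4),
                c(1, 5), c(1, 6), c(1, 7), c(2, 8), c(2, 9), c(3, 10))
  list(graph = graph_from_bonds(c("C", "C", "C", "O", rep("H", 6)),
                                bonds),
       geometry = NULL)
}

# H2 molecule plus a free oxygen atom.
fixture_h2_plus_o <- function() {
  list(graph = graph_from_bonds(c("O", "H", "H"), list(c(2, 3))),
       geometry = NULL)
}

# Three hydrogen atoms, one bond (H2 + H): the smallest nontrivial
# exploration system.
fixture_h3_system <- function() {
  list(graph = graph_from_bonds(c("H", "H", "H"), list(c(1, 2))),
       geometry = NULL)
}
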