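# Built-in per-element properties used throughout the package.
#
# Covalent radii are Pyykko-style single-bond radii (Angstrom); masses are
# standard atomic weights (amu).  The allowed-valence column gives the
# default coordination-number range [v_min, v_max] used by the valence
# filter; zero is included for elements that can plausibly occur as free
# atoms or radicals during a search, so that dissociation products such as
# a lone hydrogen atom are accepted by default.  All values are
# user-overridable through `atom_spec()`.

.element_table <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol covalent_radius mass    v_min v_max
H      0.32            1.008   0     1
He     0.46            4.0026  0     0
Li     1.33            6.94    0     1
Be     1.02            9.0122  0     2
B      0.85           10.81    0     3
C      0.75           12.011   0     4
N      0.71           14.007   0     3
O      0.63           15.999   0     2
F      0.64           18.998   0     1
Ne     0.67           20.180   0     0
Na     1.55           22.990   0     1
Mg     1.39           24.305   0     2
Al     1.26           26.982   0     3
Si     1.16           28.085   0     4
P      1.11           30.974   0     5
S      1.03           32.06    0     6
Cl     0.99           35.45    0     1
Ar     0.96           39.95    0     0
K      1.96           39.098   0     1
Ca     1.71           40.078   0     2
Ti     1.36           47.867   0     6
Cr     1.22           51.996   0     6
Mn     1.19           54.938   0     6
Fe     1.16           55.845   0     6
Co     1.11           58.933   0     6
Ni     1.10           58.693   0     6
Cu     1.12           63.546   0     6
Zn     1.18           65.38    0     6
Br     1.14           79.904   0     1
I      1.33          126.90    0     1
")
  rownames(tab) <- tab$symbol
  tab
})

#' Per-atom specification table
#'
#' Builds the per-atom property table (element symbol, covalent radius,
#' atomic mass and allowed coordination-number range) used by all graph
#' operations.  Defaults come from a built-in table of Pyykko-style
#' single-bond covalent radii and standard atomic weights; any column can
#' be overridden per element.
#'
#' @param symbols Character vector of element symbols, one per atom.
#' @param valence_ranges Optional named list overriding the allowed
#'   coordination range per element, e.g. `list(O = c(1, 2))`.
#' @param radii Optional named numeric vector overriding covalent radii
#'   (Angstrom) per element.
#' @param masses Optional named numeric vector overriding atomic masses
#'   (amu) per element.
#' @return A data frame with one row per atom and columns `symbol`,
#'   `covalent_radius`, `mass`, `v_min`, `v_max`.
#' @examples
#' atom_spec(c("C", "O", "H", "H"))
#' atom_spec(c("C", "O"), valence_ranges = list(O = c(1, 2)))
#' @export
atom_spec <- function(symbols, valence_ranges = NULL, radii = NULL,
                      masses = NULL) {
  stopifnot(is.character(symbols), length(symbols) >= 1L)
  unknown <- setdiff(unique(symbols), rownames(.element_table))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         "; supply properties via `radii`/`masses`/`valence_ranges` after ",
         "adding the element, or use a supported symbol")
  }
  spec <- .element_table[symbols, , drop = FALSE]
  rownames(spec) <- NULL
  if (!is.null(radii)) {
    for (el in names(radii)) spec$covalent_radius[spec$symbol == el] <- radii[[el]]
  }
  if (!is.null(masses)) {
    for (el in names(masses)) spec$mass[spec$symbol == el] <- masses[[el]]
  }
  if (!is.null(valence_ranges)) {
    for (el in names(valence_ranges)) {
      rng <- valence_ranges[[el]]
      stopifnot(length(rng) == 2L, rng[1] <= rng[2], rng[1] >= 0)
      spec$v_min[spec$symbol == el] <- rng[1]
      spec$v_max[spec$symbol == el] <- rng[2]
    }
  }
  stopifnot(all(spec$covalent_radius > 0), all(spec$mass > 0))
  spec
}

#' Supported element symbols
#'
#' @return Character vector of element symbols with built-in properties.
#' @export
supported_elements <- function() rownames(.element_table)
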