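# Molecular-mass class ladder for a cellulose chain discretized in
# cellobiose units. Class index increases as molar mass decreases; the last
# class is absorbing (glucose, or HMF with glucose one class above it).

CELLOBIOSE_MASS <- 342 # g/mol
WATER_MASS <- 18       # g/mol
GLUCOSE_MASS <- 180    # g/mol
HMF_MASS_DEFAULT <- 126 # g/mol (hydroxymethylfurfural)

#' Molar mass of a condensation chain of cellobiose units
#'
#' A chain of `units` cellobiose residues carries `units - 1` glycosidic
#' bonds, each formed with loss of one water, so the molar mass is
#' `units * 342 - (units - 1) * 18` g/mol.
#'
#' @param units integer vector, number of cellobiose units (each >= 1).
#' @return numeric molar mass(es) in g/mol.
#' @examples
#' chain_mass(10) # 3258
#' chain_mass(1)  # 342
#' @export
chain_mass <- function(units) {
  if (length(units) == 0 || any(!is.finite(units)) || any(units < 1) ||
      any(units != round(units))) {
    stop("`units` must be integer(s) >= 1: a chain needs at least one cellobiose unit")
  }
  units * CELLOBIOSE_MASS - (units - 1) * WATER_MASS
}

#' Build the molecular-mass class ladder
#'
#' Constructs the ordered class masses for a chain of `n_units` cellobiose
#' units. With `terminal_scheme = "glucose_terminal"` the ladder runs from
#' the intact chain down to cellobiose, followed by a terminal glucose class
#' (the absorbing state); this is the 10-cellobiose worked example. With
#' `"glucose_then_hmf"` the chain classes stop at two cellobiose units and
#' are followed by a glucose class at index `N - 1` and an absorbing HMF
#' class at index `N`, matching the 100-cellobiose scenario where glucose
#' further degrades to hydroxymethylfurfural.
#'
#' @param n_units integer >= 1, cellobiose units in the intact chain.
#' @param terminal_scheme `"glucose_terminal"` or `"glucose_then_hmf"`.
#' @param hmf_mass molar mass assigned to the HMF class (g/mol). Affects
#'   labelling and mass bookkeeping only, never transition probabilities.
#' @return object of class `mass_ladder`: list with `n_units`, `masses`
#'   (`M_0 ... M_N`, g/mol), `N` (terminal class index), `labels`,
#'   `unit_mass`, `water_mass`, `terminal_scheme`.
#' @examples
#' build_ladder(10)
#' build_ladder(100, "glucose_then_hmf")
#' @export
build_ladder <- function(n_units,
                         terminal_scheme = c("glucose_terminal", "glucose_then_hmf"),
                         hmf_mass = HMF_MASS_DEFAULT) {
  terminal_scheme <- match.arg(terminal_scheme)
  if (length(n_units) != 1 || !is.finite(n_units) || n_units < 1 ||
      n_units != round(n_units)) {
    stop("`n_units` must be a single integer >= 1")
  }
  if (terminal_scheme == "glucose_terminal") {
    masses <- c(chain_mass(n_units:1), GLUCOSE_MASS)
    labels <- c(cb_label(n_units:1), "glucose")
  } else {
    if (n_units < 2) stop("glucose_then_hmf requires n_units >= 2")
    masses <- c(chain_mass(n_units:2), GLUCOSE_MASS, hmf_mass)
    labels <- c(cb_label(n_units:2), "glucose", "HMF")
  }
  structure(
    list(n_units = n_units, masses = masses, N = length(masses) - 1L,
         labels = labels, unit_mass = CELLOBIOSE_MASS, water_mass = WATER_MASS,
         terminal_scheme = terminal_scheme),
    class = "mass_ladder"
  )
}

cb_label <- function(units) ifelse(units == 1, "CB", paste0("CB×", units))

#' Descendant masses of a binary cleavage
#'
#' A parent chain in class `parent_class` cleaves into a fragment in class
#' `child_class` plus the complementary fragment. One glycosidic bond is
#' hydrolyzed, so the two descendant masses sum to the parent mass plus one
#' water (18 g/mol). The complement must itself be representable on the
#' cellobiose ladder (or be glucose); cleavages that would leave an
#' odd-glucose fragment are rejected.
#'
#' @param ladder a [mass_ladder][build_ladder].
#' @param parent_class,child_class 0-based class indices,
#'   `parent_class < child_class <= N`; the parent must be a cleavable chain
#'   class (not glucose or HMF).
#' @return named numeric of length 2: `child` and `complement` masses, g/mol.
#' @examples
#' lad <- build_ladder(10)
#' cleavage_masses(lad, 0, 1)  # 2934 + 342 = 3258 + 18
#' cleavage_masses(lad, 9, 10) # cellobiose -> two glucose
#' @export
cleavage_masses <- function(ladder, parent_class, child_class) {
  stopifnot(inherits(ladder, "mass_ladder"))
  N <- ladder$N
  if (parent_class < 0 || child_class > N || parent_class >= child_class) {
    stop("need 0 <= parent_class < child_class <= N")
  }
  if (ladder$labels[parent_class + 1] %in% c("glucose", "HMF")) {
    stop("parent class ", parent_class, " (", ladder$labels[parent_class + 1],
         ") carries no cleavable glycosidic bond on this ladder")
  }
  m_parent <- ladder$masses[parent_class + 1]
  m_child <- ladder$masses[child_class + 1]
  m_comp <- m_parent + ladder$water_mass - m_child
  ok <- m_comp == GLUCOSE_MASS ||
    (m_comp >= CELLOBIOSE_MASS &&
       (m_comp - WATER_MASS) %% (CELLOBIOSE_MASS - WATER_MASS) == 0)
  if (!ok) {
    stop("cleavage ", parent_class, " -> ", child_class,
         " leaves a fragment of ", m_comp,
         " g/mol, not representable on the cellobiose ladder")
  }
  c(child = m_child, complement = m_comp)
}

#' @export
print.mass_ladder <- function(x, ...) {
  cat("<mass_ladder> ", x$n_units, " cellobiose units, ", x$N + 1,
      " classes (terminal scheme: ", x$terminal_scheme, ")\n", sep = "")
  print(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (x$N + 1 > 12) cat("... (", x$N - 11, " more classes)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mass_ladder <- function(x, ...) {
  data.frame(class_index = 0:x$N,
             molar_mass_g_per_mol = x$masses,
             label = x$labels,
             stringsAsFactors = FALSE)
}

#' Write a mass ladder to CSV
#'
#' Columns: `class_index`, `molar_mass_g_per_mol`, `label`.
#'
#' @param ladder a [mass_ladder][build_ladder].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ladder_csv <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
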