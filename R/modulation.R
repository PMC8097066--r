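# Acid-concentration and temperature modulation of transition frequencies.
# A single dimensionless acid factor g = (c_a/c_a_ref)^n multiplies every
# scission channel; a temperature factor h multiplies them too, with a
# separate activation energy for the glucose -> HMF step (the N-1 -> N
# entry) than for the bulk depolymerization steps.

#' Process conditions for modulated hydrolysis
#'
#' @param T_K,T_ref_K process and reference absolute temperatures (K).
#' @param c_a_pct,c_a_ref_pct acid concentration and its reference (%).
#' @param acid_order dimensionless exponent n of the acid factor.
#' @param E_Am_J_per_mol mean activation energy of all scissions down to
#'   glucose (J/mol).
#' @param E_AG_J_per_mol activation energy of the glucose-to-HMF step
#'   (J/mol).
#' @param dt_s time step (s).
#' @param c_C0_g_per_L initial cellulose suspension concentration (g/L).
#' @param arrhenius_sign `"as_printed"` keeps the modulation exponent
#'   `+ (E/R)(1/T - 1/T_ref)`, under which positive activation energies slow
#'   the chain down as temperature rises; `"physical"` flips the sign to the
#'   usual Arrhenius ratio `exp[-(E/R)(1/T - 1/T_ref)]`.
#' @return object of class `process_conditions`.
#' @export
process_conditions <- function(T_K = 483, T_ref_K = 453,
                               c_a_pct = 4, c_a_ref_pct = 1,
                               acid_order = 1,
                               E_Am_J_per_mol = 170e3,
                               E_AG_J_per_mol = 137e3,
                               dt_s = 10, c_C0_g_per_L = 100,
                               arrhenius_sign = c("as_printed", "physical")) {
  arrhenius_sign <- match.arg(arrhenius_sign)
  if (T_K <= 0 || T_ref_K <= 0) stop("temperatures must be positive (K)")
  if (c_a_pct <= 0 || c_a_ref_pct <= 0) stop("acid concentrations must be positive")
  if (dt_s <= 0) stop("dt_s must be positive")
  if (c_C0_g_per_L <= 0) stop("c_C0_g_per_L must be positive")
  structure(
    list(T_K = T_K, T_ref_K = T_ref_K, c_a_pct = c_a_pct,
         c_a_ref_pct = c_a_ref_pct, acid_order = acid_order,
         E_Am_J_per_mol = E_Am_J_per_mol, E_AG_J_per_mol = E_AG_J_per_mol,
         dt_s = dt_s, c_C0_g_per_L = c_C0_g_per_L,
         arrhenius_sign = arrhenius_sign),
    class = "process_conditions"
  )
}

#' Acid and temperature modulation factors
#'
#' `g = (c_a/c_a_ref)^n`; `h_bulk = exp[(E_Am/R)(1/T - 1/T_ref)]` for the
#' scissions among classes `0 ... N-1`; `h_G` likewise with `E_AG` for the
#' glucose-to-HMF entry. Both factors are 1 at reference conditions. With
#' `arrhenius_sign = "physical"` the exponent signs are flipped.
#'
#' @param conditions a [process_conditions()].
#' @return object of class `modulation_factors`: list `g`, `h_bulk`, `h_G`
#'   plus the conditions used.
#' @export
modulation_factors <- function(conditions) {
  stopifnot(inherits(conditions, "process_conditions"))
  sgn <- if (conditions$arrhenius_sign == "physical") -1 else 1
  inv_dT <- 1 / conditions$T_K - 1 / conditions$T_ref_K
  g <- (conditions$c_a_pct / conditions$c_a_ref_pct)^conditions$acid_order
  h_bulk <- exp(sgn * conditions$E_Am_J_per_mol / GAS_CONSTANT * inv_dT)
  h_G <- exp(sgn * conditions$E_AG_J_per_mol / GAS_CONSTANT * inv_dT)
  structure(list(g = g, h_bulk = h_bulk, h_G = h_G,
                 conditions = conditions),
            class = "modulation_factors")
}

#' Apply modulation factors to a transition matrix
#'
#' Every off-diagonal scission probability is multiplied by `g * h_bulk`,
#' except the glucose-to-HMF entry (`j = N`, `i = N - 1`), which takes
#' `g * h_G`. Interior diagonals are recomputed as one minus the modulated
#' column sum; the absorbing entry stays 1; in `strict_paper` mode the
#' (0, 0) constant is retained, in `conservative` mode it is recomputed. If
#' a modulated column sum exceeds 1 the per-step probabilities are no
#' longer admissible and an error asks for a smaller time step.
#'
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param factors a [modulation_factors()].
#' @param normalization_mode optional override of `tm$normalization_mode`.
#' @return the modulated `transition_matrix`.
#' @export
apply_modulation <- function(tm, factors, normalization_mode = NULL) {
  stopifnot(inherits(tm, "transition_matrix"),
            inherits(factors, "modulation_factors"))
  if (!all(is.finite(c(factors$g, factors$h_bulk, factors$h_G)))) {
    stop("modulation factors must be finite")
  }
  mode <- if (is.null(normalization_mode)) tm$normalization_mode else
    match.arg(normalization_mode, c("conservative", "strict_paper"))
  N <- tm$N
  off <- tm$P
  diag(off) <- 0
  off <- off * factors$g * factors$h_bulk
  # glucose -> HMF channel has its own activation energy
  off[N + 1, N] <- off[N + 1, N] / factors$h_bulk * factors$h_G
  sums <- colSums(off)
  bad <- which(sums > 1 + 1e-12) - 1L
  if (length(bad)) {
    stop("modulated off-diagonal sum exceeds 1 in column(s) ",
         paste(bad, collapse = ", "),
         ": use a smaller time step (probabilities are per-step quantities)")
  }
  P <- off
  diag(P) <- 1 - sums
  P[N + 1, N + 1] <- 1
  deficit <- 0
  if (mode == "strict_paper") {
    p00 <- if (tm$distribution == "gauss") 1 / (N + 1) else 3.5 / (N + 1)
    P[1, 1] <- p00
    deficit <- 1 - (p00 + sums[1])
  }
  out <- tm
  out$P <- P
  out$normalization_mode <- mode
  out$column0_deficit <- deficit
  out$modulation <- factors[c("g", "h_bulk", "h_G")]
  out
}
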