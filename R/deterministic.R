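# Deterministic reference kinetics: the homogeneous consecutive first-order
# scheme cellulose -> glucose -> HMF, Arrhenius rate constants with an acid
# concentration factor, and the Langmuir-modulated first-order constants of
# the enzymatic scheme.

#' Closed-form glucose concentration of the consecutive first-order scheme
#'
#' For cellulose -> glucose -> degradation with rate constants `k1`, `k2`:
#' `c_G(tau) = c_C0 * k1/(k2 - k1) * (exp(-k1 tau) - exp(-k2 tau))`.
#' This is the standard non-negative solution of the consecutive scheme;
#' with the denominator written `(k1 - k2)` the expression goes negative
#' for `k1 > k2`, a sign slip occasionally seen in print. The equal-rate
#' limit `c_C0 * k1 * tau * exp(-k1 tau)` is used when `k1` and `k2`
#' coincide to within a relative 1e-9.
#'
#' @param c_C0 initial cellulose concentration (g/L).
#' @param k1,k2 first-order rate constants (1/s), both >= 0.
#' @param tau time(s) (s), vectorized.
#' @return glucose concentration(s), g/L.
#' @export
glucose_closed_form <- function(c_C0, k1, k2, tau) {
  if (k1 < 0 || k2 < 0) stop("rate constants must be non-negative")
  if (abs(k1 - k2) <= 1e-9 * max(k1, k2)) {
    return(c_C0 * k1 * tau * exp(-k1 * tau))
  }
  c_C0 * (k1 / (k2 - k1)) * (exp(-k1 * tau) - exp(-k2 * tau))
}

#' Trajectory of the deterministic C -> G -> HMF model
#'
#' Closed forms: `c_C = c_C0 exp(-k1 tau)`, `c_G` from
#' [glucose_closed_form()], and `c_HMF = c_C0 - c_C - c_G` (the three
#' concentrations sum to `c_C0` at all times).
#'
#' @inheritParams glucose_closed_form
#' @param t_end simulation horizon (s).
#' @param dt output grid spacing (s), > 0.
#' @return data.frame with columns `time_s`, `c_C`, `c_G`, `c_HMF` (g/L).
#' @examples
#' simulate_cgh(100, 1e-3, 5e-4, t_end = 2000, dt = 100)
#' @export
simulate_cgh <- function(c_C0, k1, k2, t_end, dt) {
  if (dt <= 0) stop("dt must be positive")
  tau <- seq(0, t_end, by = dt)
  c_C <- c_C0 * exp(-k1 * tau)
  c_G <- glucose_closed_form(c_C0, k1, k2, tau)
  data.frame(time_s = tau, c_C = c_C, c_G = c_G, c_HMF = c_C0 - c_C - c_G)
}

#' Time of the glucose concentration peak
#'
#' `tau* = ln(k1/k2)/(k1 - k2)` from setting the derivative of the closed
#' form to zero; `1/k1` in the equal-rate limit.
#'
#' @inheritParams glucose_closed_form
#' @return peak time (s).
#' @export
glucose_peak_time <- function(k1, k2) {
  if (k1 <= 0 || k2 <= 0) stop("rate constants must be positive")
  if (abs(k1 - k2) <= 1e-9 * max(k1, k2)) return(1 / k1)
  log(k1 / k2) / (k1 - k2)
}

#' Arrhenius rate constant with acid-concentration factor
#'
#' `k = k0 * (c_a/c_a_ref)^n * exp(-EA/(R T))` with R = 8.314 J/(mol K).
#'
#' @param k0 pre-exponential factor (1/s).
#' @param EA activation energy (J/mol).
#' @param n acid-concentration exponent (dimensionless).
#' @param c_a,c_a_ref acid concentration and reference (%).
#' @param T_K absolute temperature (K), > 0.
#' @return rate constant (1/s).
#' @export
arrhenius_rate <- function(k0, EA, n = 0, c_a = 1, c_a_ref = 1, T_K) {
  if (T_K <= 0) stop("temperature must be positive (K)")
  k0 * (c_a / c_a_ref)^n * exp(-EA / (GAS_CONSTANT * T_K))
}

#' Langmuir-modulated first-order rate constant
#'
#' For enzymatic steps whose effective rate constant follows a Langmuir
#' adsorption isotherm in the enzyme concentration:
#' `k = kmax * cE1/(KL + cE1)`. Saturates at `kmax`, is `kmax/2` at
#' `cE1 = KL`, and vanishes without enzyme.
#'
#' @param kmax maximum rate constant at full substrate saturation (1/s).
#' @param cE1 enzyme concentration (same units as `KL`).
#' @param KL Langmuir sorption-equilibrium constant.
#' @return rate constant (1/s).
#' @export
langmuir_rate_constant <- function(kmax, cE1, KL) {
  if (kmax < 0 || cE1 < 0 || KL < 0) stop("inputs must be non-negative")
  if (KL + cE1 == 0) stop("KL + cE1 must be positive")
  kmax * cE1 / (KL + cE1)
}

#' First-order enzymatic reaction rates
#'
#' The three-channel enzymatic scheme (cellulose -> cellobiose,
#' cellobiose -> glucose, cellulose -> glucose) with plain first-order
#' kinetics; `k1` and `k3` come from [langmuir_rate_constant()], the
#' cellobiose step uses a plain constant `k2_enz`.
#'
#' @param kmax1,kmax3 maximum rate constants of the enzyme-adsorption
#'   channels (1/s).
#' @param k2_enz cellobiose-to-glucose rate constant (1/s).
#' @param KL Langmuir constant; `cE1` enzyme concentration.
#' @param cE1 enzyme concentration.
#' @param c_C,c_CB cellulose and cellobiose concentrations (g/L).
#' @return named numeric: `vR1`, `vR2`, `vR3` (g/(L s)).
#' @export
enzymatic_rates <- function(kmax1, kmax3, k2_enz, KL, cE1, c_C, c_CB) {
  k1 <- langmuir_rate_constant(kmax1, cE1, KL)
  k3 <- langmuir_rate_constant(kmax3, cE1, KL)
  c(vR1 = k1 * c_C, vR2 = k2_enz * c_CB, vR3 = k3 * c_C)
}

#' Recover an activation energy from trajectories at two temperatures
#'
#' The initial glucose slope of the consecutive first-order scheme is
#' `k1(T) * c_C0`, so the log-ratio of slopes fitted over an early window
#' at two temperatures gives
#' `EA = R * ln(s1/s2) / (1/T2 - 1/T1)`.
#' Slopes are fitted through the origin by least squares over the first
#' `n_points` non-zero times.
#'
#' @param traj1,traj2 data.frames from [simulate_cgh()] (columns `time_s`,
#'   `c_G`) at temperatures `T1_K` and `T2_K`.
#' @param T1_K,T2_K absolute temperatures (K).
#' @param n_points number of early points used in each slope fit.
#' @return activation energy estimate (J/mol).
#' @export
recover_activation_energy <- function(traj1, traj2, T1_K, T2_K, n_points = 5) {
  if (T1_K == T2_K) stop("temperatures must differ")
  slope <- function(tr) {
    idx <- which(tr$time_s > 0)[seq_len(n_points)]
    stats::coef(stats::lm(c_G ~ 0 + time_s, data = tr[idx, ]))[[1]]
  }
  s1 <- slope(traj1)
  s2 <- slope(traj2)
  GAS_CONSTANT * log(s1 / s2) / (1 / T2_K - 1 / T1_K)
}
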