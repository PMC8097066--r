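# Time evolution of the class mass-fraction vector omega: discrete-time
# Markov updates omega(n+1) = P omega(n), and the continuous-time species
# mass balance d omega_i/d tau = sum_h (P_ih/dt) omega_h
#                              - omega_i sum_j (P_ji/dt),
# integrated with fixed-step RK4. Mass fractions are on an anhydro basis
# (water uptake during hydrolysis is not added to omega), so omega is a
# probability vector summing to 1 under conservative normalization.

#' Initial state of the class mass-fraction vector
#'
#' All mass starts in the heaviest class: `omega = [1, 0, ..., 0]`.
#'
#' @param N terminal class index.
#' @return object of class `state_vector`: list `omega`, `tau` (s),
#'   `step_index`.
#' @export
initial_state <- function(N) {
  if (N < 1) stop("N must be >= 1")
  structure(list(omega = c(1, rep(0, N)), tau = 0, step_index = 0L),
            class = "state_vector")
}

#' One discrete-time Markov update
#'
#' `omega(tau_{n+1})_j = sum_i P[j, i] omega(tau_n)_i`; time advances by
#' `dt` and the step counter by one.
#'
#' @param state a [state_vector][initial_state].
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param dt time step (s); defaults to `tm$dt`.
#' @return the updated `state_vector`.
#' @export
advance_state <- function(state, tm, dt = tm$dt) {
  stopifnot(inherits(state, "state_vector"), inherits(tm, "transition_matrix"))
  if (length(state$omega) != tm$N + 1) {
    stop("state has ", length(state$omega), " classes but matrix has ", tm$N + 1)
  }
  state$omega <- as.vector(tm$P %*% state$omega)
  state$tau <- state$tau + dt
  state$step_index <- state$step_index + 1L
  state
}

#' Discrete-time hydrolysis simulation
#'
#' Evolves the class mass-fraction vector from [initial_state()] through
#' `n_steps` Markov updates.
#'
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param n_steps number of time steps (>= 0).
#' @param dt time step (s); defaults to `tm$dt`.
#' @param c_C0 optional initial suspension concentration (g/L); when given,
#'   per-class concentrations `c_i = omega_i * c_C0` are filled in.
#' @return object of class `state_trajectory`: list `times` (s), `omega`
#'   (matrix, one row per time, one column per class), `concentrations`
#'   (same shape, g/L, or NULL), `c_C0`, `N`.
#' @examples
#' tm <- build_transition_matrix(10, "gauss", dt = 100)
#' traj <- simulate_hydrolysis(tm, 50, c_C0 = 100)
#' @export
simulate_hydrolysis <- function(tm, n_steps, dt = tm$dt, c_C0 = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (n_steps < 0) stop("n_steps must be >= 0")
  N <- tm$N
  omega <- matrix(0, n_steps + 1, N + 1)
  st <- initial_state(N)
  omega[1, ] <- st$omega
  if (n_steps > 0) for (n in seq_len(n_steps)) {
    st <- advance_state(st, tm, dt)
    omega[n + 1, ] <- st$omega
  }
  new_trajectory(times = (0:n_steps) * dt, omega = omega, c_C0 = c_C0, N = N)
}

new_trajectory <- function(times, omega, c_C0, N) {
  conc <- if (is.null(c_C0)) NULL else omega * c_C0
  structure(list(times = times, omega = omega, concentrations = conc,
                 c_C0 = c_C0, N = N),
            class = "state_trajectory")
}

#' Right-hand side of the species mass-balance ODE
#'
#' Gains minus losses for every class, with per-step probabilities
#' converted to rates by `dt`:
#' `d omega_i/d tau = sum_{h != i} (P[i, h]/dt) omega_h
#'                  - omega_i sum_{j != i} (P[j, i]/dt)`.
#' Row and column sums cancel pairwise, so total mass is conserved exactly.
#'
#' @param omega numeric state vector (length N+1).
#' @param P transition matrix in per-step probability form (typically the
#'   mass-weighted matrix of [mass_weight()], or any `transition_matrix$P`).
#' @param dt time step (s) used to convert probabilities to rates.
#' @return `d omega/d tau` (1/s).
#' @export
markov_ode_rhs <- function(omega, P, dt) {
  if (dt <= 0) stop("dt must be positive")
  R <- P
  diag(R) <- 0
  R <- R / dt
  as.vector(R %*% omega) - omega * colSums(R)
}

#' Continuous-time hydrolysis simulation (fixed-step RK4)
#'
#' Integrates [markov_ode_rhs()] with the classical fixed-step fourth-order
#' Runge-Kutta method and samples the solution on the `dt` grid, so the
#' output is directly comparable with [simulate_hydrolysis()].
#'
#' @param tm a [transition_matrix][build_transition_matrix] (mass-weighted
#'   or plain).
#' @param t_end simulation horizon (s), > 0.
#' @param solver_step RK4 internal step (s); must not exceed `dt` and must
#'   divide it evenly (within rounding).
#' @param dt output grid spacing (s); defaults to `tm$dt`.
#' @inheritParams simulate_hydrolysis
#' @return a `state_trajectory` on the `dt` grid.
#' @export
simulate_hydrolysis_ode <- function(tm, t_end, solver_step = dt, dt = tm$dt,
                                    c_C0 = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (t_end <= 0) stop("t_end must be positive")
  if (solver_step > dt + 1e-12) stop("solver_step must not exceed the output grid dt")
  per <- round(dt / solver_step)
  if (abs(per * solver_step - dt) > 1e-9 * dt) {
    stop("solver_step must divide dt evenly")
  }
  n_out <- floor(t_end / dt + 1e-9)
  fine_times <- seq(0, n_out * dt, by = dt / per)
  rhs <- function(t, y, parms) list(markov_ode_rhs(y, tm$P, tm$dt))
  sol <- deSolve::ode(y = c(1, rep(0, tm$N)), times = fine_times, func = rhs,
                      parms = NULL, method = "rk4")
  keep <- seq(1, nrow(sol), by = per)
  new_trajectory(times = sol[keep, 1], omega = unname(sol[keep, -1, drop = FALSE]),
                 c_C0 = c_C0, N = tm$N)
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> ", length(x$times), " time points, ",
      x$N + 1, " classes, t = [", x$times[1], ", ",
      x$times[length(x$times)], "] s",
      if (!is.null(x$c_C0)) paste0(", c_C0 = ", x$c_C0, " g/L"), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.state_trajectory <- function(x, ...) {
  nt <- length(x$times)
  nc <- x$N + 1
  out <- data.frame(
    time_s = rep(x$times, times = nc),
    class_index = rep(0:x$N, each = nt),
    mass_fraction = as.vector(x$omega)
  )
  out$concentration_g_per_L <- if (is.null(x$concentrations)) NA_real_ else
    as.vector(x$concentrations)
  out
}

#' Quick-look trajectory plot
#'
#' Mass fraction of every class against time (base graphics).
#'
#' @param x a `state_trajectory`.
#' @param classes class indices to draw; defaults to all.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.state_trajectory <- function(x, classes = 0:x$N, ...) {
  graphics::matplot(x$times, x$omega[, classes + 1, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "mass fraction", ...)
  invisible(x)
}
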