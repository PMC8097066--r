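test_that("initial state puts all mass in the heaviest class", {
  st <- initial_state(10)
  expect_equal(st$omega, c(1, rep(0, 10)))
  expect_equal(sum(st$omega), 1)
  expect_equal(st$tau, 0)
  expect_equal(initial_state(1)$omega, c(1, 0))
  expect_error(initial_state(0))
})

test_that("discrete updates conserve mass and respect the matrix", {
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  st <- initial_state(10)
  for (k in 1:20) {
    st <- advance_state(st, tm)
    expect_equal(sum(st$omega), 1, tolerance = 1e-12)
  }
  expect_equal(st$tau, 2000)
  expect_equal(st$step_index, 20L)
  # identity matrix leaves the state unchanged
  id <- tm
  id$P <- diag(11)
  expect_equal(advance_state(initial_state(10), id)$omega, c(1, rep(0, 10)))
  st2 <- initial_state(5)
  expect_error(advance_state(st2, tm), "classes")
})

test_that("n-step state equals the matrix power route (independent oracle)", {
  for (dist in c("gauss", "weibull")) {
    tm <- build_transition_matrix(8, dist, dt = 100)
    traj <- simulate_hydrolysis(tm, 64)
    pw <- oracle_matrix_power(tm$P, 64) %*% c(1, rep(0, 8))
    expect_equal(traj$omega[65, ], as.vector(pw), tolerance = 1e-12)
    # absorption completes: everything ends in the terminal class
    long <- simulate_hydrolysis(tm, 400)
    expect_gt(long$omega[401, 9], 1 - 1e-6)
  }
})

test_that("absorption is monotone for random lower-triangular stochastic matrices", {
  set.seed(42)
  for (trial in 1:100) {
    N <- sample(2:20, 1)
    P <- matrix(0, N + 1, N + 1)
    for (i in 0:(N - 1)) {
      w <- runif(N - i)
      p_break <- runif(1)
      P[(i + 2):(N + 1), i + 1] <- p_break * w / sum(w)
      P[i + 1, i + 1] <- 1 - p_break
    }
    P[N + 1, N + 1] <- 1
    tm <- structure(list(P = P, N = N, distribution = "gauss",
                         arg_convention = "source_class",
                         normalization_mode = "conservative", dt = 1,
                         column0_deficit = 0), class = "transition_matrix")
    traj <- simulate_hydrolysis(tm, 30)
    expect_true(all(diff(traj$omega[, N + 1]) >= -1e-14))
  }
})

test_that("geometric bound on the unabsorbed mass holds", {
  # every transient class has a direct channel into the absorbing class, so
  # the unabsorbed mass is enveloped by (1 - min direct probability)^n.
  # (The breaking probability itself sets no such envelope: most scissions
  # land in another transient class.)
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  p_direct_min <- min(tm$P[11, 1:10])
  expect_gt(p_direct_min, 0)
  traj <- simulate_hydrolysis(tm, 60)
  for (n in 0:60) {
    expect_lte(1 - traj$omega[n + 1, 11], (1 - p_direct_min)^n + 1e-12)
  }
})

test_that("mass-balance ODE: stationary absorbing state and zero net flux", {
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  absorbed <- c(rep(0, 10), 1)
  expect_equal(markov_ode_rhs(absorbed, tm$P, 100), rep(0, 11))
  set.seed(7)
  for (k in 1:20) {
    w <- runif(11)
    expect_equal(sum(markov_ode_rhs(w, tm$P, 100)), 0, tolerance = 1e-14)
  }
  expect_error(markov_ode_rhs(absorbed, tm$P, 0), "positive")
})

test_that("two-class ODE reproduces the analytic exponential", {
  P <- matrix(c(0.9, 0.1, 0, 1), 2, 2)
  tm <- structure(list(P = P, N = 1L, distribution = "gauss",
                       arg_convention = "source_class",
                       normalization_mode = "conservative", dt = 100,
                       column0_deficit = 0), class = "transition_matrix")
  alpha <- 0.1 / 100
  traj <- simulate_hydrolysis_ode(tm, t_end = 5000, solver_step = 10, dt = 100)
  expect_equal(traj$omega[, 1], exp(-alpha * traj$times), tolerance = 1e-8)
  expect_equal(rowSums(traj$omega), rep(1, length(traj$times)),
               tolerance = 1e-8)
})

test_that("RK4 path matches the matrix-exponential CTMC solution", {
  tm <- build_transition_matrix(6, "weibull", dt = 100)
  traj <- simulate_hydrolysis_ode(tm, t_end = 2000, solver_step = 1, dt = 100)
  R <- tm$P / 100
  diag(R) <- 0
  Q <- R
  diag(Q) <- -colSums(R)
  for (i in c(5, 21)) {
    ref <- as.vector(Matrix::expm(Q * traj$times[i]) %*% c(1, rep(0, 6)))
    expect_equal(traj$omega[i, ], ref, tolerance = 1e-9)
  }
})

test_that("zero rates give a constant trajectory; bad steps error", {
  tm <- build_transition_matrix(4, "gauss", dt = 10)
  tm$P <- diag(5)
  traj <- simulate_hydrolysis_ode(tm, t_end = 100, solver_step = 10)
  expect_true(all(traj$omega[, 1] == 1))
  expect_error(simulate_hydrolysis_ode(tm, 100, solver_step = 20, dt = 10),
               "must not exceed")
  expect_error(simulate_hydrolysis_ode(tm, 100, solver_step = 3, dt = 10),
               "divide dt evenly")
})

test_that("discrete chain converges to the CTMC at first order in the step", {
  # hold transition frequencies fixed, halve the step, compare against a
  # near-exact CTMC reference on the common grid
  base <- calibrate_rate_scale(10, "gauss", k1 = 1e-3, dt = 100)
  freq <- frequencies_from_matrix(base$tm, 100)
  ref <- simulate_hydrolysis_ode(base$tm, t_end = 4000, solver_step = 1,
                                 dt = 100)
  err_at <- function(dt) {
    tm <- matrix_at_dt(freq, dt)
    traj <- simulate_hydrolysis(tm, 4000 / dt, dt = dt)
    keep <- seq(1, nrow(traj$omega), by = 100 / dt)
    max(abs(traj$omega[keep, ] - ref$omega))
  }
  ratio <- err_at(100) / err_at(50)
  expect_gte(ratio, 1.5)
  expect_lte(ratio, 2.5)
})

test_that("DTMC and CTMC trajectories agree when step probabilities are small", {
  base <- calibrate_rate_scale(8, "gauss", k1 = 5e-4, dt = 100)
  p_max <- max(breaking_probability(base$tm))
  expect_lte(p_max, 0.05)
  dtmc <- simulate_hydrolysis(base$tm, 200)
  ctmc <- simulate_hydrolysis_ode(base$tm, t_end = 20000, solver_step = 1,
                                  dt = 100)
  step_gap <- max(abs(dtmc$omega[-1, ] - ctmc$omega[-1, ]) /
                    matrix(1:200, 200, 9))
  expect_lte(step_gap, 2 * p_max^2)
})

test_that("trajectories carry concentrations and export as long tables", {
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  traj <- simulate_hydrolysis(tm, 3, c_C0 = 100)
  expect_equal(traj$concentrations[1, ], c(100, rep(0, 10)))
  expect_equal(traj$times, c(0, 100, 200, 300))
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 4 * 11)
  expect_equal(df$concentration_g_per_L, 100 * df$mass_fraction)
  traj0 <- simulate_hydrolysis(tm, 0)
  expect_equal(nrow(traj0$omega), 1)
  expect_equal(traj0$omega[1, ], c(1, rep(0, 10)))
})
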