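test_that("printed branch rules hold: constants, absorption, normalization", {
  tm <- build_transition_matrix(10, "gauss", normalization_mode = "strict_paper")
  expect_equal(tm$P[11, 11], 1)
  expect_equal(sum(tm$P[, 6]), 1, tolerance = 1e-12)
  expect_equal(tm$P[1, 1], 1 / 11)
  tw <- build_transition_matrix(10, "weibull", normalization_mode = "strict_paper")
  expect_equal(tw$P[1, 1], 3.5 / 11)
  # strict mode reports the column-0 normalization defect instead of hiding it
  expect_equal(tm$column0_deficit, 1 - sum(tm$P[, 1]))
  # conservative mode closes column 0
  tc <- build_transition_matrix(10, "gauss")
  expect_equal(colSums(tc$P), rep(1, 11), tolerance = 1e-12)
  expect_equal(tc$column0_deficit, 0)
})

test_that("matrix entries equal independent branch-logic evaluation (N <= 6)", {
  for (N in 2:6) {
    for (dist in c("gauss", "weibull")) {
      for (conv in c("source_class", "jump_distance")) {
        tm <- build_transition_matrix(N, dist, conv, "strict_paper")
        expect_equal(tm$P, oracle_matrix(N, dist, conv), tolerance = 1e-14,
                     info = paste(N, dist, conv))
      }
    }
  }
})

test_that("matrices are lower-triangular column-stochastic with absorbing end", {
  cases <- rbind(
    expand.grid(N = c(2, 5, 10, 22, 50, 100), dist = "gauss",
                conv = c("source_class", "jump_distance"),
                stringsAsFactors = FALSE),
    expand.grid(N = c(2, 5, 10, 22), dist = "weibull", conv = "source_class",
                stringsAsFactors = FALSE),
    expand.grid(N = c(2, 10, 38), dist = "weibull", conv = "jump_distance",
                stringsAsFactors = FALSE)
  )
  for (r in seq_len(nrow(cases))) {
    N <- cases$N[r]
    tm <- build_transition_matrix(N, cases$dist[r], cases$conv[r])
    expect_true(all(tm$P[upper.tri(tm$P)] == 0))
    expect_true(all(tm$P >= 0 & tm$P <= 1))
    expect_equal(tm$P[N + 1, N + 1], 1)
    expect_equal(colSums(tm$P), rep(1, N + 1), tolerance = 1e-12)
  }
})

test_that("Weibull weights stop being admissible probabilities at large N", {
  # the shape parameter grows with the support variance until the density
  # peak exceeds 1 and a column sums above 1
  expect_error(build_transition_matrix(23, "weibull", "source_class"),
               "exceeds 1 in column")
  expect_error(build_transition_matrix(100, "weibull", "source_class"),
               "exceeds 1 in column")
  expect_error(build_transition_matrix(39, "weibull", "jump_distance"),
               "exceeds 1 in column")
  expect_silent(build_transition_matrix(22, "weibull", "source_class"))
  expect_silent(build_transition_matrix(38, "weibull", "jump_distance"))
})

test_that("survival diagonal is the complement of the off-diagonal sum", {
  expect_equal(diag_from_column(c(0.036, 0.066, 0.114, 0.170, 0.176,
                                  0.080, 0.005, 0, 0)), 0.353)
  expect_equal(diag_from_column(c(0.036, 0.066, 0.114, 0.170, 0.176, 0.080)),
               0.358)
  expect_equal(diag_from_column(numeric(0)), 1)
  expect_error(diag_from_column(c(0.7, 0.6)), "sum above 1")
  expect_error(diag_from_column(c(-0.1)), "\\[0, 1\\]")
})

test_that("breaking probability complements the diagonal on normalized columns", {
  tm <- build_transition_matrix(10, "gauss")
  p <- breaking_probability(tm)
  expect_equal(p[11], 0)          # absorbing class never breaks
  expect_equal(p + diag(tm$P), rep(1, 11), tolerance = 1e-12)
  expect_equal(breaking_probability(tm, 0), 1 - tm$P[1, 1])
  expect_error(breaking_probability(tm, 11), "out of range")
})

test_that("frequencies are off-diagonal probabilities per unit time", {
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  fr <- frequencies_from_matrix(tm)
  off <- tm$P
  diag(off) <- 0
  expect_equal(fr$alpha * 100, off, tolerance = 1e-15)
  expect_equal(fr$alpha[2, 1], tm$P[2, 1] / 100)
  expect_true(all(diag(fr$alpha) == 0))
  expect_error(frequencies_from_matrix(tm, dt = 0), "positive")
})

test_that("mass weighting reshapes columns by destination mass, preserving survival", {
  # 3-class toy: masses (3, 2, 1), rates out of class 0 both 1/s, p_0 = 0.2
  alpha <- matrix(0, 3, 3)
  alpha[2, 1] <- 1
  alpha[3, 1] <- 1
  freq <- structure(list(alpha = alpha, dt = 0.1, N = 2L,
                         distribution = "gauss"),
                    class = "transition_frequencies")
  ladder <- structure(list(n_units = 1, masses = c(3, 2, 1), N = 2L,
                           labels = c("CB", "glucose", "HMF"),
                           unit_mass = 342, water_mass = 18,
                           terminal_scheme = "glucose_terminal"),
                      class = "mass_ladder")
  pm <- mass_weight(freq, ladder)
  expect_equal(pm$P[2, 1], 0.2 * 2 / 3)
  expect_equal(pm$P[3, 1], 0.2 * 1 / 3)
  expect_equal(pm$P[1, 1], 0.8)
  expect_equal(colSums(pm$P), rep(1, 3), tolerance = 1e-12)

  # uniform masses leave relative off-diagonal proportions unchanged
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  fr <- frequencies_from_matrix(tm)
  lad <- build_ladder(10)
  lad$masses <- rep(500, 11)
  pmu <- mass_weight(fr, lad)
  expect_equal(pmu$P, tm$P, tolerance = 1e-12)
})

test_that("acid/temperature modulation behaves multiplicatively", {
  ref <- process_conditions(T_K = 453, T_ref_K = 453, c_a_pct = 1,
                            c_a_ref_pct = 1)
  f_ref <- modulation_factors(ref)
  expect_identical(c(f_ref$g, f_ref$h_bulk, f_ref$h_G), c(1, 1, 1))
  tm <- build_transition_matrix(10, "gauss", dt = 100)
  expect_equal(apply_modulation(tm, f_ref)$P, tm$P, tolerance = 1e-15)

  fig_cond <- process_conditions() # 483 K vs 453 K, 4% vs 1% acid, n = 1
  f <- modulation_factors(fig_cond)
  expect_equal(f$g, 4)
  # printed sign convention: positive activation energy slows the chain at
  # higher temperature; the physical switch inverts the factor exactly
  expect_lt(f$h_bulk, 1)
  f_phys <- modulation_factors(process_conditions(arrhenius_sign = "physical"))
  expect_equal(f_phys$h_bulk, 1 / f$h_bulk, tolerance = 1e-14)

  tmod <- apply_modulation(tm, f)
  expect_equal(colSums(tmod$P), rep(1, 11), tolerance = 1e-12)
  off <- tm$P; diag(off) <- 0
  offm <- tmod$P; diag(offm) <- 0
  # bulk entries scale by g * h_bulk, the glucose->HMF entry by g * h_G
  expect_equal(offm[5, 2], off[5, 2] * f$g * f$h_bulk)
  expect_equal(offm[11, 10], off[11, 10] * f$g * f$h_G)

  # doubling the acid factor doubles every off-diagonal entry
  f2 <- f
  f2$g <- 2 * f$g
  tmod2 <- apply_modulation(tm, f2)
  offm2 <- tmod2$P; diag(offm2) <- 0
  expect_equal(offm2, 2 * offm, tolerance = 1e-14)

  # overdriving the factors must fail with a time-step diagnostic
  hot <- modulation_factors(process_conditions(c_a_pct = 100,
                                               arrhenius_sign = "physical"))
  expect_error(apply_modulation(tm, hot), "smaller time step")
})
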