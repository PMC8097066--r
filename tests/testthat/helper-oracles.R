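# Independent oracles, written directly from the model's defining formulas
# with no code shared with the package internals.

# Hand-coded densities (no stats:: calls) -------------------------------

oracle_gauss_density <- function(x, mu, sigma) {
  1 / (sigma * sqrt(2 * pi)) * exp(-(x - mu)^2 / (2 * sigma^2))
}

oracle_weibull_density <- function(x, lam, beta) {
  (beta / lam) * (x / lam)^(beta - 1) * exp(-(x / lam)^beta)
}

# Direct branch-logic evaluation of the strict matrix rules for small N.
# Loops entry by entry; parameters recomputed inline.
oracle_matrix <- function(N, distribution, arg_convention) {
  P <- matrix(0, N + 1, N + 1)
  for (i in 0:N) {
    for (j in 0:N) {
      if (i == 0 && j == 0) {
        P[j + 1, i + 1] <- if (distribution == "gauss") 1 / (N + 1) else 3.5 / (N + 1)
      } else if (i == N && j == N) {
        P[j + 1, i + 1] <- 1
      } else if (i < j) {
        x <- if (arg_convention == "source_class") i else j - i
        K <- N + 1 - x
        mu <- K / 2
        s2 <- (K^2 - 1) / 12
        if (distribution == "gauss") {
          P[j + 1, i + 1] <- if (s2 == 0) {
            as.numeric(abs((j - i) - mu) < 1e-9)
          } else {
            oracle_gauss_density(j - i, mu, sqrt(s2))
          }
        } else {
          P[j + 1, i + 1] <- oracle_weibull_density(j - i, 1.4 + mu / N, 0.95 + s2 / N)
        }
      }
    }
  }
  for (i in 1:(N - 1)) {
    P[i + 1, i + 1] <- 1 - sum(P[-(i + 1), i + 1])
  }
  P
}

# Matrix power by repeated squaring: independent route to the n-step state.
oracle_matrix_power <- function(P, n) {
  out <- diag(nrow(P))
  base <- P
  while (n > 0) {
    if (n %% 2 == 1) out <- base %*% out
    base <- base %*% base
    n <- n %/% 2
  }
  out
}

# Classical RK4, hand-written, for deterministic ODE cross-checks.
oracle_rk4 <- function(f, y0, times) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in seq_len(length(times) - 1)) {
    h <- times[i + 1] - times[i]
    k1 <- f(times[i], y)
    k2 <- f(times[i] + h / 2, y + h / 2 * k1)
    k3 <- f(times[i] + h / 2, y + h / 2 * k2)
    k4 <- f(times[i] + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  out
}

# Rebuild a one-step matrix from fixed transition frequencies at a new dt
# (conservative normalization). Used in DTMC/CTMC convergence experiments.
matrix_at_dt <- function(freq, dt) {
  off <- freq$alpha * dt
  P <- off
  diag(P) <- 1 - colSums(off)
  P[freq$N + 1, freq$N + 1] <- 1
  structure(list(P = P, N = freq$N, distribution = freq$distribution,
                 arg_convention = "source_class",
                 normalization_mode = "conservative", dt = dt,
                 column0_deficit = 0),
            class = "transition_matrix")
}
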