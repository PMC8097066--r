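# Assembly of the (N+1) x (N+1) one-step transition-probability matrix.
# Columns are source classes, rows destination classes: P[j, i] is the
# probability that a chain in class i is found in class j after one time
# step. Scission only lightens a chain, so the matrix is lower triangular in
# this orientation, and the terminal class N is absorbing (P[N, N] = 1).

#' Raw scission weights for a transition matrix
#'
#' Evaluates the chosen scission density at every admissible jump,
#' `pp[j, i] = f(j - i)` for `i < j`, without any normalization. Under
#' `arg_convention = "source_class"` the distribution parameters are those
#' of the source class (`x = i`, support `1 ... N - i`); under
#' `"jump_distance"` they depend on the jump itself (`x = j - i`). A
#' degenerate Gauss case (`sigma = 0`) is treated as a point mass at its
#' mean. Entries are 1-indexed in R; class indices remain 0-based.
#'
#' @param N terminal class index (>= 1).
#' @param distribution `"gauss"` or `"weibull"`.
#' @param arg_convention `"source_class"` (default) or `"jump_distance"`.
#' @return (N+1) x (N+1) matrix of raw off-diagonal weights (diagonal zero).
#' @export
scission_weights <- function(N, distribution = c("gauss", "weibull"),
                             arg_convention = c("source_class", "jump_distance")) {
  distribution <- match.arg(distribution)
  arg_convention <- match.arg(arg_convention)
  if (N < 1) stop("N must be >= 1")
  pp <- matrix(0, N + 1, N + 1)
  dens <- function(jump, x) {
    if (distribution == "gauss") {
      gp <- gauss_params_for(x, N)
      if (gp$degenerate) return(as.numeric(abs(jump - gp$mu) < 1e-9))
      gauss_pdf(jump, gp)
    } else {
      weibull_pdf(jump, weibull_params_for(x, N))
    }
  }
  for (i in 0:(N - 1)) {
    jumps <- seq_len(N - i)
    if (arg_convention == "source_class") {
      pp[i + 1 + jumps, i + 1] <- dens(jumps, i)
    } else {
      pp[i + 1 + jumps, i + 1] <- vapply(jumps, function(d) dens(d, d), 0)
    }
  }
  pp
}

#' Build a one-step transition matrix
#'
#' Assembles the column-stochastic (source-in-columns) transition matrix for
#' one time step from a Gauss or Weibull scission distribution. Branch
#' rules: the terminal class is absorbing (`P[N, N] = 1`); off-diagonal
#' entries below the diagonal are the raw scission weights of
#' [scission_weights()]; diagonals of interior columns are
#' `1 - sum(off-diagonal column)`. The (0, 0) entry is a fixed constant in
#' `"strict_paper"` mode (`1/(N+1)` for Gauss, `3.5/(N+1)` for Weibull),
#' which generally leaves column 0 unnormalized; the deviation is recorded
#' in `column0_deficit`. In `"conservative"` mode (the default, and the only
#' mode under which the dynamics conserve mass) the (0, 0) entry is
#' recomputed as `1 - sum(off-diagonal column 0)` like any other column.
#'
#' Any off-diagonal column summing above 1 means the scission weights are
#' not admissible one-step probabilities; construction then fails naming the
#' offending column. This occurs for the Weibull maps at large N (the shape
#' parameter grows with the support variance until the density peak exceeds
#' 1): roughly N >= 23 under `source_class` and N >= 39 under
#' `jump_distance`.
#'
#' @inheritParams scission_weights
#' @param normalization_mode `"conservative"` (default) or `"strict_paper"`.
#' @param dt time step Delta-tau in seconds associated with the matrix
#'   (carried along for rate conversions and simulation).
#' @return object of class `transition_matrix`: list with `P`, `N`,
#'   `distribution`, `arg_convention`, `normalization_mode`, `dt`,
#'   `column0_deficit`.
#' @examples
#' tm <- build_transition_matrix(10, "gauss")
#' colSums(tm$P)
#' @export
build_transition_matrix <- function(N, distribution = c("gauss", "weibull"),
                                    arg_convention = c("source_class", "jump_distance"),
                                    normalization_mode = c("conservative", "strict_paper"),
                                    dt = 100) {
  distribution <- match.arg(distribution)
  arg_convention <- match.arg(arg_convention)
  normalization_mode <- match.arg(normalization_mode)
  N <- as.integer(N)
  pp <- scission_weights(N, distribution, arg_convention)
  off_sums <- colSums(pp)
  bad <- which(off_sums > 1 + 1e-12) - 1L
  if (length(bad)) {
    stop("off-diagonal sum exceeds 1 in column(s) ",
         paste(bad, collapse = ", "),
         ": the ", distribution,
         " scission weights are not admissible one-step probabilities at N = ", N)
  }
  P <- pp
  diag(P) <- 1 - off_sums
  P[N + 1, N + 1] <- 1
  column0_deficit <- 0
  if (normalization_mode == "strict_paper") {
    p00 <- if (distribution == "gauss") 1 / (N + 1) else 3.5 / (N + 1)
    P[1, 1] <- p00
    column0_deficit <- 1 - (p00 + off_sums[1])
  }
  structure(
    list(P = P, N = N, distribution = distribution,
         arg_convention = arg_convention,
         normalization_mode = normalization_mode, dt = dt,
         column0_deficit = column0_deficit),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> N = ", x$N, ", ", x$distribution,
      " scission, ", x$arg_convention, ", ", x$normalization_mode,
      ", dt = ", x$dt, " s\n", sep = "")
  if (x$normalization_mode == "strict_paper") {
    cat("column-0 normalization deficit:",
        format(x$column0_deficit, digits = 4), "\n")
  }
  print(round(x$P[seq_len(min(6, x$N + 1)), seq_len(min(6, x$N + 1))], 3))
  if (x$N + 1 > 6) cat("... (showing 6 of ", x$N + 1, " classes)\n", sep = "")
  invisible(x)
}

#' Diagonal (survival) probability from a column's off-diagonal entries
#'
#' The survival probability of a class is one minus the probability of any
#' scission out of it: `1 - sum(entries)`.
#'
#' @param subdiagonal_entries off-diagonal probabilities of one column,
#'   each in `[0, 1]`, summing to at most 1.
#' @return the diagonal probability.
#' @export
diag_from_column <- function(subdiagonal_entries) {
  if (length(subdiagonal_entries) &&
      (any(subdiagonal_entries < 0) || any(subdiagonal_entries > 1))) {
    stop("entries must be probabilities in [0, 1]")
  }
  s <- sum(subdiagonal_entries)
  if (s > 1 + 1e-12) stop("off-diagonal entries sum above 1 (", s, ")")
  1 - s
}

#' Breaking probability of a class
#'
#' `p_i = sum over j != i of P[j, i]`: the probability that a class-`i`
#' chain cleaves within one time step. On a normalized column this is the
#' complement of the survival diagonal, `p_i = 1 - P[i, i]`.
#'
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param i class index (0-based) or vector of indices; defaults to all.
#' @return numeric vector of breaking probabilities.
#' @export
breaking_probability <- function(tm, i = 0:tm$N) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (any(i < 0) || any(i > tm$N)) stop("class index out of range")
  vapply(i, function(ii) sum(tm$P[-(ii + 1), ii + 1]), 0)
}

#' Transition frequencies from a one-step matrix
#'
#' Converts per-step off-diagonal probabilities into per-time rates,
#' `alpha[j, i] = P[j, i]/dt` for `j != i`. Diagonals are not converted
#' (survival is not a rate) and are stored as zero.
#'
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param dt time step in seconds; defaults to the matrix's own `dt`.
#' @return object of class `transition_frequencies`: list `alpha` (1/s),
#'   `dt`, `N`, `distribution`.
#' @export
frequencies_from_matrix <- function(tm, dt = tm$dt) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (is.null(dt) || dt <= 0) stop("dt must be positive")
  alpha <- tm$P
  diag(alpha) <- 0
  alpha <- alpha / dt
  structure(list(alpha = alpha, dt = dt, N = tm$N,
                 distribution = tm$distribution),
            class = "transition_frequencies")
}

#' Mass-weighted transition matrix
#'
#' Rescales each column's off-diagonal transition proportions by the
#' destination-class molar masses, `M_j * alpha[j, i]`, so that the state
#' vector tracks mass fractions rather than chain counts. The raw
#' destination-mass ratio normalizes a column's off-diagonals to 1, which
#' would force every chain to cleave each step; here the mass proportions
#' are rescaled so each column's off-diagonal sum equals that column's
#' breaking probability `p_i = sum(alpha[, i]) * dt`, preserving the
#' survival diagonal `1 - p_i`.
#'
#' @param freq a [transition_frequencies][frequencies_from_matrix].
#' @param ladder a [mass_ladder][build_ladder] with the same `N`.
#' @return a `transition_matrix` in mass units (conservative-normalized).
#' @export
mass_weight <- function(freq, ladder) {
  stopifnot(inherits(freq, "transition_frequencies"),
            inherits(ladder, "mass_ladder"))
  if (ladder$N != freq$N) stop("ladder and frequencies disagree on N")
  N <- freq$N
  Pm <- matrix(0, N + 1, N + 1)
  p <- colSums(freq$alpha) * freq$dt
  for (i in 0:(N - 1)) {
    w <- ladder$masses * freq$alpha[, i + 1]
    tot <- sum(w)
    if (tot == 0) {
      if (p[i + 1] > 0) stop("column ", i, " has zero mass-weighted flux but p_i > 0")
      next
    }
    Pm[, i + 1] <- p[i + 1] * w / tot
  }
  diag(Pm) <- 1 - p
  Pm[N + 1, N + 1] <- 1
  structure(
    list(P = Pm, N = N, distribution = freq$distribution,
         arg_convention = "mass_weighted",
         normalization_mode = "conservative", dt = freq$dt,
         column0_deficit = 0, mass_units = TRUE),
    class = "transition_matrix"
  )
}
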