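# Scission distributions: where along the chain a cleavage lands, expressed
# as a probability density over the (integer) jump down the class ladder.
# The parameter maps tie the distribution to the support 1 ... N + 1 - x of
# admissible scission positions: the Gauss parameters are the exact mean and
# variance of a discrete uniform variable on that support, and the Weibull
# parameters are affine maps of those two moments.

#' Gauss scission parameters for a support of size N + 1 - x
#'
#' `mu = (N + 1 - x)/2` and `sigma^2 = ((N + 1 - x)^2 - 1)/12`: the mean and
#' variance of a discrete uniform variable on `1 ... N + 1 - x`. At
#' `x = N` the support collapses to a single point and `sigma = 0`; the
#' result is then flagged `degenerate` and callers must treat the
#' distribution as a point mass at `mu` (no silent epsilon).
#'
#' @param x integer, `0 <= x <= N` (class or jump index, see
#'   [build_transition_matrix()]'s `arg_convention`).
#' @param N terminal class index.
#' @return object of class `gauss_params`: list `mu`, `sigma`, `degenerate`.
#' @export
gauss_params_for <- function(x, N) {
  if (x < 0 || x > N) stop("need 0 <= x <= N")
  K <- N + 1 - x
  sigma2 <- (K^2 - 1) / 12
  structure(list(mu = K / 2, sigma = sqrt(sigma2), degenerate = sigma2 == 0),
            class = "gauss_params")
}

#' Gauss (normal) probability density
#'
#' @param x numeric vector of evaluation points.
#' @param params a [gauss_params][gauss_params_for] (or list with `mu`,
#'   `sigma`).
#' @return density values.
#' @export
gauss_pdf <- function(x, params) {
  if (params$sigma <= 0) {
    stop("degenerate Gauss distribution (sigma = 0): handle as a point mass at mu")
  }
  stats::dnorm(x, mean = params$mu, sd = params$sigma)
}

#' Weibull scission parameters for a support of size N + 1 - x
#'
#' Scale `lambda = 1.4 + mu(x)/N` and shape `beta = 0.95 + sigma^2(x)/N`,
#' with `mu`, `sigma^2` from [gauss_params_for()]. Since `sigma^2 >= 0`,
#' `beta > 0.95`, comfortably above the `beta > 0.5` admissibility bound.
#'
#' @inheritParams gauss_params_for
#' @return object of class `weibull_params`: list `lam`, `beta`.
#' @export
weibull_params_for <- function(x, N) {
  gp <- gauss_params_for(x, N)
  structure(list(lam = 1.4 + gp$mu / N, beta = 0.95 + gp$sigma^2 / N),
            class = "weibull_params")
}

#' Weibull probability density
#'
#' `f(x) = (beta/lam) (x/lam)^(beta-1) exp(-(x/lam)^beta)` for `x >= 0`.
#'
#' @param x numeric vector of evaluation points, all `>= 0`.
#' @param params a [weibull_params][weibull_params_for] (or list with `lam`,
#'   `beta`); requires `lam > 0` and `beta > 0.5`.
#' @return density values.
#' @export
weibull_pdf <- function(x, params) {
  if (any(x < 0)) stop("Weibull density is defined for x >= 0 only")
  if (params$lam <= 0) stop("Weibull scale parameter must be positive")
  if (params$beta <= 0.5) stop("Weibull shape parameter must exceed 0.5")
  stats::dweibull(x, shape = params$beta, scale = params$lam)
}
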