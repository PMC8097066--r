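# Agreement metrics between stochastic class trajectories and deterministic
# species trajectories.

#' Root-mean-square error between two series
#'
#' @param a,b numeric series of equal length (>= 2) on a common time grid.
#' @return `sqrt(mean((a - b)^2))`, in the units of the inputs.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 2) stop("need at least 2 points")
  sqrt(mean((a - b)^2))
}

#' Coefficient of variation of the model disagreement
#'
#' Defined here as RMSE divided by the mean of the reference series `b`
#' over the compared horizon. (Alternative normalizations — mean of both
#' series, or the reference range — are possible; the chosen definition is
#' recorded in every [compare_models()] report.)
#'
#' @inheritParams rmse
#' @return dimensionless CV, >= 0.
#' @export
coefficient_of_variation <- function(a, b) {
  m <- mean(b)
  if (m == 0) stop("reference series has zero mean: CV undefined")
  rmse(a, b) / m
}

#' Compare stochastic and deterministic hydrolysis trajectories
#'
#' Maps stochastic class concentrations onto deterministic species (by
#' default class `N - 1` onto glucose and class `N` onto HMF), restricts
#' both to the common time grid (the coarser grid; no interpolation), and
#' reports per-species RMSE and CV together with their maxima.
#'
#' @param stochastic a [state_trajectory][simulate_hydrolysis] with
#'   concentrations filled (pass `c_C0` when simulating).
#' @param deterministic a data.frame from [simulate_cgh()].
#' @param mapping named integer vector: names are deterministic columns
#'   (`"c_G"`, `"c_HMF"`, `"c_C"`), values the stochastic class indices;
#'   default `c(c_G = N - 1, c_HMF = N)`.
#' @return object of class `agreement_report`: list with `species` table
#'   (rmse_g_per_L, cv per mapped species), `max_rmse`, `max_cv`,
#'   `n_points`, `mapping`, `cv_definition`.
#' @export
compare_models <- function(stochastic, deterministic, mapping = NULL) {
  stopifnot(inherits(stochastic, "state_trajectory"))
  if (is.null(stochastic$concentrations)) {
    stop("stochastic trajectory has no concentrations: simulate with c_C0")
  }
  if (is.null(mapping)) {
    mapping <- c(c_G = stochastic$N - 1L, c_HMF = stochastic$N)
  }
  if (is.null(names(mapping)) || !all(names(mapping) %in% names(deterministic))) {
    stop("mapping names must be deterministic trajectory columns")
  }
  common <- intersect(round(stochastic$times, 9), round(deterministic$time_s, 9))
  if (length(common) < 2) stop("trajectories share fewer than 2 time points")
  si <- match(common, round(stochastic$times, 9))
  di <- match(common, round(deterministic$time_s, 9))
  species <- do.call(rbind, lapply(names(mapping), function(sp) {
    a <- stochastic$concentrations[si, mapping[[sp]] + 1]
    b <- deterministic[[sp]][di]
    data.frame(species = sp, class_index = mapping[[sp]],
               rmse_g_per_L = rmse(a, b),
               cv = coefficient_of_variation(a, b))
  }))
  structure(
    list(species = species,
         max_rmse = max(species$rmse_g_per_L), max_cv = max(species$cv),
         n_points = length(common), mapping = mapping,
         cv_definition = "rmse / mean(reference)"),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$n_points, " common time points\n", sep = "")
  print(x$species, row.names = FALSE)
  cat("max RMSE:", format(x$max_rmse, digits = 4), "g/L; max CV:",
      format(x$max_cv, digits = 4), "(", x$cv_definition, ")\n")
  invisible(x)
}

#' Write an agreement report to JSON
#'
#' @param report an [agreement_report][compare_models].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(
    list(species = report$species, max_rmse = report$max_rmse,
         max_cv = report$max_cv, n_points = report$n_points,
         mapping = as.list(report$mapping),
         cv_definition = report$cv_definition),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
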