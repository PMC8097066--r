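# CSV round-trip I/O for matrices and trajectories, plus the shipped
# reference matrix. Numbers are serialized with 17 significant digits so
# read(write(x)) is exact.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write a transition matrix to CSV
#'
#' Row-major values with a commented metadata header (`N`, distribution,
#' conventions, `dt`). Full 17-digit precision; [read_matrix_csv()]
#' round-trips exactly.
#'
#' @param tm a [transition_matrix][build_transition_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(tm, path) {
  stopifnot(inherits(tm, "transition_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# N=", tm$N),
    paste0("# distribution=", tm$distribution),
    paste0("# arg_convention=", tm$arg_convention),
    paste0("# normalization_mode=", tm$normalization_mode),
    paste0("# dt=", fmt17(tm$dt))
  ), con)
  utils::write.table(matrix(fmt17(tm$P), nrow(tm$P)), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition matrix written by [write_matrix_csv()]
#'
#' @param path file path.
#' @return a `transition_matrix`.
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  P <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                   sep = ",", header = FALSE))
  dimnames(P) <- NULL
  structure(
    list(P = P, N = as.integer(meta$N), distribution = meta$distribution,
         arg_convention = meta$arg_convention,
         normalization_mode = meta$normalization_mode,
         dt = as.numeric(meta$dt), column0_deficit = 1 - sum(P[, 1])),
    class = "transition_matrix"
  )
}

#' Write a trajectory to CSV
#'
#' Long format, one row per (time, class): columns `time_s`, `class_index`,
#' `mass_fraction`, `concentration_g_per_L`.
#'
#' @param traj a [state_trajectory][simulate_hydrolysis].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "state_trajectory"))
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference worked-example transition matrix (N = 10, Gauss label)
#'
#' An 11 x 11 reference transition matrix for the 10-cellobiose worked
#' example, recorded to three decimals and shipped as a plain-text
#' fixture. It is used for internal-consistency regression only: its
#' off-diagonal profile repeats a single jump profile across columns and
#' its (0, 0) entry equals the Weibull constant `3.5/(N+1)` rather than the
#' Gauss `1/(N+1)`, so it is not reproducible from the documented
#' distribution formulas (see the vignette).
#'
#' @return an 11 x 11 numeric matrix (columns are source classes).
#' @export
printed_reference_matrix <- function() {
  path <- system.file("extdata", "reference_gauss_matrix_N10.csv",
                      package = "cellhydro", mustWork = TRUE)
  P <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(P) <- NULL
  P
}
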