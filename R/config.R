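# Run configuration: a validated bundle of scenario settings, with defaults
# matching the two worked scenarios (10 cellobiose units with dt = 100 s;
# 100 units with dt = 10 s, modulated at T = 483 K vs 453 K and 4% vs 1%
# acid).

run_config_fields <- c(
  "n_units", "distribution", "arg_convention", "normalization_mode",
  "dt_s", "n_steps", "c_C0_g_per_L", "T_K", "T_ref_K", "c_a_pct",
  "c_a_ref_pct", "acid_order", "E_Am_J_per_mol", "E_AG_J_per_mol",
  "arrhenius_sign", "terminal_scheme", "modulated", "output_dir"
)

#' Build a validated run configuration
#'
#' Unspecified fields take scenario defaults keyed on `n_units`: the
#' 10-unit scenario uses `dt_s = 100`, the 100-unit scenario `dt_s = 10`
#' and the glucose-then-HMF ladder. `modulated = TRUE` applies the acid and
#' temperature factors to the transition matrix in [run_scenario()].
#'
#' @param ... any of the fields listed in Details; unknown names are an
#'   error.
#' @details Fields: `n_units`, `distribution`, `arg_convention`,
#'   `normalization_mode`, `dt_s`, `n_steps`, `c_C0_g_per_L`, `T_K`,
#'   `T_ref_K`, `c_a_pct`, `c_a_ref_pct`, `acid_order`, `E_Am_J_per_mol`,
#'   `E_AG_J_per_mol`, `arrhenius_sign`, `terminal_scheme`, `modulated`,
#'   `output_dir`.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  unknown <- setdiff(names(user), run_config_fields)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  n_units <- if (!is.null(user$n_units)) user$n_units else 10
  big <- n_units >= 100
  cfg <- list(
    n_units = n_units,
    distribution = "gauss",
    arg_convention = "source_class",
    normalization_mode = "conservative",
    dt_s = if (big) 10 else 100,
    n_steps = 100,
    c_C0_g_per_L = 100,
    T_K = 483, T_ref_K = 453,
    c_a_pct = 4, c_a_ref_pct = 1,
    acid_order = 1,
    E_Am_J_per_mol = 170e3, E_AG_J_per_mol = 137e3,
    arrhenius_sign = "as_printed",
    terminal_scheme = if (big) "glucose_then_hmf" else "glucose_terminal",
    modulated = FALSE,
    output_dir = "."
  )
  cfg[names(user)] <- user
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_pos <- function(field) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1 ||
        !is.finite(cfg[[field]]) || cfg[[field]] <= 0) {
      stop("config field `", field, "` must be a positive number")
    }
  }
  for (f in c("n_units", "dt_s", "c_C0_g_per_L", "T_K", "T_ref_K",
              "c_a_pct", "c_a_ref_pct", "E_Am_J_per_mol", "E_AG_J_per_mol")) {
    check_pos(f)
  }
  if (!is.numeric(cfg$n_steps) || cfg$n_steps < 0) {
    stop("config field `n_steps` must be >= 0")
  }
  match.arg(cfg$distribution, c("gauss", "weibull"))
  match.arg(cfg$arg_convention, c("source_class", "jump_distance"))
  match.arg(cfg$normalization_mode, c("conservative", "strict_paper"))
  match.arg(cfg$arrhenius_sign, c("as_printed", "physical"))
  match.arg(cfg$terminal_scheme, c("glucose_terminal", "glucose_then_hmf"))
  invisible(cfg)
}

#' Load a run configuration from JSON or YAML
#'
#' The format is chosen by extension (`.json` vs `.yml`/`.yaml`). An empty
#' file yields the full default scenario. Unknown keys and invariant
#' violations are errors naming the field.
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) NULL else jsonlite::fromJSON(txt)
  }
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Save a run configuration
#'
#' JSON or YAML by extension; [load_config()] of the result reproduces the
#' configuration exactly.
#'
#' @param cfg a [run_config()].
#' @param path output path (`.json`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(unclass(cfg), path)
  } else {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run a configured hydrolysis scenario
#'
#' Builds the ladder and transition matrix, applies modulation if
#' requested, and simulates the discrete-time chain.
#'
#' @param cfg a [run_config()].
#' @return list: `ladder`, `tm` (possibly modulated), `trajectory`,
#'   `config`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ladder <- build_ladder(cfg$n_units, cfg$terminal_scheme)
  tm <- build_transition_matrix(ladder$N, cfg$distribution,
                                cfg$arg_convention, cfg$normalization_mode,
                                dt = cfg$dt_s)
  if (isTRUE(cfg$modulated)) {
    cond <- process_conditions(
      T_K = cfg$T_K, T_ref_K = cfg$T_ref_K, c_a_pct = cfg$c_a_pct,
      c_a_ref_pct = cfg$c_a_ref_pct, acid_order = cfg$acid_order,
      E_Am_J_per_mol = cfg$E_Am_J_per_mol,
      E_AG_J_per_mol = cfg$E_AG_J_per_mol, dt_s = cfg$dt_s,
      c_C0_g_per_L = cfg$c_C0_g_per_L, arrhenius_sign = cfg$arrhenius_sign)
    tm <- apply_modulation(tm, modulation_factors(cond))
  }
  traj <- simulate_hydrolysis(tm, cfg$n_steps, c_C0 = cfg$c_C0_g_per_L)
  list(ladder = ladder, tm = tm, trajectory = traj, config = cfg)
}
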