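#' Read an observed time-value dataset from delimited text
#'
#' Imports observations from a comma-delimited file with a header row,
#' selecting the time and value columns by index (mirroring the usual
#' import-dataset dialog). Non-numeric cells are rejected with the offending
#' row numbers.
#'
#' @param path Path to a CSV file.
#' @param x_col,y_col 1-based column indices of the time and value columns.
#' @return A tibble of class `pk_observations` with columns `time` and
#'   `value`, in file order.
#' @export
read_observations <- function(path, x_col = 1, y_col = 2) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!nrow(raw)) stop("Empty dataset: ", path, call. = FALSE)
  for (col in c(x_col, y_col)) {
    if (col < 1 || col > ncol(raw))
      stop(sprintf("Column index %d not present (file has %d columns).",
                   col, ncol(raw)), call. = FALSE)
  }
  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !raw[[col]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("Non-numeric %s value(s) in row(s): %s.", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    v
  }
  out <- tibble(time = parse_num(x_col, "time"),
                value = parse_num(y_col, "value"))
  if (any(!is.finite(out$time)))
    stop("All observation times must be finite.", call. = FALSE)
  class(out) <- c("pk_observations", class(out))
  out
}

#' Write a trajectory as delimited text
#'
#' Comma-delimited export with a mandatory header row, `time` as the first
#' column and one column per state/output series. The file is bit-stable for
#' fixed inputs and seed: re-exporting an identical run yields a
#' byte-identical file.
#'
#' @param trajectory A `pk_trajectory` (or any data frame with a `time`
#'   column).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_table <- function(trajectory, path) {
  stopifnot("time" %in% names(trajectory))
  d <- as.data.frame(trajectory)
  d <- d[, c("time", setdiff(names(d), "time")), drop = FALSE]
  readr::write_csv(d, path)  # shortest round-trippable numeric representation
  invisible(path)
}

#' Generate a synthetic observed PK dataset
#'
#' Simulates a model, samples the chosen output at the requested times, and
#' applies multiplicative lognormal measurement noise:
#' `observed = predicted * exp(N(0, noise_sd))`. With `noise_sd = 0` the
#' observations equal the model predictions exactly. Every test dataset in
#' the package is produced this way, so tests are self-contained.
#'
#' @param model A `pk_model` or character model id.
#' @param regimen A [dose_regimen()] (or list).
#' @param config A [solver_config()] whose window covers `sample_times`.
#' @param sample_times Observation times.
#' @param noise_sd Lognormal noise standard deviation (sd of the log
#'   residuals).
#' @param seed Optional integer seed (reproducible datasets).
#' @param output Trajectory column to observe (default `"conc"` if present,
#'   else the last non-time column).
#' @param model_params Parameter list when `model` is a character id.
#' @return A tibble of class `pk_observations` with `time` and `value`.
#' @examples
#' cfg <- solver_config(stop_time = 48, dt = 0.1)
#' generate_pk_dataset("one_cpt_oral", dose_regimen(100, n_doses = 1), cfg,
#'                     sample_times = c(1, 4, 12), noise_sd = 0)
#' @export
generate_pk_dataset <- function(model, regimen, config, sample_times,
                                noise_sd = 0, seed = NULL, output = NULL,
                                model_params = list()) {
  if (any(sample_times < config$start_time | sample_times > config$stop_time))
    stop("`sample_times` must lie within the solver window.", call. = FALSE)
  if (is.character(model)) model <- pk_model(model, model_params)
  traj <- pk_integrate(model, regimen, config = config)
  out <- output %||% if ("conc" %in% names(traj)) "conc" else
    tail(setdiff(names(traj), "time"), 1)
  pred <- approx(traj$time, traj[[out]], xout = sample_times, rule = 2)$y
  eps <- with_master_seed(seed, rnorm(length(sample_times), 0, noise_sd))
  res <- tibble(time = sample_times, value = pred * exp(eps))
  class(res) <- c("pk_observations", class(res))
  res
}

#' Read and write run configurations
#'
#' A run configuration is a nested key-value structure (YAML on disk)
#' holding the solver block, the model block (id + parameters), regimen
#' block(s), and optional population/trial/sweep blocks plus the master
#' seed. `read_run_config()` and `write_run_config()` round-trip losslessly,
#' so parse - serialize - parse is idempotent.
#'
#' @param path Path to a YAML configuration file.
#' @return `read_run_config()`: a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble simulation pieces from a run configuration
#'
#' Maps the declarative blocks of a [read_run_config()] result onto package
#' objects: `solver` to [solver_config()], `model` to [pk_model()],
#' `regimens` to a list of [dose_regimen()].
#'
#' @param config A `run_config` list.
#' @return A list with elements `config` (solver), `model`, `regimens`,
#'   `seed`.
#' @export
build_run <- function(config) {
  solver <- do.call(solver_config, config$solver %||% list())
  model <- pk_model(config$model$id, config$model$params %||% list())
  regs <- lapply(config$regimens %||% list(), function(r)
    do.call(dose_regimen, r))
  list(config = solver, model = model, regimens = regs,
       seed = config$seed %||% NULL)
}

#' Execute a configured simulation run
#'
#' Runs the simulation a configuration describes and (optionally) writes the
#' trajectory table plus a metadata sidecar (`<out>.meta.yaml` with the
#' config echo, seed and package version) sufficient to reproduce the output
#' byte-identically.
#'
#' @param config A `run_config` list (see [read_run_config()]).
#' @param out Optional output CSV path.
#' @return The trajectory tibble, invisibly when `out` is given.
#' @export
simulate_run <- function(config, out = NULL) {
  run <- build_run(config)
  traj <- pk_integrate(run$model, run$regimens, config = run$config)
  if (!is.null(out)) {
    write_trajectory_table(traj, out)
    meta <- list(config = unclass(config), seed = run$seed,
                 package_version = as.character(utils::packageVersion("pkpdtrial")))
    yaml::write_yaml(meta, paste0(out, ".meta.yaml"))
    return(invisible(traj))
  }
  traj
}
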