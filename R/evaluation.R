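#' Value of a simulated series at an evaluation time
#'
#' Returns the value at the first grid time `t` with
#' `|t - eval_time| < dt` — the programmatic equivalent of reading a trough
#' or evaluation-time statistic off a simulation grid, tolerant of the small
#' numerical misses that occur when the evaluation time is not exactly on
#' the grid. If no time matches, an explicit missing value (`NA`) is
#' returned rather than a sentinel.
#'
#' @param data Data frame with a time column and a value column.
#' @param eval_time Evaluation time.
#' @param dt Matching half-window (typically the integration step).
#' @param time,value Column names; `value` defaults to the first non-time
#'   column.
#' @return A single value, or `NA_real_` when no grid time matches.
#' @examples
#' tr <- tibble::tibble(time = seq(0, 100, 0.1), conc = exp(-0.1 * seq(0, 100, 0.1)))
#' statistic_at_time(tr, eval_time = 72, dt = 0.1)
#' @export
statistic_at_time <- function(data, eval_time, dt, time = "time",
                              value = NULL) {
  stopifnot(nrow(data) > 0)
  if (is.null(value)) value <- setdiff(names(data), time)[1]
  hit <- which(abs(data[[time]] - eval_time) < dt)
  if (!length(hit)) return(NA_real_)
  data[[value]][hit[1]]
}

# Evenly spaced sweep grid from + k*(to-from)/(steps-1); steps = 1 -> from.
sweep_grid <- function(from, to, steps) {
  stopifnot(steps >= 1)
  if (steps == 1) return(from)
  from + (0:(steps - 1)) * (to - from) / (steps - 1)
}

#' Parameter sweep over full simulations
#'
#' Runs one complete simulation per value of a parameter grid and records a
#' summary statistic of each requested output series — the scripted
#' equivalent of a parameter plot. The parameter may be a structural model
#' parameter or `"dose"` (the regimen amount).
#'
#' @param model A [pk_model()] id-and-parameter pair: either a `pk_model`
#'   object (rebuilt per grid value) or a character id plus `model_params`.
#' @param regimen A [dose_regimen()].
#' @param config A [solver_config()].
#' @param param Name of the parameter to vary (`"dose"` or a model
#'   parameter).
#' @param from,to,steps Sweep grid: `steps` evenly spaced values from `from`
#'   to `to` (the sequence 100, 110, ..., 200 for 11 steps from 100 to 200).
#' @param outputs Character vector of trajectory columns to summarize;
#'   defaults to all non-time columns.
#' @param stat One of `"min"`, `"max"`, `"mean"`, `"at_time"`.
#' @param at_time,at_dt Evaluation time and matching window for
#'   `stat = "at_time"` (`at_dt` defaults to the solver `dt`).
#' @param model_params Base parameter list when `model` is a character id.
#' @return A tibble with columns `param`, `value` (grid value), `output`,
#'   `statistic`, `result`.
#' @examples
#' cfg <- solver_config(stop_time = 48, dt = 0.1)
#' parameter_sweep("one_cpt_oral", dose_regimen(100, n_doses = 1), cfg,
#'                 param = "dose", from = 100, to = 200, steps = 3,
#'                 outputs = "conc", stat = "max")
#' @export
parameter_sweep <- function(model, regimen, config, param, from, to, steps,
                            outputs = NULL, stat = c("min", "max", "mean",
                                                     "at_time"),
                            at_time = NULL, at_dt = NULL,
                            model_params = list()) {
  stat <- match.arg(stat)
  grid <- sweep_grid(from, to, steps)
  if (inherits(model, "pk_model")) {
    model_id <- model$id
    base_params <- model$params
  } else {
    model_id <- model
    base_params <- pk_model(model_id, model_params)$params
  }
  if (!param %in% c("dose", names(base_params)))
    stop("Parameter `", param, "` is not in the model (or \"dose\").",
         call. = FALSE)
  if (stat == "at_time") {
    if (is.null(at_time)) stop("`at_time` is required for stat = \"at_time\".",
                               call. = FALSE)
    if (is.null(at_dt)) at_dt <- config$dt
  }

  purrr::map_dfr(grid, function(v) {
    pars <- base_params
    rg <- regimen
    if (param == "dose") rg$amount <- v else pars[[param]] <- v
    pars <- pars[setdiff(names(pars), "koff")]
    mod <- pk_model(model_id, pars)
    traj <- pk_integrate(mod, rg, config = config)
    outs <- outputs %||% setdiff(names(traj), "time")
    purrr::map_dfr(outs, function(o) {
      res <- switch(stat,
        min = min(traj[[o]]),
        max = max(traj[[o]]),
        mean = mean(traj[[o]]),
        at_time = statistic_at_time(traj, at_time, at_dt, value = o))
      tibble(param = param, value = v, output = o, statistic = stat,
             result = res)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean, SD and normal-quantile interval of a sample
#'
#' Summary of a simulated array: mean, standard deviation and the interval
#' `m -/+ z * sd`. The default multiplier is the 97.5th percentile of the
#' standard normal (`qnorm(0.975)`, 1.96 to two decimals), giving a central
#' 95% normal interval. The SD uses the population (denominator `n`)
#' estimator to match the arraystatistics convention of simulation tools.
#'
#' @param values Non-empty numeric vector.
#' @param z Normal quantile multiplier.
#' @return A one-row tibble with `n`, `m`, `sd`, `int_low`, `int_high`, `z`.
#' @examples
#' array_summary(c(1, 2, 3))
#' @export
array_summary <- function(values, z = qnorm(0.975)) {
  if (!length(values)) stop("`values` must be non-empty.", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  tibble(n = length(values), m = m, sd = s,
         int_low = m - z * s, int_high = m + z * s, z = z)
}
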