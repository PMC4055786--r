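#' Least-squares fit of a structural model to observed data
#'
#' Minimizes the sum of squared residuals between observed values and the
#' simulated output series, treating all observations as independent (no
#' weighting, no subject grouping). This is a deliberately simple curve-fit:
#' the estimates are starting values for mixed-effects estimation in
#' dedicated tools, not substitutes for it. The optimizer is a
#' derivative-free local search (Nelder-Mead) run from each provided start
#' (multistart); parameters are searched on the log scale, so only positive
#' values are considered. Predictions at observation times are obtained by
#' linear interpolation of the simulated trajectory on its output grid.
#'
#' Identifiability caveat: for first-order absorption models, `ka` and `ke`
#' can exchange roles (flip-flop kinetics); starts should be placed near the
#' intended mode.
#'
#' @param data Data frame of observations with `time` and `value` columns
#'   (see [read_observations()]).
#' @param model A `pk_model` object or character model id.
#' @param regimen A [dose_regimen()] (or list of them).
#' @param config A [solver_config()]; its window must cover the observation
#'   times.
#' @param fit Named list of starting values, one or two starts per
#'   parameter, e.g. `list(ka = c(0.05, 0.3), ke = 0.1)`. Each distinct
#'   start-slot defines one multistart run.
#' @param output Trajectory column compared with the observations (default
#'   `"conc"` if present, else the last state column).
#' @param model_params Base parameter list when `model` is a character id.
#' @param control Passed to [stats::optim()]; defaults to a tight relative
#'   tolerance and a generous iteration cap.
#' @return An object of class `pk_fit`: `estimates` (named numeric), `rss`,
#'   `converged`, `iterations`, `starts` (per-start results), plus the
#'   inputs needed to recompute predictions. Non-convergence is flagged,
#'   never thrown.
#' @examples
#' cfg <- solver_config(start_time = -1, stop_time = 48, dt = 0.1)
#' obs <- generate_pk_dataset("one_cpt_oral", dose_regimen(100, n_doses = 1),
#'                            cfg, sample_times = c(2, 5, 10, 20, 40),
#'                            model_params = list(ka = 0.1, ke = 0.2))
#' fit <- least_squares_fit(obs, "one_cpt_oral",
#'                          dose_regimen(100, n_doses = 1), cfg,
#'                          fit = list(ka = 0.15, ke = 0.25))
#' tidy(fit)
#' @export
least_squares_fit <- function(data, model, regimen, config, fit,
                              output = NULL, model_params = list(),
                              control = list(reltol = 1e-12, maxit = 2000)) {
  stopifnot(is.list(fit), length(fit) > 0, nrow(data) >= 2)
  if (!all(c("time", "value") %in% names(data)))
    stop("`data` must have `time` and `value` columns.", call. = FALSE)
  if (inherits(model, "pk_model")) {
    model_id <- model$id
    base_params <- model$params
  } else {
    model_id <- model
    base_params <- pk_model(model_id, model_params)$params
  }
  fit_names <- names(fit)
  unknown <- setdiff(fit_names, names(base_params))
  if (length(unknown))
    stop("Fit parameter(s) not in model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(vapply(fit, function(g) any(g <= 0), logical(1))))
    stop("Starting values must be positive (log-scale search).", call. = FALSE)

  predict_at <- function(theta) {
    pars <- base_params
    pars[fit_names] <- as.list(theta)
    pars <- pars[setdiff(names(pars), "koff")]
    mod <- pk_model(model_id, pars)
    traj <- pk_integrate(mod, regimen, config = config)
    out <- output %||% if ("conc" %in% names(traj)) "conc" else
      tail(setdiff(names(traj), "time"), 1)
    approx(traj$time, traj[[out]], xout = data$time, rule = 2)$y
  }
  objective <- function(log_theta) {
    pred <- tryCatch(predict_at(exp(log_theta)), error = function(e) NULL)
    if (is.null(pred)) return(1e300)
    sum((data$value - pred)^2)
  }

  n_starts <- max(vapply(fit, length, integer(1)))
  starts <- lapply(seq_len(n_starts), function(k)
    vapply(fit, function(g) g[min(k, length(g))], numeric(1)))
  starts <- unique(starts)

  runs <- lapply(starts, function(s) {
    if (length(s) == 1) {
      opt <- optim(log(s), objective, method = "Brent",
                   lower = log(s) - 10, upper = log(s) + 10)
      iters <- NA_integer_
    } else {
      opt <- optim(log(s), objective, method = "Nelder-Mead",
                   control = control)
      iters <- unname(opt$counts[1])
    }
    list(start = s, estimates = setNames(exp(opt$par), fit_names),
         rss = opt$value, converged = opt$convergence == 0,
         iterations = iters)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "rss"))]]

  structure(
    list(estimates = best$estimates, rss = best$rss,
         converged = best$converged, iterations = best$iterations,
         starts = runs, data = data, model_id = model_id,
         base_params = base_params, regimen = regimen, config = config,
         output = output, predict_at = predict_at),
    class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> RSS =", format(x$rss, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$estimates)
  invisible(x)
}

#' @rdname least_squares_fit
#' @param x A `pk_fit` object.
#' @param ... Unused.
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname least_squares_fit
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, iterations = x$iterations,
         n_obs = nrow(x$data), n_starts = length(x$starts))
}

#' Fitted predictions at the observation times
#'
#' @param object A `pk_fit`.
#' @param ... Unused.
#' @return The fitted `data` tibble with a `fitted` column appended.
#' @export
fitted_observations <- function(object, ...) {
  stopifnot(inherits(object, "pk_fit"))
  dplyr::mutate(object$data, fitted = object$predict_at(object$estimates))
}
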