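#' Solver configuration
#'
#' Bundles the integration method and the time/step controls used by
#' [pk_integrate()]. Fixed-step methods (`euler`, `rk2`, `rk4`) advance on a
#' grid anchored at `start_time` with step `dt`; the `adaptive_stiff` method
#' is an implicit variable-step solver honouring `tolerance` between step
#' bounds `dt_min` and `dt_max`.
#'
#' `start_time` defaults to -1 time unit so that the grid starts before a
#' first dose at time 0; dosing exactly at the integration start is a classic
#' source of half-delivered doses in simulation tools.
#'
#' @param method One of `"euler"`, `"rk2"`, `"rk4"`, `"adaptive_stiff"`.
#' @param start_time,stop_time Integration window; `start_time < stop_time`.
#' @param dt Fixed step size (> 0), used by the fixed-step methods.
#' @param dt_min,dt_max Step-size bounds for the adaptive method.
#' @param tolerance Relative tolerance for the adaptive method.
#' @param dt_out Output interval: 0 returns every step (fixed-step methods)
#'   or a `dt_max`-spaced grid (adaptive); a positive value returns an evenly
#'   spaced grid obtained by linear interpolation of the accepted steps.
#' @return An object of class `solver_config`.
#' @examples
#' solver_config(stop_time = 100, dt = 0.02)
#' @export
solver_config <- function(method = c("rk4", "euler", "rk2", "adaptive_stiff"),
                          start_time = -1, stop_time = 100, dt = 0.02,
                          dt_min = 1e-3, dt_max = 0.1, tolerance = 1e-3,
                          dt_out = 0) {
  method <- match.arg(method)
  if (!is.finite(start_time) || !is.finite(stop_time) || stop_time <= start_time)
    stop("`stop_time` must be greater than `start_time`.", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  if (dt_min > dt_max) stop("`dt_min` must not exceed `dt_max`.", call. = FALSE)
  if (dt_out < 0) stop("`dt_out` must be >= 0.", call. = FALSE)
  structure(
    list(method = method, start_time = start_time, stop_time = stop_time,
         dt = dt, dt_min = dt_min, dt_max = dt_max, tolerance = tolerance,
         dt_out = dt_out),
    class = "solver_config"
  )
}

#' Dose regimen
#'
#' One administration pattern: repeated boluses into a target compartment, or
#' a repeated zero-order infusion. Bolus amounts are delivered as discrete
#' state increments of `amount * bioavailability` at the scheduled times
#' (snapped forward to the integration grid if necessary); infusions enter as
#' a rate term while `(t - first_time) mod interval < infusion_duration`.
#'
#' @param amount Dose amount (mass, e.g. mg). May be a vector when `target`
#'   indexes several state elements (e.g. one depot per simulated subject).
#' @param route `"bolus"` or `"infusion"`.
#' @param first_time Time of the first administration.
#' @param interval Dosing interval (> 0).
#' @param n_doses Number of doses; 0 means unlimited within the simulation
#'   window.
#' @param lag Absorption lag time added to every dose time (>= 0).
#' @param infusion_rate Zero-order input rate (mass/time), infusion route.
#' @param infusion_duration Duration of each infusion
#'   (`<= interval`).
#' @param bioavailability Fraction of `amount` reaching the target, in
#'   `[0, 1]`.
#' @param target Name (or integer indices) of the state variable(s) receiving
#'   the dose.
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(100, first_time = 0, interval = 24, n_doses = 3)
#' dose_regimen(route = "infusion", infusion_rate = 7,
#'              infusion_duration = 2, interval = 24, target = "comp1")
#' @export
dose_regimen <- function(amount = 0, route = c("bolus", "infusion"),
                         first_time = 0, interval = 24, n_doses = 0,
                         lag = 0, infusion_rate = 0, infusion_duration = 0,
                         bioavailability = 1, target = "depot") {
  route <- match.arg(route)
  if (any(amount < 0)) stop("`amount` must be >= 0.", call. = FALSE)
  if (interval <= 0) stop("`interval` must be > 0.", call. = FALSE)
  if (lag < 0) stop("`lag` must be >= 0.", call. = FALSE)
  if (n_doses < 0) stop("`n_doses` must be >= 0.", call. = FALSE)
  if (route == "infusion") {
    if (infusion_rate < 0 || infusion_duration < 0)
      stop("Infusion rate and duration must be >= 0.", call. = FALSE)
    if (infusion_duration > interval)
      stop("`infusion_duration` must not exceed `interval`.", call. = FALSE)
  }
  if (bioavailability < 0 || bioavailability > 1)
    stop("`bioavailability` must be in [0, 1].", call. = FALSE)
  structure(
    list(amount = amount, route = route, first_time = first_time,
         interval = interval, n_doses = n_doses, lag = lag,
         infusion_rate = infusion_rate, infusion_duration = infusion_duration,
         bioavailability = bioavailability, target = target),
    class = "dose_regimen"
  )
}

#' Scheduled bolus dose times within a simulation window
#'
#' Expands a bolus regimen into its event list: times
#' `first_time + lag + k * interval` for `k = 0, 1, ...` (all `k` if
#' `n_doses = 0`, else `k < n_doses`), intersected with the solver window.
#' Each event carries `amount * bioavailability`.
#'
#' @param regimen A [dose_regimen()].
#' @param config A [solver_config()].
#' @return A tibble with columns `time` and `amount` (the delivered amount;
#'   for vector-valued regimens the total across targets).
#' @examples
#' cfg <- solver_config(start_time = -1, stop_time = 100)
#' dose_times(dose_regimen(100, interval = 24), cfg)
#' @export
dose_times <- function(regimen, config) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(config, "solver_config"))
  if (regimen$route != "bolus" || all(regimen$amount == 0))
    return(tibble(time = numeric(), amount = numeric()))
  t0 <- regimen$first_time + regimen$lag
  kmax <- if (regimen$n_doses > 0) regimen$n_doses - 1 else
    max(-1, floor((config$stop_time - t0) / regimen$interval + 1e-9))
  if (kmax < 0) return(tibble(time = numeric(), amount = numeric()))
  times <- t0 + (0:kmax) * regimen$interval
  keep <- times >= config$start_time - 1e-12 & times <= config$stop_time + 1e-12
  tibble(time = times[keep],
         amount = sum(regimen$amount) * regimen$bioavailability)
}

#' Zero-order infusion rate at a time point
#'
#' Modulo-window infusion input: the rate is delivered while `t >= 0` and
#' `t mod freq < duration`, and is zero otherwise.
#'
#' @param t Time (vectorized).
#' @param rate Infusion rate (mass/time, >= 0).
#' @param duration Infusion duration per interval (`<= freq`).
#' @param freq Interval between infusion starts.
#' @return Input rate at `t`.
#' @examples
#' infusion_rate_at(c(-1, 1, 25), rate = 7, duration = 2, freq = 24)
#' @export
infusion_rate_at <- function(t, rate, duration, freq) {
  if (duration < 0 || freq <= 0) stop("Negative duration or non-positive frequency.", call. = FALSE)
  if (rate < 0) stop("`rate` must be >= 0.", call. = FALSE)
  if (duration > freq) stop("`duration` must not exceed `freq`.", call. = FALSE)
  ifelse(t >= 0 & (t %% freq) < duration, rate, 0)
}

#' Saturable (capped) absorption rate
#'
#' First-order absorption from a depot, capped at `absmax`:
#' `min(absmax, ka * depot_amount)`.
#'
#' @param depot_amount Amount in the absorption depot (>= 0, vectorized).
#' @param ka First-order absorption rate constant (1/time).
#' @param absmax Maximum absorbable rate (mass/time).
#' @return Absorption rate (mass/time).
#' @examples
#' saturable_absorption_rate(100, ka = 1, absmax = 20)
#' @export
saturable_absorption_rate <- function(depot_amount, ka, absmax) {
  stopifnot(all(depot_amount >= 0), ka >= 0, absmax >= 0)
  pmin(absmax, ka * depot_amount)
}

#' Single explicit integration step
#'
#' Advances a state vector by one step of the named method: forward Euler,
#' the midpoint (second-order Runge-Kutta) rule, or the classical
#' fourth-order Runge-Kutta scheme.
#'
#' @param method `"euler"`, `"rk2"`, or `"rk4"`.
#' @param rhs Derivative function `rhs(t, state)` returning a numeric vector
#'   the same length as `state`.
#' @param t Current time.
#' @param state Current state vector (named or not).
#' @param dt Step size (> 0).
#' @return The state after one step.
#' @examples
#' ode_step("rk4", function(t, y) -y, t = 0, state = c(y = 1), dt = 0.1)
#' @export
ode_step <- function(method, rhs, t, state, dt) {
  if (dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  k1 <- rhs(t, state)
  .check_finite_deriv(k1, t, state)
  out <- switch(method,
    euler = state + dt * k1,
    rk2 = {
      k2 <- rhs(t + dt / 2, state + dt / 2 * k1)
      state + dt * k2
    },
    rk4 = {
      k2 <- rhs(t + dt / 2, state + dt / 2 * k1)
      k3 <- rhs(t + dt / 2, state + dt / 2 * k2)
      k4 <- rhs(t + dt, state + dt * k3)
      state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    },
    stop("Unknown fixed-step method: ", method, call. = FALSE)
  )
  out
}

.check_finite_deriv <- function(deriv, t, state) {
  bad <- which(!is.finite(deriv))
  if (length(bad)) {
    nm <- names(state)[bad[1]]
    if (is.null(nm) || is.na(nm) || !nzchar(nm)) nm <- paste0("state[", bad[1], "]")
    stop(sprintf("Non-finite derivative for %s at t = %g.", nm, t), call. = FALSE)
  }
  invisible(TRUE)
}

# Resolve a regimen target to integer state indices.
.target_indices <- function(target, state_names) {
  if (is.numeric(target)) {
    idx <- as.integer(target)
    if (any(idx < 1) || any(idx > length(state_names)))
      stop("Dose target index out of range.", call. = FALSE)
    return(idx)
  }
  idx <- which(state_names %in% target)
  if (!length(idx))
    stop("Unknown dose target compartment: ", paste(target, collapse = ", "),
         call. = FALSE)
  idx
}

#' Integrate a compartmental model with dosing events
#'
#' Solves a (possibly vectorized) ODE system over the solver window, applying
#' bolus doses as discrete state increments and infusions as zero-order rate
#' terms. Rows of the returned trajectory at exact bolus times hold the
#' *pre-dose* state for fixed-step methods (the trough convention), so that a
#' concentration read at a dose time is the value just before that dose is
#' given; the adaptive method reports the post-event state at dose times.
#'
#' Fixed-step methods use a grid anchored at `start_time`; bolus times not on
#' the grid are snapped forward to the next grid point with a warning.
#'
#' @param model A [pk_model()] object, or a derivative function
#'   `rhs(t, state, input)` where `input` is the vector of exogenous infusion
#'   rates per state element.
#' @param regimens A [dose_regimen()] or a list of them.
#' @param init Named numeric initial state. Optional when `model` is a
#'   `pk_model` (its own initial state is used).
#' @param config A [solver_config()].
#' @param outputs Named list of functions `f(t, state)` returning one derived
#'   value per time point (e.g. concentrations). Defaults to the model's own
#'   outputs for `pk_model` input.
#' @return A tibble of class `pk_trajectory`: column `time`, one column per
#'   state variable, then one per derived output.
#' @examples
#' mod <- pk_model("one_cpt_bolus", list(ke = 0.2))
#' cfg <- solver_config(start_time = -1, stop_time = 10, dt = 0.02)
#' traj <- pk_integrate(mod, dose_regimen(100, n_doses = 1, target = "central"),
#'                      config = cfg)
#' tail(traj)
#' @export
pk_integrate <- function(model, regimens = list(), init = NULL,
                         config = solver_config(), outputs = NULL) {
  stopifnot(inherits(config, "solver_config"))
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  if (inherits(model, "pk_model")) {
    rhs <- model$rhs
    if (is.null(init)) init <- model$init
    if (is.null(outputs)) outputs <- model$outputs
  } else if (is.function(model)) {
    rhs <- model
    if (is.null(init)) stop("`init` is required when `model` is a function.", call. = FALSE)
  } else stop("`model` must be a `pk_model` or a function.", call. = FALSE)
  state <- init
  if (is.null(names(state))) names(state) <- paste0("x", seq_along(state))
  snames <- names(state)

  bolus <- list(time = numeric(), idx = list(), amount = list())
  inf_reg <- list()
  for (rg in regimens) {
    stopifnot(inherits(rg, "dose_regimen"))
    idx <- .target_indices(rg$target, snames)
    if (rg$route == "bolus") {
      dt_tab <- dose_times(rg, config)
      amt <- rep_len(rg$amount * rg$bioavailability, length(idx))
      for (tt in dt_tab$time) {
        bolus$time <- c(bolus$time, tt)
        bolus$idx <- c(bolus$idx, list(idx))
        bolus$amount <- c(bolus$amount, list(amt))
      }
    } else {
      inf_reg <- c(inf_reg, list(list(regimen = rg, idx = idx)))
    }
  }

  input_at <- function(t) {
    inp <- numeric(length(state))
    for (ir in inf_reg) {
      rg <- ir$regimen
      tt <- t - rg$first_time - rg$lag
      k <- floor(tt / rg$interval)
      on <- tt >= 0 && (tt %% rg$interval) < rg$infusion_duration &&
        (rg$n_doses == 0 || k < rg$n_doses)
      if (on) inp[ir$idx] <- inp[ir$idx] + rg$infusion_rate * rg$bioavailability
    }
    inp
  }
  has_inf <- length(inf_reg) > 0

  if (config$method == "adaptive_stiff") {
    traj <- .integrate_adaptive(rhs, state, config, bolus, input_at, has_inf)
  } else {
    traj <- .integrate_fixed(rhs, state, config, bolus, input_at, has_inf)
  }

  times <- traj$times
  states <- traj$states
  colnames(states) <- snames
  out <- as_tibble(as.data.frame(states))
  out <- dplyr::bind_cols(tibble(time = times), out)
  if (!is.null(outputs) && length(outputs)) {
    for (nm in names(outputs)) {
      f <- outputs[[nm]]
      out[[nm]] <- vapply(seq_along(times),
                          function(i) f(times[i], states[i, ]), numeric(1))
    }
  }
  if (any(!is.finite(as.matrix(out))))
    stop("Trajectory contains non-finite values.", call. = FALSE)
  class(out) <- c("pk_trajectory", class(out))
  out
}

.integrate_fixed <- function(rhs, state, config, bolus, input_at, has_inf) {
  t0 <- config$start_time; t1 <- config$stop_time; dt <- config$dt
  n_steps <- ceiling((t1 - t0) / dt - 1e-9)
  grid <- t0 + (0:n_steps) * dt
  grid[n_steps + 1] <- min(grid[n_steps + 1], t1)

  # map bolus times to grid indices, snapping forward
  bolus_at <- vector("list", n_steps + 1)
  if (length(bolus$time)) {
    for (b in seq_along(bolus$time)) {
      tt <- bolus$time[b]
      k <- ceiling((tt - t0) / dt - 1e-9)
      k <- max(0L, min(as.integer(k), n_steps))
      snapped <- grid[k + 1]
      if (abs(snapped - tt) > 1e-8 * max(1, abs(tt)))
        warning(sprintf("Dose at t = %g snapped forward to grid time %g.", tt, snapped))
      bolus_at[[k + 1]] <- c(bolus_at[[k + 1]], b)
    }
  }

  method <- config$method
  states <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(state))
  stepper <- function(t, y) {
    if (has_inf) rhs(t, y, input_at(t)) else rhs(t, y, NULL)
  }
  for (k in 0:n_steps) {
    states[k + 1, ] <- state  # pre-dose record (trough convention)
    bs <- bolus_at[[k + 1]]
    if (length(bs)) for (b in bs) {
      state[bolus$idx[[b]]] <- state[bolus$idx[[b]]] + bolus$amount[[b]]
    }
    if (k < n_steps) {
      h <- grid[k + 2] - grid[k + 1]
      state <- ode_step(method, stepper, grid[k + 1], state, h)
      if (any(!is.finite(state))) {
        bad <- which(!is.finite(state))[1]
        stop(sprintf("Integration produced a non-finite value for %s at t = %g.",
                     names(state)[bad], grid[k + 2]), call. = FALSE)
      }
    }
  }

  if (config$dt_out > 0) {
    t_out <- seq(config$start_time, config$stop_time, by = config$dt_out)
    if (tail(t_out, 1) < config$stop_time - 1e-9) t_out <- c(t_out, config$stop_time)
    states <- apply(states, 2, function(col) approx(grid, col, xout = t_out)$y)
    grid <- t_out
  }
  list(times = grid, states = states)
}

.integrate_adaptive <- function(rhs, state, config, bolus, input_at, has_inf) {
  dt_out <- if (config$dt_out > 0) config$dt_out else config$dt_max
  t_out <- seq(config$start_time, config$stop_time, by = dt_out)
  if (tail(t_out, 1) < config$stop_time - 1e-9) t_out <- c(t_out, config$stop_time)

  events <- NULL
  if (length(bolus$time)) {
    ev <- do.call(rbind, lapply(seq_along(bolus$time), function(b) {
      data.frame(var = names(state)[bolus$idx[[b]]],
                 time = bolus$time[b],
                 value = bolus$amount[[b]],
                 method = "add")
    }))
    keep <- ev$time >= config$start_time & ev$time <= config$stop_time
    ev <- ev[keep, , drop = FALSE]
    if (nrow(ev)) events <- ev[order(ev$time), , drop = FALSE]
  }
  times <- sort(unique(c(t_out, if (!is.null(events)) events$time)))

  func <- function(t, y, parms) {
    d <- if (has_inf) rhs(t, y, input_at(t)) else rhs(t, y, NULL)
    list(d)
  }
  sol <- deSolve::ode(
    y = state, times = times, func = func, parms = NULL,
    method = "lsoda", rtol = config$tolerance,
    atol = config$tolerance * 1e-3,
    hmax = config$dt_max, hmin = config$dt_min * 1e-3,
    events = if (!is.null(events)) list(data = events) else NULL
  )
  if (attr(sol, "istate")[1] < 0)
    stop("Adaptive solver failed to meet the tolerance within the step bounds.",
         call. = FALSE)
  sol <- sol[sol[, 1] %in% t_out | vapply(sol[, 1], function(tt)
    any(abs(tt - t_out) < 1e-9), logical(1)), , drop = FALSE]
  sol <- sol[!duplicated(sol[, 1]), , drop = FALSE]
  list(times = sol[, 1], states = sol[, -1, drop = FALSE])
}
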