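#' Blood-pressure trial design
#'
#' Design of the dose-success simulation: `n_subjects` patients receive
#' `n_doses` daily oral doses of `dose` mg; a patient is a success if the
#' drug-induced blood-pressure change is below `pd_threshold` (mmHg) at
#' `eval_time` hours after the start of treatment, read pre-dose (trough)
#' when `eval_time` coincides with a dose time.
#'
#' @param dose Dose amount (mg).
#' @param n_doses Number of daily doses (interval 24 h).
#' @param n_subjects Number of simulated patients.
#' @param eval_time Evaluation time (h after first dose; default 72).
#' @param pd_threshold Success threshold on the blood-pressure change (mmHg;
#'   default -20, i.e. a reduction of at least 20 mmHg).
#' @param residual_sd Lognormal residual standard deviation applied to the
#'   concentration at evaluation.
#' @param start_time,stop_time,dt Integration window and step (h).
#' @return An object of class `bp_trial_design`.
#' @export
bp_trial_design <- function(dose = 130, n_doses = 4, n_subjects = 100,
                            eval_time = 72, pd_threshold = -20,
                            residual_sd = 0.01,
                            start_time = -1, stop_time = 144, dt = 0.1) {
  stopifnot(n_subjects >= 1, dose >= 0, n_doses >= 0)
  if (eval_time <= start_time || eval_time > stop_time)
    stop("`eval_time` must lie within the simulation window.", call. = FALSE)
  structure(list(dose = dose, n_doses = n_doses, n_subjects = n_subjects,
                 eval_time = eval_time, pd_threshold = pd_threshold,
                 residual_sd = residual_sd, start_time = start_time,
                 stop_time = stop_time, dt = dt),
            class = "bp_trial_design")
}

#' Blood-pressure model parameters
#'
#' Population PK/PD parameters of the blood-pressure model: oral
#' one-compartment PK (`ka`, `ke` 1/h, volume `V1`), an inhibitory Emax
#' effect on blood pressure (`E0` mmHg baseline, `Emax` mmHg, `EC50` ng/mL)
#' and lognormal interindividual standard deviations on `ka`, `ke`, `V1` and
#' the baseline.
#'
#' @param ka,ke Absorption/elimination rate constants (1/h).
#' @param V1 Central volume.
#' @param CL Nominal clearance (carried for completeness; elimination is via
#'   `ke`).
#' @param E0 Baseline blood pressure (mmHg).
#' @param Emax Maximal drug effect (mmHg; negative = reduction).
#' @param EC50 Concentration at half-maximal effect (ng/mL).
#' @param eta_ka,eta_ke,eta_V1,eta_BL Lognormal standard deviations of the
#'   interindividual random effects.
#' @return A named list of class `bp_model_params`.
#' @export
bp_model_params <- function(ka = 0.1, ke = 0.1, V1 = 1, CL = 1,
                            E0 = 125, Emax = -40, EC50 = 20,
                            eta_ka = 1.0, eta_ke = 0.01, eta_V1 = 0.2,
                            eta_BL = 0.1) {
  structure(list(ka = ka, ke = ke, V1 = V1, CL = CL, E0 = E0, Emax = Emax,
                 EC50 = EC50, eta_ka = eta_ka, eta_ke = eta_ke,
                 eta_V1 = eta_V1, eta_BL = eta_BL),
            class = "bp_model_params")
}

#' Simulate one blood-pressure success trial
#'
#' Simulates `n_subjects` patients with individual lognormal PK parameters
#' and baselines, daily oral dosing, and an inhibitory Emax effect of the
#' (residual-error-perturbed) concentration on blood pressure. Success per
#' patient is a blood-pressure change below the threshold at the evaluation
#' time, read pre-dose; the trial outcome is the percentage of successes.
#'
#' @param design A [bp_trial_design()].
#' @param params A [bp_model_params()].
#' @param seed Optional integer master seed.
#' @param mc_switch 1 for interindividual variability, 0 for identical
#'   population-typical subjects.
#' @param keep_trajectory Keep the full concentration trajectories (wide
#'   tibble) on the result; off by default.
#' @return An object of class `bp_trial`: list with `subjects` (per-subject
#'   tibble), `success_percent`, `design`, `params`, `seed`, and optionally
#'   `trajectory`.
#' @examples
#' res <- simulate_bp_trial(bp_trial_design(dose = 150, n_subjects = 20),
#'                          seed = 1)
#' glance(res)
#' @export
simulate_bp_trial <- function(design = bp_trial_design(),
                              params = bp_model_params(), seed = NULL,
                              mc_switch = 1, keep_trajectory = FALSE) {
  stopifnot(inherits(design, "bp_trial_design"))
  n <- design$n_subjects
  p <- params

  draws <- with_master_seed(seed, {
    subj <- sample_subject_params(
      c(ka = p$ka, ke = p$ke, V1 = p$V1, BL = p$E0), n = n,
      sds = c(ka = p$eta_ka, ke = p$eta_ke, V1 = p$eta_V1, BL = p$eta_BL),
      mc_switch = mc_switch)
    list(subj = subj, resid = rnorm(n, 0, design$residual_sd))
  })
  subj <- draws$subj

  cfg <- solver_config("rk4", start_time = design$start_time,
                       stop_time = design$stop_time, dt = design$dt)
  init <- c(setNames(rep(0, n), paste0("depot", seq_len(n))),
            setNames(rep(0, n), paste0("central", seq_len(n))))
  ka_i <- subj$ka; ke_i <- subj$ke
  rhs <- function(t, y, input = NULL) {
    a <- ka_i * y[1:n]
    c(-a, a - ke_i * y[(n + 1):(2 * n)])
  }
  regimen <- dose_regimen(rep(design$dose, n), first_time = 0, interval = 24,
                          n_doses = design$n_doses, target = seq_len(n))
  traj <- pk_integrate(rhs, regimen, init = init, config = cfg)

  row <- which(abs(traj$time - design$eval_time) < design$dt)[1]
  if (is.na(row))
    stop("No output time within `dt` of `eval_time`.", call. = FALSE)
  central <- as.numeric(traj[row, paste0("central", seq_len(n))])
  conc <- central / subj$V1 * exp(draws$resid * mc_switch)
  pd_change <- emax_effect(conc, E0 = 0, Emax = p$Emax, EC50 = p$EC50)
  success <- pd_change < design$pd_threshold

  subjects <- dplyr::mutate(subj,
    conc_eval = conc, pd_change = pd_change, pd = subj$BL + pd_change,
    success = success)
  res <- structure(
    list(subjects = subjects,
         success_percent = 100 * mean(success),
         eval_time = design$eval_time, design = design, params = p,
         seed = seed),
    class = "bp_trial")
  if (keep_trajectory) res$trajectory <- traj
  res
}

#' @export
print.bp_trial <- function(x, ...) {
  cat(sprintf(
    "<bp_trial> dose %g mg, %d subjects: %.1f%% success at %g h\n",
    x$design$dose, x$design$n_subjects, x$success_percent, x$eval_time))
  invisible(x)
}

#' @rdname simulate_bp_trial
#' @param x A `bp_trial` object.
#' @param ... Unused.
#' @method tidy bp_trial
#' @export
tidy.bp_trial <- function(x, ...) x$subjects

#' @rdname simulate_bp_trial
#' @method glance bp_trial
#' @export
glance.bp_trial <- function(x, ...) {
  tibble(n_subjects = x$design$n_subjects, dose = x$design$dose,
         eval_time = x$eval_time, success_percent = x$success_percent)
}

#' Success percentage at an evaluation time from long trajectories
#'
#' Extracts, per subject, the value at the first time within `dt` of
#' `eval_time` and reports the percentage of subjects whose value lies below
#' `threshold`. The result does not depend on subject order.
#'
#' @param data Long tibble with columns `subject`, `time`, `value`
#'   (column names configurable).
#' @param eval_time Evaluation time.
#' @param dt Matching half-window: the first time with
#'   `|time - eval_time| < dt` is used.
#' @param threshold Success threshold (success = value strictly below it).
#' @param time,value,subject Column names.
#' @return Percentage of successful subjects in `[0, 100]`.
#' @export
success_percent_at <- function(data, eval_time, dt, threshold,
                               time = "time", value = "value",
                               subject = "subject") {
  d <- dplyr::filter(data, abs(.data[[time]] - eval_time) < dt)
  if (!nrow(d))
    stop("No time point within `dt` of `eval_time`.", call. = FALSE)
  d <- dplyr::slice_min(dplyr::group_by(d, .data[[subject]]),
                        .data[[time]], n = 1, with_ties = FALSE)
  100 * mean(d[[value]] < threshold)
}

#' Dose-response table of trial success percentages
#'
#' Runs one independent blood-pressure trial per (replicate, dose) cell and
#' tabulates the success percentage, the programmatic equivalent of
#' overlaying repeated dose-response simulations.
#'
#' @param doses Dose grid (mg), e.g. `seq(0, 200, by = 10)`.
#' @param n_replicates Number of replicate studies per dose.
#' @param design,params Passed to [simulate_bp_trial()]; the design's `dose`
#'   field is overridden by the grid.
#' @param seed Optional master seed; each (replicate, dose) cell gets an
#'   independent derived sub-seed.
#' @return A tibble `(replicate, dose, success_percent)` of class
#'   `bp_dose_response`.
#' @export
bp_dose_response <- function(doses = seq(0, 200, by = 10), n_replicates = 10,
                             design = bp_trial_design(),
                             params = bp_model_params(), seed = NULL) {
  stopifnot(length(doses) >= 1, n_replicates >= 1)
  cells <- tidyr::expand_grid(replicate = seq_len(n_replicates), dose = doses)
  seeds <- derive_seeds(seed, nrow(cells))
  out <- purrr::pmap_dfr(
    list(cells$replicate, cells$dose, seeds),
    function(rep_i, dose_i, seed_i) {
      des <- design; des$dose <- dose_i
      r <- simulate_bp_trial(des, params, seed = seed_i)
      tibble(replicate = rep_i, dose = dose_i,
             success_percent = r$success_percent)
    })
  class(out) <- c("bp_dose_response", class(out))
  out
}
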