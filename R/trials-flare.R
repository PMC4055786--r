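#' Weight-based canakinumab dose rule
#'
#' Flat 150 mg for patients of 40 kg or more; 2 mg/kg below 40 kg
#' (paediatric rule).
#'
#' @param weight Body weight (kg, > 0, vectorized).
#' @return Dose in mg.
#' @examples
#' canakinumab_dose(c(30, 40, 70))
#' @export
canakinumab_dose <- function(weight) {
  stopifnot(all(weight > 0))
  ifelse(weight < 40, 2 * weight, 150)
}

#' Flare / randomized-withdrawal trial design
#'
#' Two active arms of `n_per_arm` patients each. Both arms receive a first
#' weight-based dose at time 0; at `start_p2` (randomized-withdrawal start)
#' arm 1 continues treatment with `n_doses_p2[1]` doses every `tau` days
#' while arm 2 receives `n_doses_p2[2]` (default 0: withdrawal to placebo).
#' Visits occur every `visit_freq` days from `start_time`; at each visit
#' strictly after `start_p2` a flare occurs with the concentration-dependent
#' probability, and the first flare transfers the patient out of the
#' randomized phase (absorbing).
#'
#' @param n_per_arm Patients per arm (default 18).
#' @param tau Inter-dose interval in the maintenance phase (days).
#' @param start_p2 Start of the randomized-withdrawal phase (days).
#' @param start_time,stop_time Simulation window (days; baseline runs from
#'   -28 d).
#' @param visit_freq Visit interval (days).
#' @param n_doses_p2 Length-2 count of maintenance doses per arm.
#' @param dt Fixed integration step (days).
#' @param weight_lo,weight_hi Uniform body-weight bounds (kg).
#' @return An object of class `flare_trial_design`.
#' @export
flare_trial_design <- function(n_per_arm = 18, tau = 56, start_p2 = 56,
                               start_time = -28, stop_time = 224,
                               visit_freq = 7, n_doses_p2 = c(3, 0),
                               dt = 1, weight_lo = 10, weight_hi = 80) {
  stopifnot(n_per_arm >= 1, tau > 0, visit_freq > 0, length(n_doses_p2) == 2)
  if (start_p2 < 0)
    stop("`start_p2` must not precede the first dose at time 0.", call. = FALSE)
  structure(list(n_per_arm = n_per_arm, tau = tau, start_p2 = start_p2,
                 start_time = start_time, stop_time = stop_time,
                 visit_freq = visit_freq, n_doses_p2 = n_doses_p2, dt = dt,
                 weight_lo = weight_lo, weight_hi = weight_hi),
            class = "flare_trial_design")
}

#' Flare model parameters
#'
#' Population PK and flare-probability parameters for a subcutaneous
#' monoclonal antibody (time in days): two-compartment clearance-form PK
#' with allometric body-weight scaling (`CL`, `V2`, `V3` proportional to
#' `WT/70`; `PS` to `(WT/70)^0.667`), correlated lognormal random effects on
#' (CL, V2) and (PS, V3) given by covariance matrices, independent lognormal
#' effects on `ka`, bioavailability `F` and the flare IC50 `KIEF`, and a
#' Hill coefficient for the flare probability.
#'
#' @param CL_pop Clearance for a 70 kg patient (L/d).
#' @param V2_pop,V3_pop Central/peripheral volumes (L).
#' @param PS_pop Intercompartmental clearance (L/d).
#' @param cov_cl_v2 2x2 covariance of the (CL, V2) log effects.
#' @param cov_ps_v3 2x2 covariance of the (PS, V3) log effects.
#' @param ka_pop,ka_sd Absorption rate constant (1/d) and its lognormal sd.
#' @param F_pop,F_sd Bioavailability and its lognormal sd.
#' @param KIEF_pop,KIEF_sd Concentration for a 50:50 flare probability
#'   (ug/mL) and its lognormal sd.
#' @param HILL Hill coefficient of the flare-probability curve.
#' @param allo_cl,allo_v,allo_ps Allometric exponents.
#' @return A list of class `flare_model_params`.
#' @export
flare_model_params <- function(CL_pop = 0.181, V2_pop = 5.07, V3_pop = 1.74,
                               PS_pop = 0.103,
                               cov_cl_v2 = matrix(c(0.0442, 0.0556,
                                                    0.0556, 0.0869), 2, 2),
                               cov_ps_v3 = matrix(c(0.366, 0.0153,
                                                    0.0153, 0.000651), 2, 2),
                               ka_pop = 0.438, ka_sd = sqrt(0.185),
                               F_pop = 0.663, F_sd = sqrt(0.0881),
                               KIEF_pop = 1.13, KIEF_sd = sqrt(0.0158),
                               HILL = 4.22,
                               allo_cl = 1, allo_v = 1, allo_ps = 0.667) {
  structure(list(CL_pop = CL_pop, V2_pop = V2_pop, V3_pop = V3_pop,
                 PS_pop = PS_pop, cov_cl_v2 = cov_cl_v2,
                 cov_ps_v3 = cov_ps_v3, ka_pop = ka_pop, ka_sd = ka_sd,
                 F_pop = F_pop, F_sd = F_sd, KIEF_pop = KIEF_pop,
                 KIEF_sd = KIEF_sd, HILL = HILL, allo_cl = allo_cl,
                 allo_v = allo_v, allo_ps = allo_ps),
            class = "flare_model_params")
}

# Draw the per-subject frozen parameter table for one flare trial.
.flare_population <- function(design, params, mc_switch) {
  n_arm <- design$n_per_arm
  n <- 2L * n_arm
  p <- params
  wt <- sample_bodyweight(n, "uniform", lo = design$weight_lo,
                          hi = design$weight_hi, mc_switch = mc_switch)
  eta1 <- as.matrix(sample_mvn_effects(n, p$cov_cl_v2))
  eta2 <- as.matrix(sample_mvn_effects(n, p$cov_ps_v3))
  eta_ka <- rnorm(n, 0, p$ka_sd)
  eta_F <- rnorm(n, 0, p$F_sd)
  eta_KIEF <- rnorm(n, 0, p$KIEF_sd)
  mc <- mc_switch
  tibble(
    subject = seq_len(n),
    arm = rep(1:2, each = n_arm),
    WT = wt,
    dose = canakinumab_dose(wt),
    CL = p$CL_pop * (wt / 70)^p$allo_cl * exp(eta1[, 1] * mc),
    V2 = p$V2_pop * (wt / 70)^p$allo_v * exp(eta1[, 2] * mc),
    PS = p$PS_pop * (wt / 70)^p$allo_ps * exp(eta2[, 1] * mc),
    V3 = p$V3_pop * (wt / 70)^p$allo_v * exp(eta2[, 2] * mc),
    ka = p$ka_pop * exp(eta_ka * mc),
    F = p$F_pop * exp(eta_F * mc),
    KIEF = p$KIEF_pop * exp(eta_KIEF * mc)
  )
}

#' Simulate one flare / randomized-withdrawal trial
#'
#' Per subject: a weight-dependent subcutaneous dose with two-compartment
#' clearance-form PK and allometric scaling; a flare probability declining
#' in concentration via a Hill function; weekly visits at which (strictly
#' after the withdrawal time) a flare event is drawn from a Bernoulli with
#' that probability. The first flare transfers the subject out (absorbing);
#' the arm-level readout is the flare-free fraction over time.
#'
#' Visits that coincide with a dose time read the concentration pre-dose.
#'
#' @param design A [flare_trial_design()].
#' @param params A [flare_model_params()].
#' @param seed Optional integer master seed.
#' @param mc_switch 1 for interindividual variability, 0 for
#'   population-typical subjects.
#' @return An object of class `flare_trial`: `subjects` (frozen parameter
#'   table), `events` (per subject x visit: concentration, flare
#'   probability, flare draw, absorbing transfer indicator), `curves`
#'   (per arm x visit flare-free fraction), `design`, `params`, `seed`.
#' @examples
#' res <- simulate_flare_trial(flare_trial_design(n_per_arm = 4), seed = 1)
#' head(res$curves)
#' @export
simulate_flare_trial <- function(design = flare_trial_design(),
                                 params = flare_model_params(), seed = NULL,
                                 mc_switch = 1) {
  stopifnot(inherits(design, "flare_trial_design"))
  n_arm <- design$n_per_arm
  n <- 2L * n_arm

  visit_times <- seq(design$start_time, design$stop_time,
                     by = design$visit_freq)
  n_vis <- length(visit_times)

  draws <- with_master_seed(seed, {
    subj <- .flare_population(design, params, mc_switch)
    u <- matrix(runif(n * n_vis), nrow = n, byrow = TRUE)  # subject-major
    list(subj = subj, u = u)
  })
  subj <- draws$subj

  cfg <- solver_config("rk4", start_time = design$start_time,
                       stop_time = design$stop_time, dt = design$dt)
  init <- c(setNames(rep(0, n), paste0("S", seq_len(n))),
            setNames(rep(0, n), paste0("D", seq_len(n))),
            setNames(rep(0, n), paste0("P", seq_len(n))))
  ka <- subj$ka; CL <- subj$CL; V2 <- subj$V2; V3 <- subj$V3; PS <- subj$PS
  rhs <- function(t, y, input = NULL) {
    d <- two_cpt_clearance_rhs(y[1:n], y[(n + 1):(2 * n)],
                               y[(2 * n + 1):(3 * n)],
                               ka = ka, CL = CL, V2 = V2, V3 = V3, PS = PS)
    c(d$dS, d$dD, d$dT)
  }

  amt <- subj$dose * subj$F
  regimens <- list(
    dose_regimen(amt, first_time = 0, interval = design$tau, n_doses = 1,
                 target = seq_len(n)))
  for (a in 1:2) {
    if (design$n_doses_p2[a] > 0) {
      idx <- which(subj$arm == a)
      regimens <- c(regimens, list(
        dose_regimen(amt[idx], first_time = design$start_p2,
                     interval = design$tau, n_doses = design$n_doses_p2[a],
                     target = idx)))
    }
  }
  traj <- pk_integrate(rhs, regimens, init = init, config = cfg)

  vrows <- vapply(visit_times, function(tt)
    which(abs(traj$time - tt) < design$dt / 2)[1], integer(1))
  conc <- as.matrix(traj[vrows, paste0("D", seq_len(n))]) /
    matrix(subj$V2, nrow = n_vis, ncol = n, byrow = TRUE)  # visits x subjects

  pflare <- t(apply(conc, 1, function(cc)
    flare_probability(pmax(cc, 0), subj$KIEF, params$HILL)))
  counted <- visit_times > design$start_p2
  flare <- t(draws$u) < pflare            # visits x subjects
  flare[!counted, ] <- FALSE
  transferred <- apply(flare, 2, cumsum) > 0  # visits x subjects, absorbing

  events <- tibble(
    subject = rep(subj$subject, each = n_vis),
    arm = rep(subj$arm, each = n_vis),
    visit_time = rep(visit_times, n),
    counted = rep(counted, n),
    conc = as.vector(conc),
    pflare = as.vector(pflare),
    flare = as.vector(flare),
    part3 = as.vector(transferred) * 1L
  )

  curves <- dplyr::bind_rows(lapply(1:2, function(a) {
    cols <- which(subj$arm == a)
    tibble(arm = a, time = visit_times,
           flare_free = 1 - rowSums(transferred[, cols, drop = FALSE]) / n_arm)
  }))

  structure(list(subjects = subj, events = events, curves = curves,
                 design = design, params = params, seed = seed),
            class = "flare_trial")
}

#' @export
print.flare_trial <- function(x, ...) {
  fin <- dplyr::filter(x$curves, .data$time == max(.data$time))
  cat(sprintf(
    "<flare_trial> %d patients/arm; final flare-free fraction: arm 1 %.2f, arm 2 %.2f\n",
    x$design$n_per_arm, fin$flare_free[fin$arm == 1],
    fin$flare_free[fin$arm == 2]))
  invisible(x)
}

#' @rdname simulate_flare_trial
#' @param x A `flare_trial` object.
#' @param ... Unused.
#' @method tidy flare_trial
#' @export
tidy.flare_trial <- function(x, ...) x$curves

#' @rdname simulate_flare_trial
#' @method glance flare_trial
#' @export
glance.flare_trial <- function(x, ...) {
  fin <- dplyr::filter(x$curves, .data$time == max(.data$time))
  tibble(n_per_arm = x$design$n_per_arm,
         flare_free_arm1 = fin$flare_free[fin$arm == 1],
         flare_free_arm2 = fin$flare_free[fin$arm == 2])
}

#' Replicate trial simulations
#'
#' Runs `n_replicates` independent flare trials under sub-seeds derived from
#' the master seed, quantifying between-trial variability.
#'
#' @param n_replicates Number of replicate trials (>= 1).
#' @param design,params,mc_switch Passed to [simulate_flare_trial()].
#' @param seed Optional master seed.
#' @return A list of `flare_trial` objects.
#' @seealso [flare_free_curves()] to bind the replicate curves into one tidy
#'   table.
#' @export
replicate_trials <- function(n_replicates, design = flare_trial_design(),
                             params = flare_model_params(), seed = NULL,
                             mc_switch = 1) {
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(k)
    simulate_flare_trial(design, params, seed = seeds[k],
                         mc_switch = mc_switch))
}

#' Bind replicate flare-free curves into a tidy table
#'
#' @param results A `flare_trial` or list of them (e.g. from
#'   [replicate_trials()]).
#' @return A tibble `(replicate, arm, time, flare_free)`.
#' @export
flare_free_curves <- function(results) {
  if (inherits(results, "flare_trial")) results <- list(results)
  purrr::imap_dfr(results, function(r, k)
    dplyr::mutate(r$curves, replicate = k, .before = 1))
}
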