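#' One-compartment oral PK derivatives
#'
#' First-order absorption from a depot into a central compartment with
#' first-order elimination:
#' `d(depot) = input - ka * depot`, `d(central) = ka * depot - ke * central`.
#'
#' @param state Named numeric with elements `depot` and `central`.
#' @param ka,ke Absorption and elimination rate constants (1/time).
#' @param input_rate Exogenous zero-order input into the depot (mass/time).
#' @return Named derivative vector.
#' @examples
#' one_compartment_oral_rhs(c(depot = 100, central = 0), ka = 0.1, ke = 0.2)
#' @export
one_compartment_oral_rhs <- function(state, ka, ke, input_rate = 0) {
  c(depot = input_rate - ka * state[["depot"]],
    central = ka * state[["depot"]] - ke * state[["central"]])
}

#' Two/three-compartment PK derivatives (rate-constant form)
#'
#' Depot (`comp1`), central (`comp2`) and peripheral (`comp3`) compartments
#' linked by first-order rate constants:
#' `d(comp2) = ka*comp1 - k23*comp2 + k32*comp3 - ke*comp2`,
#' `d(comp3) = k23*comp2 - k32*comp3`.
#'
#' @param state Named numeric with `comp1`, `comp2`, `comp3`.
#' @param ka,ke,k23,k32 First-order rate constants (1/time).
#' @param input_rate Zero-order input into `comp1`.
#' @return Named derivative vector.
#' @examples
#' multi_compartment_rhs(c(comp1 = 0, comp2 = 2, comp3 = 3),
#'                       ka = 0, ke = 0, k23 = 0.3, k32 = 0.2)
#' @export
multi_compartment_rhs <- function(state, ka, ke, k23, k32, input_rate = 0) {
  c(comp1 = input_rate - ka * state[["comp1"]],
    comp2 = ka * state[["comp1"]] - k23 * state[["comp2"]] +
      k32 * state[["comp3"]] - ke * state[["comp2"]],
    comp3 = k23 * state[["comp2"]] - k32 * state[["comp3"]])
}

#' Two-compartment subcutaneous PK derivatives (clearance form)
#'
#' The clearance parameterization used for monoclonal-antibody PK: depot `S`
#' (injection site), central `D` and peripheral `T_periph` amounts with
#' clearance `CL`, central volume `V2`, intercompartmental clearance `PS` and
#' peripheral volume `V3`:
#' `d(D) = ka*S - D*CL/V2 + PS*(T/V3 - D/V2)`.
#'
#' All arguments are vectorized, so a whole population can be advanced at
#' once with per-subject parameters.
#'
#' @param S,D,T_periph Amounts in depot, central and peripheral compartments.
#' @param ka Absorption rate constant (1/time).
#' @param CL Clearance (volume/time).
#' @param V2,V3 Central and peripheral volumes.
#' @param PS Intercompartmental clearance (volume/time).
#' @param input_rate Zero-order input into `S`.
#' @return List of derivative vectors `dS`, `dD`, `dT`.
#' @export
two_cpt_clearance_rhs <- function(S, D, T_periph, ka, CL, V2, V3, PS,
                                  input_rate = 0) {
  list(dS = input_rate - ka * S,
       dD = ka * S - D * CL / V2 + PS * (T_periph / V3 - D / V2),
       dT = PS * (D / V2 - T_periph / V3))
}

#' Transit-compartment chain derivatives
#'
#' A chain of `n` transit compartments feeding a plasma compartment: the
#' first transit receives the dosing input, each subsequent one receives
#' `ktr * previous - ktr * self`, and plasma receives `ktr * last` less
#' first-order elimination `kout`.
#'
#' @param transit Numeric vector of transit-compartment amounts (length >= 1).
#' @param Aplasma Plasma amount.
#' @param ktr Inter-transit transfer rate constant (1/time).
#' @param kout Elimination rate constant from plasma (1/time).
#' @param input_rate Zero-order input into the first transit compartment.
#' @return List with `d_transit` (vector) and `d_Aplasma`.
#' @examples
#' transit_chain_rhs(c(10, 0), Aplasma = 0, ktr = 0.25, kout = 0.25)
#' @export
transit_chain_rhs <- function(transit, Aplasma, ktr, kout, input_rate = 0) {
  n <- length(transit)
  if (n < 1) stop("At least one transit compartment is required.", call. = FALSE)
  d <- numeric(n)
  d[1] <- input_rate - ktr * transit[1]
  if (n > 1) d[2:n] <- ktr * transit[1:(n - 1)] - ktr * transit[2:n]
  list(d_transit = d, d_Aplasma = ktr * transit[n] - kout * Aplasma)
}

#' Target-mediated drug disposition parameters
#'
#' Parameter set for the full-binding TMDD system. The dissociation rate is
#' reparameterized as `koff = Kd * kon`. Units follow a theoretical
#' monoclonal antibody with time in days: `kon` in 1/(nM d), `Kd` in nM,
#' elimination rates in 1/d, `RateT` in nmol/d, `V` in L. Amounts are carried
#' in nmol; `drug_conc_factor` and `target_conc_factor` convert nmol/L to the
#' reporting concentration scales for drug and target (the absolute unit
#' labels are conventional and should be treated as nominal).
#'
#' @param kon Second-order association rate constant.
#' @param Kd Equilibrium dissociation constant; `koff = Kd * kon`.
#' @param keD,keT,keTD Elimination rate constants of free drug, free target
#'   and complex (1/time).
#' @param RateT Zero-order target production rate (amount/time).
#' @param V Volume of the binding compartment.
#' @param ka Absorption rate constant from the injection site.
#' @param drug_conc_factor Mass-concentration factor for the drug (default
#'   0.15 per nmol/L).
#' @param target_conc_factor Mass-concentration factor for the target
#'   (default 190 per nmol/L).
#' @return A list of class `tmdd_params` (with `koff` filled in).
#' @examples
#' p <- tmdd_params()
#' p$koff  # 1.5 = Kd * kon
#' @export
tmdd_params <- function(kon = 1, Kd = 1.5, keD = 0.03, keT = 0.5, keTD = 0.1,
                        RateT = 50, V = 7, ka = 1,
                        drug_conc_factor = 0.15, target_conc_factor = 190) {
  stopifnot(kon >= 0, Kd >= 0, keD >= 0, keT >= 0, keTD >= 0,
            RateT >= 0, V > 0, ka >= 0)
  if (keT <= 0 && RateT > 0)
    stop("`keT` must be > 0 when `RateT` > 0 (initial target = RateT/keT).",
         call. = FALSE)
  structure(list(kon = kon, Kd = Kd, koff = Kd * kon, keD = keD, keT = keT,
                 keTD = keTD, RateT = RateT, V = V, ka = ka,
                 drug_conc_factor = drug_conc_factor,
                 target_conc_factor = target_conc_factor),
            class = "tmdd_params")
}

#' Full-binding TMDD derivatives
#'
#' Drug `D` binds reversibly to a continuously produced target `T` forming a
#' complex `TD`; drug, target and complex are eliminated at distinct
#' first-order rates. Amounts are molar masses; `kon` is second order with
#' respect to concentration, hence the `kon/V` terms:
#' \deqn{S' = input - ka S,\quad
#'   D' = -\frac{k_{on}}{V} D T + k_{off} TD - k_{eD} D + ka S}
#' \deqn{T' = -\frac{k_{on}}{V} D T + k_{off} TD - k_{eT} T + Rate_T,\quad
#'   TD' = +\frac{k_{on}}{V} D T - k_{off} TD - k_{eTD} TD}
#'
#' @param state Named numeric with `S`, `D`, `T`, `TD` (amounts >= 0).
#' @param params A [tmdd_params()] object.
#' @param input_rate Zero-order input into `S`.
#' @return Named derivative vector.
#' @examples
#' p <- tmdd_params()
#' tmdd_rhs(c(S = 0, D = 0, T = 100, TD = 0), p)  # steady state: all zero
#' @export
tmdd_rhs <- function(state, params, input_rate = 0) {
  p <- params
  S <- state[["S"]]; D <- state[["D"]]; T <- state[["T"]]; TD <- state[["TD"]]
  bind <- p$kon / p$V * D * T
  c(S = input_rate - p$ka * S,
    D = -bind + p$koff * TD - p$keD * D + p$ka * S,
    T = -bind + p$koff * TD - p$keT * T + p$RateT,
    TD = +bind - p$koff * TD - p$keTD * TD)
}

#' TMDD derived concentrations
#'
#' Free and total drug and target concentrations:
#' `CFD = f_D * D / V`, `CTD = f_D * (D + TD) / V`,
#' `CFT = f_T * T / V`, `CTT = f_T * (T + TD) / V`,
#' with `f_D` and `f_T` the drug and target concentration factors.
#'
#' @param D,T,TD Amounts of free drug, free target and complex (vectorized).
#' @param params A [tmdd_params()] object.
#' @return A tibble with columns `CFD`, `CTD`, `CFT`, `CTT`.
#' @examples
#' tmdd_concentrations(D = 0, T = 100, TD = 0, params = tmdd_params())
#' @export
tmdd_concentrations <- function(D, T, TD, params) {
  p <- params
  tibble(CFD = p$drug_conc_factor * D / p$V,
         CTD = p$drug_conc_factor * (D + TD) / p$V,
         CFT = p$target_conc_factor * T / p$V,
         CTT = p$target_conc_factor * (T + TD) / p$V)
}

#' Circadian multiplier
#'
#' A 24-hour cosine modulation of a PD baseline:
#' `1 + amp * cos(2 * pi * (t - tshift) / 24)`, maximal at `t = tshift`.
#'
#' @param t Time of day (h, vectorized).
#' @param amp Amplitude as a fraction of baseline (>= 0).
#' @param tshift Time of the maximum (h).
#' @return Multiplicative factor.
#' @examples
#' circadian_factor(c(10, 22), amp = 0.1, tshift = 10)
#' @export
circadian_factor <- function(t, amp, tshift) {
  stopifnot(amp >= 0)
  1 + amp * cos(2 * pi * (t - tshift) / 24)
}

#' Placebo-response multiplier
#'
#' A placebo effect that gradually appears and only partially disappears:
#' `1 + maxup * (1 - exp(-rateup * t)) - maxdown * (1 - exp(-ratedown * t))`,
#' applied multiplicatively to the baseline response.
#'
#' @param t Time since start of treatment (>= 0, vectorized).
#' @param maxdown,maxup Maximal fractional decrease/increase from baseline.
#' @param ratedown,rateup Onset rate constants (1/time).
#' @return Multiplicative factor (1 at `t = 0`).
#' @examples
#' placebo_factor(1)
#' @export
placebo_factor <- function(t, maxdown = 0.1, maxup = 0.1,
                           ratedown = 1, rateup = 0.3) {
  1 + maxup * (1 - exp(-rateup * t)) - maxdown * (1 - exp(-ratedown * t))
}

#' Emax concentration-effect model
#'
#' Saturating effect `E0 + Emax * C / (C + EC50)`; the effect is half-maximal
#' at `C = EC50`.
#'
#' @param conc Drug concentration (>= 0, vectorized).
#' @param E0 Baseline effect.
#' @param Emax Maximal effect (may be negative for inhibitory responses).
#' @param EC50 Concentration producing half the maximal effect (> 0).
#' @return Effect.
#' @examples
#' emax_effect(40, E0 = 25, Emax = 50, EC50 = 40)  # E0 + Emax/2
#' @export
emax_effect <- function(conc, E0, Emax, EC50) {
  stopifnot(EC50 > 0, all(conc >= 0))
  E0 + Emax * conc / (conc + EC50)
}

#' Logistic response
#'
#' `exp(a + b*x) / (1 + exp(a + b*x))`, evaluated in a numerically stable
#' form for large `|a + b*x|`. Typically a probability estimate.
#'
#' @param x Predictor (vectorized).
#' @param a Intercept.
#' @param b Slope.
#' @return Probability in `[0, 1]`.
#' @examples
#' logistic_response(0)        # 0.5
#' logistic_response(1000, b = 1)  # 1, no overflow
#' @export
logistic_response <- function(x, a = 0, b = 1) {
  stats::plogis(a + b * x)
}

#' Indirect-response derivative
#'
#' Turnover PD compartment driven by concentration:
#' `d(PD) = PD_in * C - PD_out * PD`, with steady state
#' `PD = PD_in * C / PD_out` under constant concentration.
#'
#' @param PD Current response.
#' @param conc Driving concentration.
#' @param PD_in Production rate constant (response/(conc * time)).
#' @param PD_out Loss rate constant (1/time).
#' @return Derivative of `PD`.
#' @examples
#' indirect_effect_rhs(PD = 40, conc = 40, PD_in = 0.1, PD_out = 0.1)  # 0
#' @export
indirect_effect_rhs <- function(PD, conc, PD_in, PD_out) {
  PD_in * conc - PD_out * PD
}

#' Probability of a disease flare
#'
#' A Hill function declining in drug concentration:
#' `Pflare = 1 - C^H / (K^H + C^H) = 1 / (1 + (C/K)^H)`, equal to 0.5 at
#' `C = K` and 1 without drug.
#'
#' @param conc Drug concentration (>= 0, vectorized).
#' @param KIEF Concentration giving a 50:50 flare probability (> 0).
#' @param HILL Hill coefficient (> 0).
#' @return Probability in `[0, 1]`, strictly decreasing in `conc`.
#' @examples
#' flare_probability(c(0, 1.13, 100), KIEF = 1.13, HILL = 4.22)
#' @export
flare_probability <- function(conc, KIEF, HILL) {
  stopifnot(all(conc >= 0), all(KIEF > 0), HILL > 0)
  1 / (1 + (conc / KIEF)^HILL)
}

#' Closed-form PK reference solutions
#'
#' Analytic amounts used as independent oracles for the numerical solver:
#' a one-compartment intravenous bolus `dose * exp(-ke * t)` and the Bateman
#' function for first-order absorption and elimination
#' `dose * ka / (ka - ke) * (exp(-ke*t) - exp(-ka*t))`, with the degenerate
#' `ka = ke` limit `dose * ka * t * exp(-ka * t)` applied when
#' `|ka - ke| < 1e-10 * ka`.
#'
#' @param model_id `"one_cpt_bolus"` or `"one_cpt_oral_bateman"`.
#' @param params List with `dose`, `ke`, and `ka` (Bateman only).
#' @param t Time (vectorized, >= 0 for the dose to have been given).
#' @return Central-compartment amount at `t`.
#' @examples
#' pk_analytic("one_cpt_oral_bateman",
#'             list(dose = 100, ka = 0.1, ke = 0.2), t = 10)
#' @export
pk_analytic <- function(model_id, params, t) {
  dose <- params$dose
  switch(model_id,
    one_cpt_bolus = dose * exp(-params$ke * t),
    one_cpt_oral_bateman = {
      ka <- params$ka; ke <- params$ke
      if (abs(ka - ke) < 1e-10 * ka) {
        dose * ka * t * exp(-ka * t)
      } else {
        dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
      }
    },
    stop("Unknown reference model: ", model_id, call. = FALSE)
  )
}

#' Structural model builders
#'
#' Constructs a named structural model: its state vector, derivative
#' function, and default derived outputs, ready for [pk_integrate()]. The
#' identifier keys the model library so that scenario configurations can
#' switch structural models.
#'
#' Available identifiers:
#' \describe{
#'   \item{`one_cpt_bolus`}{central amount with first-order elimination
#'     (`ke`; optional `V1` for the `conc` output).}
#'   \item{`one_cpt_oral`}{depot + central (`ka`, `ke`, optional `V1`,
#'     optional `absmax` for capped absorption).}
#'   \item{`two_cpt_oral`}{depot + central + peripheral, rate-constant form
#'     (`ka`, `ke`, `k23`, `k32`).}
#'   \item{`transit`}{transit-compartment chain (`n_transit`, `ktr`, `kout`).}
#'   \item{`tmdd`}{full-binding TMDD (a [tmdd_params()] list); the free
#'     target starts at its turnover steady state `RateT/keT`.}
#'   \item{`one_cpt_oral_indirect`}{oral PK plus an indirect-response
#'     compartment (`PD_in`, `PD_out`, `V1`).}
#' }
#'
#' @param id Model identifier (see Details).
#' @param params Named list of parameter values; unspecified parameters take
#'   the library defaults.
#' @return An object of class `pk_model` with elements `id`, `params`,
#'   `init`, `rhs` (signature `function(t, state, input)`), `outputs` and
#'   `default_target` (the compartment doses go into).
#' @examples
#' mod <- pk_model("one_cpt_oral", list(ka = 0.1, ke = 0.2))
#' names(mod$init)
#' @export
pk_model <- function(id, params = list()) {
  build <- switch(id,
    one_cpt_bolus = .build_one_cpt_bolus,
    one_cpt_oral = .build_one_cpt_oral,
    two_cpt_oral = .build_two_cpt_oral,
    transit = .build_transit,
    tmdd = .build_tmdd,
    one_cpt_oral_indirect = .build_indirect,
    stop("Unknown model id: ", id, call. = FALSE)
  )
  mod <- build(params)
  mod$id <- id
  structure(mod, class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("<pk_model>", x$id, "\n  states: ", paste(names(x$init), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.merge_params <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("Unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  modifyList(defaults, params)
}

.build_one_cpt_bolus <- function(params) {
  p <- .merge_params(list(ke = 0.2, V1 = 1), params)
  list(params = p,
       init = c(central = 0),
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         c(central = inp - p$ke * state[[1]])
       },
       outputs = list(conc = function(t, state) state[["central"]] / p$V1),
       default_target = "central")
}

.build_one_cpt_oral <- function(params) {
  p <- .merge_params(list(ka = 0.1, ke = 0.2, V1 = 1, absmax = Inf), params)
  list(params = p,
       init = c(depot = 0, central = 0),
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         abs_rate <- saturable_absorption_rate(max(state[[1]], 0), p$ka, p$absmax)
         c(depot = inp - abs_rate, central = abs_rate - p$ke * state[[2]])
       },
       outputs = list(conc = function(t, state) state[["central"]] / p$V1),
       default_target = "depot")
}

.build_two_cpt_oral <- function(params) {
  p <- .merge_params(list(ka = 0.4, ke = 0.1, k23 = 0.3, k32 = 0.2, V1 = 1),
                     params)
  list(params = p,
       init = c(comp1 = 0, comp2 = 0, comp3 = 0),
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         multi_compartment_rhs(state, ka = p$ka, ke = p$ke, k23 = p$k23,
                               k32 = p$k32, input_rate = inp)
       },
       outputs = list(conc = function(t, state) state[["comp2"]] / p$V1),
       default_target = "comp1")
}

.build_transit <- function(params) {
  p <- .merge_params(list(n_transit = 15, ktr = 0.25, kout = 0.25), params)
  n <- p$n_transit
  if (n < 1) stop("`n_transit` must be >= 1.", call. = FALSE)
  init <- c(setNames(rep(0, n), paste0("transit", seq_len(n))), Aplasma = 0)
  list(params = p,
       init = init,
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         d <- transit_chain_rhs(state[1:n], state[[n + 1]], p$ktr, p$kout,
                                input_rate = inp)
         c(d$d_transit, d$d_Aplasma)
       },
       outputs = NULL,
       default_target = "transit1")
}

.build_tmdd <- function(params) {
  p <- if (inherits(params, "tmdd_params")) params else do.call(tmdd_params, params)
  list(params = p,
       init = c(S = 0, D = 0, T = p$RateT / p$keT, TD = 0),
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         tmdd_rhs(state, p, input_rate = inp)
       },
       outputs = list(
         CFD = function(t, state) p$drug_conc_factor * state[["D"]] / p$V,
         CTD = function(t, state) p$drug_conc_factor * (state[["D"]] + state[["TD"]]) / p$V,
         CFT = function(t, state) p$target_conc_factor * state[["T"]] / p$V,
         CTT = function(t, state) p$target_conc_factor * (state[["T"]] + state[["TD"]]) / p$V
       ),
       default_target = "S")
}

.build_indirect <- function(params) {
  p <- .merge_params(list(ka = 0.1, ke = 0.2, V1 = 33, PD_in = 0.1,
                          PD_out = 0.1), params)
  list(params = p,
       init = c(depot = 0, central = 0, PD = 0),
       rhs = function(t, state, input = NULL) {
         inp <- if (is.null(input)) 0 else input[1]
         conc <- state[[2]] / p$V1
         c(depot = inp - p$ka * state[[1]],
           central = p$ka * state[[1]] - p$ke * state[[2]],
           PD = indirect_effect_rhs(state[[3]], conc, p$PD_in, p$PD_out))
       },
       outputs = list(conc = function(t, state) state[["central"]] / p$V1),
       default_target = "depot")
}
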