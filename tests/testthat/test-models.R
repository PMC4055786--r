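test_that("one-compartment oral derivatives balance inputs and losses", {
  d <- one_compartment_oral_rhs(c(depot = 100, central = 0), ka = 0.1, ke = 0.2)
  expect_equal(d, c(depot = -10, central = 10))
  expect_equal(one_compartment_oral_rhs(c(depot = 0, central = 0), 0.1, 0.2),
               c(depot = 0, central = 0))
  # absorption and elimination cancel at the balance point
  d <- one_compartment_oral_rhs(c(depot = 100, central = 50), 0.1, 0.2)
  expect_equal(unname(d["central"]), 0)
})

test_that("multi-compartment derivatives conserve and equilibrate", {
  st <- c(comp1 = 0, comp2 = 2, comp3 = 3)
  d <- multi_compartment_rhs(st, ka = 0, ke = 0, k23 = 0.3, k32 = 0.2)
  expect_equal(unname(d["comp2"]), 0)  # 2:3 is the k32:k23 equilibrium ratio
  expect_equal(multi_compartment_rhs(c(comp1 = 0, comp2 = 0, comp3 = 0),
                                     0.4, 0.1, 0.3, 0.2),
               c(comp1 = 0, comp2 = 0, comp3 = 0))
  # without elimination or input the derivatives sum to zero
  st <- c(comp1 = 5, comp2 = 7, comp3 = 11)
  expect_equal(sum(multi_compartment_rhs(st, 0.4, 0, 0.3, 0.2)), 0)
})

test_that("transit chain derivatives are a conveyor with conservation", {
  d <- transit_chain_rhs(c(10, 0), Aplasma = 0, ktr = 0.25, kout = 0.25)
  expect_equal(d$d_transit, c(-2.5, 2.5))
  expect_equal(d$d_Aplasma, 0)
  d0 <- transit_chain_rhs(rep(0, 5), 0, 0.25, 0.25)
  expect_equal(d0$d_transit, rep(0, 5))
  # kout = 0, no input: total derivative zero at any state
  st <- runif(8, 0, 50)
  d <- transit_chain_rhs(st, Aplasma = 3, ktr = 0.4, kout = 0)
  expect_equal(sum(d$d_transit) + d$d_Aplasma, 0, tolerance = 1e-12)
  expect_error(transit_chain_rhs(numeric(0), 0, 1, 1), "transit compartment")
})

test_that("transit peak time increases with chain length", {
  cfg <- solver_config(start_time = -1, stop_time = 120, dt = 0.1)
  peak_time <- function(n) {
    mod <- pk_model("transit", list(n_transit = n, ktr = 0.25, kout = 0.25))
    traj <- pk_integrate(mod, dose_regimen(100, n_doses = 1,
                                           target = "transit1"), config = cfg)
    last <- paste0("transit", n)
    traj$time[which.max(traj[[last]])]
  }
  tp <- vapply(c(3, 9, 15), peak_time, numeric(1))
  expect_true(all(diff(tp) > 0))
})

test_that("TMDD derivatives match the binding system and conserve target", {
  p <- tmdd_params()
  expect_equal(p$koff, 1.5)  # koff = Kd * kon reparameterization
  # steady state: T = RateT/keT = 100, everything else zero
  expect_equal(tmdd_rhs(c(S = 0, D = 0, T = 100, TD = 0), p),
               c(S = 0, D = 0, T = 0, TD = 0))
  st <- c(S = 0, D = 7, T = 100, TD = 0)
  d <- tmdd_rhs(st, p)
  expect_equal(unname(d["D"]), -100.21)  # -kon/V*D*T - keD*D
  expect_equal(unname(d["TD"]), 100)     # binding flux only
  # target mass balance: d(T + TD) = RateT - keT*T - keTD*TD at random states
  set.seed(11)
  for (i in 1:20) {
    st <- c(S = runif(1, 0, 500), D = runif(1, 0, 500),
            T = runif(1, 0, 200), TD = runif(1, 0, 200))
    d <- tmdd_rhs(st, p)
    expect_equal(unname(d["T"] + d["TD"]),
                 p$RateT - p$keT * st[["T"]] - p$keTD * st[["TD"]],
                 tolerance = 1e-12)
  }
})

test_that("TMDD concentrations form free and total quantities", {
  p <- tmdd_params()
  cc <- tmdd_concentrations(D = 0, T = 100, TD = 0, params = p)
  expect_equal(cc$CTT, 190 * 100 / 7, tolerance = 1e-12)
  expect_equal(tmdd_concentrations(0, 0, 0, p),
               tibble::tibble(CFD = 0, CTD = 0, CFT = 0, CTT = 0))
  cc <- tmdd_concentrations(D = 12, T = 34, TD = 5, p)
  expect_lte(cc$CFT, cc$CTT)
  expect_lte(cc$CFD, cc$CTD)
})

test_that("TMDD with no dosing stays at steady state over 112 days", {
  cfg <- solver_config("adaptive_stiff", start_time = -28, stop_time = 84,
                       dt_min = 1e-3, dt_max = 0.1, tolerance = 1e-3,
                       dt_out = 1)
  traj <- pk_integrate(pk_model("tmdd", tmdd_params()), config = cfg)
  expect_lt(max(abs(traj$T - 100)) / 100, 1e-3)
  expect_equal(max(abs(traj$D)), 0, tolerance = 1e-6)
  expect_equal(max(abs(traj$TD)), 0, tolerance = 1e-6)
})

test_that("circadian factor has amplitude, phase, and exact period 24", {
  expect_equal(circadian_factor(10, amp = 0.3, tshift = 10), 1.3)
  expect_equal(circadian_factor(22, amp = 0.1, tshift = 10), 0.9)
  expect_equal(circadian_factor(seq(0, 48, 0.5), 0, 10), rep(1, 97))
  t <- seq(-12, 36, by = 0.25)
  expect_equal(circadian_factor(t + 24, 0.2, 10), circadian_factor(t, 0.2, 10),
               tolerance = 1e-14)
})

test_that("placebo factor starts at 1 and settles at 1 + maxup - maxdown", {
  expect_equal(placebo_factor(0), 1)
  expect_equal(placebo_factor(1e6), 1)  # defaults: maxup = maxdown = 0.1
  expect_equal(placebo_factor(1), 0.9627061, tolerance = 1e-6)
  expect_equal(placebo_factor(1e6, maxdown = 0.2, maxup = 0.05), 0.85)
})

test_that("Emax effect is half-maximal at EC50 and saturates", {
  expect_equal(emax_effect(40, E0 = 25, Emax = 50, EC50 = 40), 50)
  expect_equal(emax_effect(0, 25, 50, 40), 25)
  expect_equal(emax_effect(1e12, 25, 50, 40), 75, tolerance = 1e-6)
})

test_that("logistic response is stable, symmetric and bounded", {
  expect_equal(logistic_response(0), 0.5)
  expect_equal(logistic_response(1e4), 1)
  expect_equal(logistic_response(-1e4), 0)
  x <- seq(-5, 5, 0.5)
  expect_equal(logistic_response(x) + logistic_response(-x), rep(1, length(x)))
  set.seed(4)
  p <- logistic_response(rnorm(200, 0, 50), a = rnorm(1), b = rnorm(1))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("indirect response has the expected steady state", {
  expect_equal(indirect_effect_rhs(40, 40, 0.1, 0.1), 0)
  expect_equal(indirect_effect_rhs(0, 0, 0.1, 0.1), 0)
  # constant concentration: PD rises monotonically to PD_in*C/PD_out
  cfg <- solver_config(start_time = 0, stop_time = 100, dt = 0.05)
  mod <- pk_model("one_cpt_oral_indirect",
                  list(ka = 0, ke = 0, V1 = 1, PD_in = 0.1, PD_out = 0.1))
  traj <- pk_integrate(mod, init = c(depot = 0, central = 40, PD = 0),
                       config = cfg)
  expect_true(all(diff(traj$PD) > 0))
  expect_equal(traj$PD[nrow(traj)], 40 * (1 - exp(-0.1 * 100)),
               tolerance = 1e-6)
})

test_that("flare probability is a declining Hill curve in [0, 1]", {
  expect_equal(flare_probability(1.13, KIEF = 1.13, HILL = 4.22), 0.5)
  expect_equal(flare_probability(0, 1.13, 4.22), 1)
  expect_equal(flare_probability(1e9, 1.13, 4.22), 0)
  set.seed(9)
  conc <- sort(runif(100, 0, 20))
  p <- flare_probability(conc, KIEF = 2, HILL = 3)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) < 0))
})

test_that("closed-form references include the ka = ke limit", {
  expect_equal(pk_analytic("one_cpt_bolus", list(dose = 100, ke = 0.2), 0), 100)
  expect_equal(pk_analytic("one_cpt_oral_bateman",
                           list(dose = 100, ka = 0.1, ke = 0.2), 10),
               23.25442, tolerance = 1e-6)
  expect_equal(pk_analytic("one_cpt_oral_bateman",
                           list(dose = 100, ka = 0.1, ke = 0.1), 10),
               100 * 0.1 * 10 * exp(-1), tolerance = 1e-12)
  # the limit is continuous: ke -> ka approaches the degenerate form
  near <- pk_analytic("one_cpt_oral_bateman",
                      list(dose = 100, ka = 0.1, ke = 0.1 + 1e-9), 10)
  expect_equal(near, 100 * 0.1 * 10 * exp(-1), tolerance = 1e-6)
  expect_error(pk_analytic("nope", list(), 1), "Unknown reference model")
})

test_that("capped absorption slows delivery but preserves mass", {
  cfg <- solver_config(start_time = -1, stop_time = 200, dt = 0.02)
  capped <- pk_model("one_cpt_oral", list(ka = 1, ke = 0, absmax = 20))
  free <- pk_model("one_cpt_oral", list(ka = 1, ke = 0, absmax = Inf))
  reg <- dose_regimen(100, n_doses = 1)
  tc <- pk_integrate(capped, reg, config = cfg)
  tf <- pk_integrate(free, reg, config = cfg)
  i24 <- which.min(abs(tc$time - 2))
  expect_lt(tc$central[i24], tf$central[i24])      # slower uptake
  expect_equal(tc$central[nrow(tc)] + tc$depot[nrow(tc)], 100,
               tolerance = 1e-9)                   # same total mass
})
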