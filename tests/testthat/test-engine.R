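test_that("single steps reproduce hand-computed updates", {
  decay <- function(t, y) -y
  # one Euler step of y' = -y from 1: 1 - 0.1
  expect_equal(unname(ode_step("euler", decay, 0, c(y = 1), 0.1)), 0.9)
  # one classical RK4 step equals the 4th-order Taylor expansion of e^-0.1
  taylor4 <- 1 - 0.1 + 0.1^2 / 2 - 0.1^3 / 6 + 0.1^4 / 24
  expect_equal(unname(ode_step("rk4", decay, 0, c(y = 1), 0.1)), taylor4,
               tolerance = 1e-12)
  expect_equal(taylor4, 0.9048375)
  # zero derivative leaves any state unchanged, all methods
  for (m in c("euler", "rk2", "rk4")) {
    expect_equal(ode_step(m, function(t, y) 0 * y, 2, c(a = 3, b = -1), 0.5),
                 c(a = 3, b = -1))
  }
  expect_error(ode_step("rk4", function(t, y) NaN * y, 0, c(y = 1), 0.1),
               "Non-finite derivative for y at t = 0")
})

test_that("dose_times expands regimens and respects the window", {
  cfg <- solver_config(start_time = -1, stop_time = 100)
  unlimited <- dose_regimen(100, first_time = 0, interval = 24, n_doses = 0)
  expect_equal(dose_times(unlimited, cfg)$time, c(0, 24, 48, 72, 96))
  expect_equal(dose_times(unlimited, cfg)$amount, rep(100, 5))
  limited <- dose_regimen(100, interval = 24, n_doses = 3)
  expect_equal(dose_times(limited, cfg)$time, c(0, 24, 48))
  lagged <- dose_regimen(100, interval = 24, n_doses = 3, lag = 0.5)
  expect_equal(dose_times(lagged, cfg)$time, c(0.5, 24.5, 48.5))
  # bioavailability scales the delivered amount
  half <- dose_regimen(100, n_doses = 1, bioavailability = 0.5)
  expect_equal(dose_times(half, cfg)$amount, 50)
  # empty list allowed
  none <- dose_regimen(100, first_time = 200, n_doses = 1)
  expect_equal(nrow(dose_times(none, cfg)), 0)
})

test_that("infusion window follows the modulo rule", {
  expect_equal(infusion_rate_at(1, 7, 2, 24), 7)
  expect_equal(infusion_rate_at(25, 7, 2, 24), 7)  # mod(25, 24) = 1 < 2
  expect_equal(infusion_rate_at(-1, 7, 2, 24), 0)  # before first dose
  expect_equal(infusion_rate_at(c(0, 1.99, 2, 23.9, 24), 7, 2, 24),
               c(7, 7, 0, 0, 7))
  expect_error(infusion_rate_at(0, 7, -1, 24), "Negative duration")
})

test_that("saturable absorption caps at absmax", {
  expect_equal(saturable_absorption_rate(100, 1, 20), 20)
  expect_equal(saturable_absorption_rate(10, 1, 20), 10)
  expect_equal(saturable_absorption_rate(0, 1, 20), 0)
})

test_that("RK4 integration matches the closed-form solutions", {
  cfg <- solver_config("rk4", start_time = -1, stop_time = 100, dt = 0.02)
  bolus <- pk_integrate(pk_model("one_cpt_bolus", list(ke = 0.2)),
                        dose_regimen(100, n_doses = 1, target = "central"),
                        config = cfg)
  at5 <- bolus$central[which.min(abs(bolus$time - 5))]
  expect_equal(at5, 100 * exp(-0.2 * 5), tolerance = 1e-7)

  oral <- pk_integrate(pk_model("one_cpt_oral", list(ka = 0.1, ke = 0.2)),
                       dose_regimen(100, n_doses = 1), config = cfg)
  at10 <- oral$central[which.min(abs(oral$time - 10))]
  expect_equal(at10, 23.25442, tolerance = 1e-5)

  keep <- bolus$time > 0
  ref <- pk_analytic("one_cpt_bolus", list(dose = 100, ke = 0.2),
                     bolus$time[keep])
  expect_lt(max(abs(bolus$central[keep] - ref) / ref), 1e-6)
  keep <- oral$time > 0.05
  ref <- pk_analytic("one_cpt_oral_bateman",
                     list(dose = 100, ka = 0.1, ke = 0.2), oral$time[keep])
  expect_lt(max(abs(oral$central[keep] - ref) / ref), 1e-6)
})

test_that("no doses and zero initial state give an all-zero trajectory", {
  traj <- pk_integrate(pk_model("one_cpt_oral"), config = cfg_fast(10))
  expect_true(all(as.matrix(traj[, c("depot", "central")]) == 0))
})

test_that("RK4 shows fourth-order self-convergence on halving dt", {
  run <- function(dt) {
    cfg <- solver_config("rk4", start_time = 0, stop_time = 10, dt = dt)
    traj <- pk_integrate(pk_model("one_cpt_oral", list(ka = 0.3, ke = 0.1)),
                         init = c(depot = 100, central = 0), config = cfg)
    traj$central[nrow(traj)]
  }
  v1 <- run(0.4); v2 <- run(0.2); v3 <- run(0.1)
  d12 <- abs(v1 - v2); d23 <- abs(v2 - v3)
  expect_lt(d23, d12)          # refinement shrinks the change
  expect_lt(d23, d12 / 8)      # consistent with order >= 3 asymptotics
})

test_that("linear PK scales linearly with dose", {
  cfg <- cfg_fast(72, dt = 0.05)
  run <- function(dose) pk_integrate(
    pk_model("one_cpt_oral", list(ka = 0.2, ke = 0.1)),
    dose_regimen(dose, interval = 24, n_doses = 3), config = cfg)
  t1 <- run(50); t3 <- run(150)
  expect_equal(3 * t1$central, t3$central, tolerance = 1e-12)
  expect_equal(3 * t1$depot, t3$depot, tolerance = 1e-12)
})

test_that("mass is conserved when elimination is switched off", {
  cfg <- solver_config("rk4", start_time = -1, stop_time = 120, dt = 0.1)
  reg <- dose_regimen(100, interval = 24, n_doses = 3)
  # transit chain, kout = 0
  mod <- pk_model("transit", list(n_transit = 15, ktr = 0.25, kout = 0))
  reg_t <- dose_regimen(100, interval = 24, n_doses = 3, target = "transit1")
  traj <- pk_integrate(mod, reg_t, config = cfg)
  tot <- total_amount(traj, setdiff(names(traj), "time"))
  expected <- administered_before(traj$time, dose_times(reg_t, cfg))
  keep <- expected > 0
  expect_lt(max(abs(tot[keep] - expected[keep]) / expected[keep]), 1e-9)
  # three-compartment model, ke = 0
  mod3 <- pk_model("two_cpt_oral", list(ka = 0.4, ke = 0, k23 = 0.3, k32 = 0.2))
  traj3 <- pk_integrate(mod3, dose_regimen(100, interval = 24, n_doses = 3,
                                           target = "comp1"), config = cfg)
  tot3 <- total_amount(traj3, c("comp1", "comp2", "comp3"))
  expected3 <- administered_before(traj3$time, dose_times(reg, cfg))
  keep <- expected3 > 0
  expect_lt(max(abs(tot3[keep] - expected3[keep]) / expected3[keep]), 1e-9)
})

test_that("off-grid dose times snap forward with a warning", {
  cfg <- solver_config(start_time = 0, stop_time = 1, dt = 0.25)
  reg <- dose_regimen(10, first_time = 0.3, n_doses = 1, target = "central")
  expect_warning(
    traj <- pk_integrate(pk_model("one_cpt_bolus", list(ke = 0)), reg,
                         config = cfg),
    "snapped forward")
  expect_equal(traj$central[traj$time == 0.5][1], 0)   # pre-dose row
  expect_equal(traj$central[traj$time == 0.75][1], 10)
})

test_that("infusion regimens deliver the zero-order input", {
  # 2 h infusion at 7 mg/h every 24 h with no elimination: 14 mg per cycle
  cfg <- solver_config(start_time = -1, stop_time = 47, dt = 0.01)
  reg <- dose_regimen(route = "infusion", infusion_rate = 7,
                      infusion_duration = 2, interval = 24, target = "central")
  traj <- pk_integrate(pk_model("one_cpt_bolus", list(ke = 0)), reg,
                       config = cfg)
  expect_equal(traj$central[which.min(abs(traj$time - 23))], 14,
               tolerance = 1e-9)
  expect_equal(traj$central[nrow(traj)], 28, tolerance = 1e-9)
})

test_that("dt_out thins the output grid by interpolation", {
  cfg <- solver_config(start_time = 0, stop_time = 10, dt = 0.02, dt_out = 1)
  traj <- pk_integrate(pk_model("one_cpt_bolus", list(ke = 0.2)),
                       init = c(central = 100), config = cfg)
  expect_equal(traj$time, 0:10)
  expect_equal(traj$central, 100 * exp(-0.2 * (0:10)), tolerance = 1e-6)
})

test_that("the adaptive stiff method solves the TMDD system", {
  p <- tmdd_params()
  cfg <- solver_config("adaptive_stiff", start_time = -28, stop_time = 84,
                       dt_min = 1e-3, dt_max = 0.1, tolerance = 1e-3,
                       dt_out = 1)
  # undosed: stays at the target turnover steady state
  traj <- pk_integrate(pk_model("tmdd", p), config = cfg)
  expect_equal(range(traj$T), c(100, 100), tolerance = 1e-3)
  # dosed: nonlinear kinetics, complexes form and drug is absorbed
  dosed <- pk_integrate(pk_model("tmdd", p),
                        dose_regimen(150 / 0.15, interval = 28, target = "S"),
                        config = cfg)
  expect_gt(max(dosed$TD), 0)
  expect_lt(min(dosed$CFT), 190 * 100 / 7)  # free target suppressed
})

test_that("invalid configurations are rejected", {
  expect_error(solver_config(start_time = 10, stop_time = 0), "stop_time")
  expect_error(solver_config(dt = 0), "dt")
  expect_error(dose_regimen(-1), "amount")
  expect_error(dose_regimen(route = "infusion", infusion_rate = 1,
                            infusion_duration = 30, interval = 24),
               "infusion_duration")
  expect_error(
    pk_integrate(pk_model("one_cpt_oral"),
                 dose_regimen(10, target = "nowhere"), config = cfg_fast(10)),
    "Unknown dose target")
})
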