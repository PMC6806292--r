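test_that("parameter validation enforces the physical boxes", {
  expect_s3_class(patient_params(), "patient_params")
  expect_error(patient_params(SI = -0.001), "positive")
  expect_error(patient_params(Ag = 0), "Ag")
  expect_error(patient_params(Ag = 1.2), "Ag")
  expect_error(patient_params(tl = 90, tmaxG = 85), "tl")
  expect_error(patient_params(SG = NA), "finite")
})

test_that("meal classes shift the absorption time by the fixed 20 min", {
  p <- patient_params(tmaxG = 85)
  expect_equal(effective_tmaxg(p, "fast"), 65)
  expect_equal(effective_tmaxg(p, "medium"), 85)
  expect_equal(effective_tmaxg(p, "slow"), 105)
  expect_error(effective_tmaxg(p, "brunch"))
})

test_that("basal steady state has zero derivatives and stays put for 24 h", {
  p <- default_test_params()
  x <- model_state(G = p$Gb)
  d <- derivatives(x, p, list(uCHO = 0, uINS = 0, uABS = "none"))
  expect_equal(unname(d), rep(0, 7))
  traj <- simulate_model(x, p, event_schedule(horizon = 1440))
  expect_lt(max(abs(traj$G - p$Gb)), 1e-9)
})

test_that("derivatives match an independent evaluation of the model", {
  p <- patient_params(SG = 0.02, ke = 1.5, p2 = 0.02, Ag = 0.85,
                      V = 0.9, Vi = 1.2, SI = 0.003, Gb = 120, W = 70,
                      tmaxI = 75, tmaxG = 85)
  x <- model_state(G = 150, X = 0.01, S1 = 200, S2 = 150, I = 20,
                   Ra1 = 300, Ra = 250)
  d <- derivatives(x, p, list(uCHO = 500, uINS = 40, uABS = "fast"))
  # independent arithmetic, written straight from the model equations
  expect_equal(d[["G"]], -(0.02 + 0.01) * 150 + 0.02 * 120 +
                 250 / (0.9 * 70))
  expect_equal(d[["X"]], -0.02 * 0.01 + 0.02 * 0.003 * 20)
  expect_equal(d[["S1"]], 40 - 200 / 75)
  expect_equal(d[["S2"]], (200 - 150) / 75)
  expect_equal(d[["I"]], -1.5 * 20 + 1000 * 150 / (1.2 * 70 * 75))
  expect_equal(d[["Ra1"]], -(300 - 0.85 * 500) / 65)  # fast: tmaxG - 20
  expect_equal(d[["Ra"]], -(250 - 300) / 65)
})

test_that("a gut balance Ra = Ra1 gives a zero Ra derivative", {
  p <- default_test_params()
  x <- model_state(G = 120, Ra1 = 123.4, Ra = 123.4)
  d <- derivatives(x, p)
  expect_equal(d[["Ra"]], 0)
})

test_that("a meal impulse enters the first gut compartment only", {
  p <- default_test_params()
  x0 <- model_state(G = p$Gb)
  x1 <- euler_step(x0, p, list(uCHO = 60000, uINS = 0, uABS = "medium"))
  expect_equal(x1[["Ra1"]], 0.85 * 60000 / p$tmaxG)
  expect_equal(x1[["Ra"]], 0)
  expect_error(euler_step(x0, p, dt = 0), "dt")
})

test_that("gut mass is conserved: integral of Ra approaches Ag * dose", {
  p <- patient_params(Ag = 1)
  sched <- event_schedule(
    meals = data.frame(time_min = 10, grams = 60, class = "medium"),
    horizon = 2880)
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  expect_equal(sum(traj$Ra[-1]), 60000, tolerance = 0.01)
})

test_that("1-min Euler matches an adaptive-step ODE oracle within 1 mg/dL", {
  skip_if_not_installed("deSolve")
  p <- default_test_params()
  sched <- day_schedule()
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  orac <- ode_oracle(model_state(G = p$Gb), p, sched)
  expect_lt(rmse(traj$G, orac$G), 1)
})

test_that("a single bolus yields an ordered unimodal insulin cascade", {
  p <- default_test_params()
  sched <- event_schedule(
    boluses = data.frame(time_min = 60, units = 0.5), horizon = 720)
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  pk <- vapply(c("S1", "S2", "I"), function(v) which.max(traj[[v]]),
               integer(1))
  expect_true(pk[["S1"]] < pk[["S2"]] && pk[["S2"]] < pk[["I"]])
  for (v in c("S1", "S2", "I")) {
    y <- traj[[v]]
    ix <- which.max(y)
    expect_true(all(diff(y[1:ix]) >= -1e-9))
    expect_true(all(diff(y[ix:length(y)]) <= 1e-9))
  }
  # insulin with no meal pushes glucose below basal
  expect_lt(min(traj$G), p$Gb)
})

test_that("fast meals peak earlier than slow meals", {
  p <- default_test_params()
  mk <- function(cls) {
    sched <- event_schedule(
      meals = data.frame(time_min = 10, grams = 60, class = cls),
      horizon = 720)
    simulate_model(model_state(G = p$Gb), p, sched)
  }
  expect_lt(which.max(mk("fast")$Ra), which.max(mk("medium")$Ra))
  expect_lt(which.max(mk("medium")$Ra), which.max(mk("slow")$Ra))
})

test_that("the later of two overlapping meals controls the meal class", {
  p <- default_test_params()
  sched <- event_schedule(
    meals = data.frame(time_min = c(100, 160), grams = c(10, 10),
                       class = c("slow", "fast")),
    horizon = 480)
  arr <- glucast:::schedule_arrays(sched, p)
  expect_equal(arr$tmaxg[150], effective_tmaxg(p, "slow"))
  expect_equal(arr$tmaxg[200], effective_tmaxg(p, "fast"))
})
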