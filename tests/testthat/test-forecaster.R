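test_that("initialisation anchors glucose to the first CGM sample", {
  x <- initialize_state(120)
  expect_equal(unname(x), c(120, 0, 0, 0, 0, 0, 0))
  expect_error(initialize_state(0), "positive")
  expect_error(initialize_state(-5), "positive")
})

test_that("fusion is the stated weighted average and passes insulin through", {
  x <- model_state(G = 100, X = 0.01, S1 = 5, S2 = 4, I = 3, Ra1 = 8,
                   Ra = 10)
  cfg <- forecast_config(q1 = 0.7, q2 = 0.7)
  f <- fuse(x, list(ra_filtered = 20, ra1 = 18), 110, cfg)
  expect_equal(f[["Ra"]], 0.7 * 20 + 0.3 * 10)   # 17
  expect_equal(f[["Ra1"]], 0.7 * 18 + 0.3 * 8)
  expect_equal(f[["G"]], 0.7 * 110 + 0.3 * 100)  # 107
  expect_equal(f[c("X", "S1", "S2", "I")], x[c("X", "S1", "S2", "I")])
  # boundary weights
  f0 <- fuse(x, list(ra_filtered = 20, ra1 = 18), 110,
             forecast_config(q1 = 0, q2 = 0))
  expect_equal(f0, x)
  f1 <- fuse(x, list(ra_filtered = 20, ra1 = 18), 110,
             forecast_config(q1 = 1, q2 = 1))
  expect_equal(unname(f1[c("G", "Ra1", "Ra")]), c(110, 18, 20))
  expect_error(forecast_config(q1 = 1.2), "weights")
})

test_that("compiled and reference R engines produce the same forecasts", {
  p <- default_test_params()
  sched <- day_schedule()
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  set.seed(4)
  idx <- seq(1, nrow(traj), by = 5)
  cgm <- cgm_series(traj$time[idx],
                    pmin(pmax(traj$G[idx] + rnorm(length(idx), 0, 5), 20),
                         600))
  for (ph in c(0, 30)) {
    cfg <- forecast_config(ph = ph)
    a <- run_forecaster(cgm, sched, p, cfg, engine = "cpp")
    b <- run_forecaster(cgm, sched, p, cfg, engine = "r")
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("a zero horizon returns the fused glucose", {
  p <- default_test_params()
  sched <- day_schedule()
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  cgm <- noiseless_cgm(traj)
  res <- run_forecaster(cgm, sched, p, forecast_config(ph = 0),
                        details = TRUE)
  expect_equal(res$records$g_forecast, unname(res$fused[-(1:2), "G"]))
})

test_that("record bookkeeping: warm start and unmatched tail", {
  p <- default_test_params()
  cgm <- cgm_series(seq(0, 495, by = 5), rep(p$Gb, 100))
  rec <- run_forecaster(cgm, event_schedule(horizon = 600), p,
                        forecast_config(ph = 30))
  expect_equal(nrow(rec), 98)            # N - 2 with a 3-sample warm start
  expect_equal(sum(is.na(rec$g_observed)), 6)  # last PH/M anchors unmatched
  # constant CGM at basal with no events forecasts the basal level
  expect_equal(rec$g_forecast, rep(p$Gb, 98))
})

test_that("fusion weight boundaries reproduce pure simulation / anchoring", {
  p <- default_test_params()
  sched <- day_schedule()
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  cgm <- noiseless_cgm(traj)
  # Q = 0: per-sample states equal an uncorrected simulation started from
  # the first CGM value
  res0 <- run_forecaster(cgm, sched, p,
                         forecast_config(q1 = 0, q2 = 0, ph = 0),
                         details = TRUE)
  pure <- simulate_model(model_state(G = cgm$glucose[1]), p, sched)
  expect_equal(res0$fused[, "G"],
               pure$G[pure$time %in% cgm$time_min],
               tolerance = 1e-12)
  # Q = 1: glucose anchored to the CGM and gut states to the deconvolution
  res1 <- run_forecaster(cgm, sched, p,
                         forecast_config(q1 = 1, q2 = 1, ph = 0),
                         details = TRUE)
  expect_equal(unname(res1$fused[, "G"]), cgm$glucose)
  expect_equal(unname(res1$fused[, "Ra"]), res1$deconvolution$ra_filtered)
  expect_equal(unname(res1$fused[, "Ra1"]), res1$deconvolution$ra1)
})

test_that("forecasts are deterministic and degrade with the horizon", {
  p <- default_test_params()
  sched <- day_schedule(horizon = 1560)
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  set.seed(11)
  idx <- seq(1, 1441, by = 5)
  cgm <- cgm_series(traj$time[idx],
                    pmin(pmax(traj$G[idx] + rnorm(length(idx), 0, 8), 20),
                         600))
  r1 <- run_forecaster(cgm, sched, p, forecast_config(ph = 30))
  r2 <- run_forecaster(cgm, sched, p, forecast_config(ph = 30))
  expect_identical(r1, r2)
  e30 <- rmse(r1$g_forecast, r1$g_observed)
  r120 <- run_forecaster(cgm, sched, p, forecast_config(ph = 120))
  e120 <- rmse(r120$g_forecast, r120$g_observed)
  expect_lt(e30, e120)
})

test_that("gaps must be imputed before forecasting", {
  p <- default_test_params()
  g <- rep(p$Gb, 20)
  g[8] <- NA
  cgm <- cgm_series(seq(0, 95, by = 5), g)
  expect_error(run_forecaster(cgm, event_schedule(horizon = 200), p),
               "impute")
  cgm2 <- cgm_series(c(0, 5, 15, 20), rep(100, 4), interval = 5)
  expect_error(run_forecaster(cgm2, event_schedule(horizon = 200), p),
               "grid")
})

test_that("meal announcement within the horizon is used and switchable", {
  p <- default_test_params()
  sched <- event_schedule(
    meals = data.frame(time_min = 305, grams = 80, class = "fast"),
    horizon = 600)
  traj <- simulate_model(model_state(G = p$Gb), p, sched)
  cgm <- noiseless_cgm(traj)
  cgm <- cgm[cgm$time_min <= 300, , drop = FALSE]
  on <- run_forecaster(cgm, sched, p, forecast_config(ph = 60))
  off <- run_forecaster(cgm, sched, p,
                        forecast_config(ph = 60, announce_meals = FALSE))
  n <- nrow(on)
  # with announcement the last anchor sees the future meal and predicts a
  # rise; without it the forecast stays at basal
  expect_gt(on$g_forecast[n], off$g_forecast[n] + 20)
})
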