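test_that("rmse and mard match hand arithmetic", {
  expect_equal(rmse(c(100, 120), c(100, 120)), 0)
  expect_equal(rmse(c(110, 120), c(100, 100)), sqrt(250))
  expect_equal(rmse(70, 100), 30)
  expect_equal(mard(c(110, 90), c(100, 100)), 10)
  expect_equal(mard(120, 100), 20)
  expect_equal(mard(c(100, 100), c(100, 100)), 0)
  expect_error(rmse(numeric(), numeric()))
  expect_error(mard(100, -1), "positive")
  # homogeneity: scaling residuals scales the RMSE
  obs <- c(100, 150, 200)
  err <- c(5, -10, 20)
  expect_equal(rmse(obs + 3 * err, obs), 3 * rmse(obs + err, obs))
})

test_that("error-grid regions follow the rule list with A,E,C,D,B precedence", {
  expect_equal(as.character(ega_region(100, 100)), "A")
  expect_equal(as.character(ega_region(60, 60)), "A")    # joint hypo
  expect_equal(as.character(ega_region(65, 150)), "C")
  expect_equal(as.character(ega_region(60, 200)), "E")
  expect_equal(as.character(ega_region(200, 60)), "E")
  expect_equal(as.character(ega_region(100, 220)), "D")
  expect_equal(as.character(ega_region(100, 65)), "D")
  expect_equal(as.character(ega_region(100, 210)), "D")
  expect_equal(as.character(ega_region(200, 320)), "C")  # >100 below obs
  expect_equal(as.character(ega_region(130, 250)), "D")  # D beats C when in target
  expect_equal(as.character(ega_region(250, 150)), "B")
  # every pair maps to exactly one region and percentages sum to 100
  set.seed(2)
  f <- runif(500, 25, 590); o <- runif(500, 25, 590)
  expect_false(anyNA(ega_region(f, o)))
  expect_equal(sum(ega_summary(f, o)), 100)
  summ <- ega_summary(c(100, 60, 65, 60, 100), c(100, 60, 150, 200, 220))
  expect_equal(unname(summ), c(40, 0, 20, 20, 20))
})

test_that("hypoglycaemic events are maximal runs of >= 3 samples below 70", {
  ev <- detect_hypo_events(c(100, 65, 64, 63, 80))
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start, ev$end), c(2, 4))
  expect_equal(nrow(detect_hypo_events(c(100, 65, 80, 65, 80))), 0)
  ev2 <- detect_hypo_events(rep(60, 10))
  expect_equal(c(ev2$start, ev2$end, ev2$length), c(1, 10, 10))
})

test_that("confusion counting works at sample and event level", {
  obs <- c(100, 65, 64, 63, 80, 90, 100, 100)
  expect_equal(unname(hypo_confusion(obs, obs)[c("FP", "FN")]), c(0, 0))
  pred <- c(100, 100, 100, 100, 100, 60, 60, 60)
  conf <- hypo_confusion(pred, rep(100, 8))
  expect_equal(unname(conf), c(0, 3, 5, 0))  # TP FP TN FN
  none <- hypo_confusion(rep(100, 8), rep(100, 8))
  expect_equal(unname(none), c(0, 0, 8, 0))
  expect_equal(mcc(none), 0)
  # event level: any overlap counts once
  ev <- hypo_confusion(c(60, 60, 60, 100, 100, 100),
                       c(100, 60, 60, 60, 100, 100), level = "event")
  expect_equal(unname(ev[c("TP", "FP", "FN")]), c(1, 0, 0))
  expect_error(hypo_confusion(1:3, 1:4), "aligned")
})

test_that("MCC matches its closed form and symmetries", {
  expect_equal(mcc(TP = 1, TN = 1, FP = 0, FN = 0), 1)
  expect_equal(mcc(TP = 6, TN = 9, FP = 1, FN = 2), 52 / sqrt(6160))
  expect_equal(mcc(TP = 0, TN = 0, FP = 1, FN = 1), -1)
  expect_equal(mcc(TP = 5, TN = 0, FP = 0, FN = 0), 0)  # degenerate
  set.seed(3)
  for (i in 1:20) {
    v <- sample(0:30, 4, replace = TRUE)
    m <- mcc(v[1], v[2], v[3], v[4])
    expect_gte(m, -1); expect_lte(m, 1)
    # swapping classes preserves MCC; inverting labels flips its sign
    expect_equal(mcc(v[2], v[1], v[4], v[3]), m)
    expect_equal(mcc(v[4], v[3], v[2], v[1]), -m)
  }
  expect_error(mcc(-1, 0, 0, 0))
})

test_that("metrics_report aggregates all metrics over matched pairs", {
  rec <- data.frame(time_min = seq(0, 45, by = 5),
                    g_forecast = c(100, 110, 60, 62, 61, 100, 210, 180,
                                   100, 100),
                    g_observed = c(105, 100, 65, 64, 66, 95, 200, 185,
                                   NA, 100),
                    ph_min = 30)
  rep <- metrics_report(rec)
  expect_equal(rep$n, 9)
  expect_equal(sum(rep$ega), 100)
  expect_equal(rep$rmse, rmse(rec$g_forecast[-9], rec$g_observed[-9]))
  expect_true(rep$mcc >= -1 && rep$mcc <= 1)
})
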