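test_that("cohort sampling is deterministic and honours zero spreads", {
  cfg <- cohort_config(n_subjects = 4, seed = 123)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  cfg0 <- cohort_config(n_subjects = 3, seed = 5, si_sd = 0, tmaxi_sd = 0,
                        tmaxg_sd = 0, w_sd = 0, gb_sd = 0)
  cohort <- sample_cohort(cfg0)
  expect_equal(cohort[[1]], cohort[[3]])
  expect_equal(cohort[[1]]$SI, cfg0$si_mean)
  expect_error(cohort_config(), "seed")
})

test_that("sampled SI dispersion matches the censored-normal target moments", {
  cfg <- cohort_config(n_subjects = 1000, seed = 77)
  si <- vapply(sample_cohort(cfg), `[[`, numeric(1), "SI")
  # oracle: moments of a normal(0.00275, 0.0014) censored into
  # [0.001, 0.005], by numerical integration
  dens <- function(x) dnorm(x, cfg$si_mean, cfg$si_sd)
  lo <- 0.001; hi <- 0.005
  m1 <- integrate(function(x) x * dens(x), lo, hi)$value +
    lo * pnorm(lo, cfg$si_mean, cfg$si_sd) +
    hi * (1 - pnorm(hi, cfg$si_mean, cfg$si_sd))
  m2 <- integrate(function(x) x^2 * dens(x), lo, hi)$value +
    lo^2 * pnorm(lo, cfg$si_mean, cfg$si_sd) +
    hi^2 * (1 - pnorm(hi, cfg$si_mean, cfg$si_sd))
  target_sd <- sqrt(m2 - m1^2)
  expect_equal(mean(si), m1, tolerance = 4 * target_sd / sqrt(1000) / m1)
  expect_equal(sd(si), target_sd, tolerance = 0.1)
  expect_true(all(si >= lo & si <= hi))
})

test_that("scenario meals follow the configured daily pattern", {
  cfg0 <- cohort_config(n_subjects = 1, seed = 9, meal_cv = 0,
                        meal_time_sd = 0, carb_err = c(0, 0))
  p <- patient_params()
  set.seed(9)
  scen <- generate_scenario(cfg0, p, days = 2)
  m <- scen$truth$meals
  expect_equal(m$time_min, c(420, 780, 1140, 1860, 2220, 2580))
  expect_equal(m$grams, rep(c(70, 100, 80), 2))
  # 14 days yield 42 meals
  set.seed(9)
  expect_equal(nrow(generate_scenario(cfg0, p, 14)$truth$meals), 42)
})

test_that("meal-size CV and carb-counting error match their targets", {
  cfg <- cohort_config(n_subjects = 1, seed = 10)
  p <- patient_params()
  set.seed(10)
  scen <- generate_scenario(cfg, p, days = 334)  # ~1000 meals
  m <- scen$meals
  sizes <- m$true_grams[abs(m$time_min %% 1440 - 780) < 120]
  expect_equal(sd(sizes) / mean(sizes), 0.10, tolerance = 0.2)
  relerr <- m$logged_grams / m$true_grams - 1
  expect_gte(min(relerr), -0.30)
  expect_lte(max(relerr), 0.20)
  expect_gt(max(relerr), 0.10)   # support is actually reached
  expect_lt(min(relerr), -0.20)
  # meal-time jitter is truncated at +/- 60 min
  jit <- m$time_min %% 1440 - rep(c(420, 780, 1140),
                                  length.out = nrow(m))
  expect_lte(max(abs(jit)), 60)
})

test_that("CGM sampling adds the configured noise and flags gaps", {
  p <- patient_params()
  traj <- simulate_model(model_state(G = p$Gb), p,
                         event_schedule(horizon = 7 * 1440))
  cfg0 <- cohort_config(n_subjects = 1, seed = 1, noise_sd = 0,
                        gaps_per_day = 0)
  set.seed(1)
  cgm0 <- generate_cgm(traj, cfg0)
  expect_equal(cgm0$glucose, rep(p$Gb, nrow(cgm0)))
  expect_equal(diff(cgm0$time_min), rep(5, nrow(cgm0) - 1))

  cfg10 <- cohort_config(n_subjects = 1, seed = 1, noise_sd = 10,
                         noise_rho = 0.9, gaps_per_day = 0)
  set.seed(1)
  cgm10 <- generate_cgm(traj, cfg10)
  expect_equal(sd(cgm10$glucose - p$Gb), 10, tolerance = 0.15)

  cfgg <- cohort_config(n_subjects = 1, seed = 2, noise_sd = 0,
                        gaps_per_day = 2, gap_len = c(30, 30))
  set.seed(2)
  cgmg <- generate_cgm(traj, cfgg)
  expect_gt(sum(is.na(cgmg$glucose)), 0)
  r <- rle(is.na(cgmg$glucose))
  expect_true(all(r$lengths[r$values] <= 6))
})

test_that("gap imputation is exact on linear data and beats linear on curves", {
  tt <- seq(0, 200, by = 5)
  lin <- 100 + 0.4 * tt
  gap <- tt >= 60 & tt <= 100
  cgm <- cgm_series(tt, ifelse(gap, NA, lin))
  imp <- impute_gaps(cgm)
  expect_equal(imp$glucose, lin)
  expect_equal(imp$imputed, gap)
  # identity when nothing is missing
  full <- cgm_series(tt, lin)
  expect_equal(impute_gaps(full)$glucose, lin)
  # smooth curve: modified-Akima beats straight-line interpolation
  wave <- 150 + 60 * sin(tt / 35)
  cgmw <- cgm_series(tt, ifelse(gap, NA, wave))
  impw <- impute_gaps(cgmw)
  linw <- approx(tt[!gap], wave[!gap], xout = tt)$y
  expect_lt(max(abs(impw$glucose - wave)[gap]),
            max(abs(linw - wave)[gap]))
})

test_that("profile factory and classifier are mutually consistent", {
  # absorption-class thresholds and the +/- 20 min shifts agree on the
  # two-compartment kernel for mid-range absorption times
  for (tg in c(66, 70, 74)) {
    p <- patient_params(tmaxG = tg)
    for (cls in c("fast", "medium", "slow")) {
      prof <- make_ra_profile(cls, 60, p)
      expect_equal(classify_meal(prof), cls)
    }
  }
  p <- patient_params(tmaxG = 70)
  prof <- make_ra_profile("medium", 60, p)
  expect_equal(glucast:::.trapz(prof$time, prof$ra), 0.85 * 60000,
               tolerance = 0.01)
  # peak ordering across classes
  pk <- vapply(c("fast", "medium", "slow"), function(cl)
    make_ra_profile(cl, 60, p)$time[which.max(make_ra_profile(cl, 60,
                                                              p)$ra)],
    numeric(1))
  expect_true(pk[["fast"]] < pk[["medium"]] &&
                pk[["medium"]] < pk[["slow"]])
})

test_that("classifier matches the AUC-fraction rules on constructed profiles", {
  # an impulse at t = 0 has all of its mass within 2 h
  expect_equal(classify_meal(list(time = c(0, 1, 2), ra = c(100, 0, 0))),
               "fast")
  # uniform absorption over 6 h: 1/3 in 2 h, 2/3 in 4 h -> slow
  expect_equal(classify_meal(list(time = 0:360, ra = rep(10, 361))),
               "slow")
  # 50% in 2 h, 90% in 4 h -> medium
  prof <- list(time = 0:300,
               ra = c(rep(1000 / 120, 120), rep(800 / 120, 120),
                      rep(200 / 60, 61)))
  expect_equal(classify_meal(prof), "medium")
  expect_error(classify_meal(list(time = 0:10, ra = rep(0, 11))), "AUC")
})

test_that("end-to-end subject generation is reproducible under one seed", {
  cfg <- cohort_config(n_subjects = 1, seed = 55)
  p <- sample_cohort(cfg)[[1]]
  a <- generate_subject_data(cfg, p, days = 2)
  b <- generate_subject_data(cfg, p, days = 2)
  expect_identical(a$cgm$glucose, b$cgm$glucose)
  expect_identical(a$scenario$meals, b$scenario$meals)
})
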