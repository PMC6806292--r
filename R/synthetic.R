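#' Virtual-patient cohort configuration
#'
#' Defines the statistical structure of the synthetic open-loop scenarios:
#' inter-subject parameter dispersion, the daily meal pattern with its
#' variability (meal-size CV 10%, meal-time jitter SD 20 min truncated at
#' +/- 60 min, carbohydrate-counting error uniform on -30%..+20%), per-meal
#' absorption-kinetics perturbations (+/- 30% on the absorption rate,
#' +/- 10% on bioavailability), daily +/- 30% perturbation of the insulin
#' absorption time, the CGM noise model and the sensor gap model.
#'
#' Subject-level `SI`, `tmaxI` and `tmaxG` are drawn from normal
#' distributions censored to their admissible boxes; the default means and
#' SDs are the dispersion scale of an identified 10-adult in-silico cohort
#' (`SI` 0.00275 +/- 0.0014, `tmaxI` 114.6 +/- 21.6, `tmaxG` 68.9 +/- 6.8).
#'
#' @param n_subjects cohort size.
#' @param base base [patient_params()] supplying the fixed population
#'   constants.
#' @param si_mean,si_sd,tmaxi_mean,tmaxi_sd,tmaxg_mean,tmaxg_sd
#'   inter-subject distributions of the identifiable parameters.
#' @param w_mean,w_sd,gb_mean,gb_sd body weight (kg) and basal glucose
#'   (mg/dL) distributions.
#' @param meal_times,meal_grams daily meal pattern (min after midnight,
#'   grams).
#' @param meal_cv meal-size coefficient of variation.
#' @param meal_time_sd meal-time jitter SD, min (truncated at +/- 60).
#' @param carb_err carbohydrate-counting error support (relative, uniform).
#' @param class_probs per-slot absorption-class sampling weights: a named
#'   list with entries `breakfast` and `main` giving `c(fast, medium,
#'   slow)` weights.  Defaults encode the clinical pattern that breakfasts
#'   are fast-absorption meals while lunches and dinners are mostly medium,
#'   with a minority of fast and slow mixed meals.
#' @param kabs_pert,ag_pert per-meal perturbation half-widths of the
#'   absorption time and bioavailability (relative, uniform).
#' @param ins_pert daily perturbation half-width of the insulin absorption
#'   time (relative, uniform).
#' @param noise_sd CGM additive noise SD, mg/dL.
#' @param noise_rho AR(1) correlation of the CGM noise (0 = white).
#' @param gaps_per_day expected number of sensor gaps per day.
#' @param gap_len gap duration range, min.
#' @param interval CGM sampling interval, min.
#' @param bolus_fraction fraction of each meal's glucose appearance covered
#'   by the bolus (the rest is cleared by glucose effectiveness); sets the
#'   subject's carbohydrate ratio via [carb_ratio()].
#' @param seed mandatory RNG seed; every random draw in the generator flows
#'   from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10, base = patient_params(),
                          si_mean = 0.00275, si_sd = 0.0014,
                          tmaxi_mean = 114.6, tmaxi_sd = 21.6,
                          tmaxg_mean = 68.9, tmaxg_sd = 6.8,
                          w_mean = 70, w_sd = 12,
                          gb_mean = 115, gb_sd = 12,
                          meal_times = c(420, 780, 1140),
                          meal_grams = c(70, 100, 80),
                          meal_cv = 0.10, meal_time_sd = 20,
                          carb_err = c(-0.30, 0.20),
                          class_probs = list(
                            breakfast = c(fast = 8, medium = 2, slow = 0),
                            main = c(fast = 1, medium = 7, slow = 2)),
                          kabs_pert = 0.30, ag_pert = 0.10,
                          ins_pert = 0.30,
                          noise_sd = 10, noise_rho = 0,
                          gaps_per_day = 1, gap_len = c(15, 60),
                          interval = 5, bolus_fraction = 0.5,
                          seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  spreads <- c(si_sd, tmaxi_sd, tmaxg_sd, w_sd, gb_sd, meal_cv,
               meal_time_sd, kabs_pert, ag_pert, ins_pert, noise_sd,
               gaps_per_day)
  if (any(spreads < 0)) stop("spreads must be non-negative", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

# normal draw censored into [lo, hi]
.rnorm_box <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd),
                                                      lo), hi)

#' Sample a virtual cohort of patient parameter sets
#'
#' Draws `n_subjects` parameter sets from the cohort distributions, with
#' the identifiable parameters censored into their admissible boxes.
#' Deterministic under the configuration seed.
#'
#' @param cfg a [cohort_config()].
#' @return List of [patient_params()] objects.
#' @export
sample_cohort <- function(cfg) {
  set.seed(cfg$seed)
  b <- identification_bounds()
  n <- cfg$n_subjects
  si <- .rnorm_box(n, cfg$si_mean, cfg$si_sd, b$SI[1], b$SI[2])
  ti <- .rnorm_box(n, cfg$tmaxi_mean, cfg$tmaxi_sd, b$tmaxI[1], b$tmaxI[2])
  tg <- .rnorm_box(n, cfg$tmaxg_mean, cfg$tmaxg_sd, b$tmaxG[1], b$tmaxG[2])
  w <- .rnorm_box(n, cfg$w_mean, cfg$w_sd, 40, 120)
  gb <- .rnorm_box(n, cfg$gb_mean, cfg$gb_sd, 80, 160)
  lapply(seq_len(n), function(i) {
    p <- cfg$base
    p$SI <- si[i]; p$tmaxI <- ti[i]; p$tmaxG <- tg[i]
    p$W <- w[i]; p$Gb <- gb[i]
    validate_params(p)
    p
  })
}

#' Carbohydrate ratio implied by the model's insulin potency
#'
#' Open-loop bolus rule used by the scenario generator: the bolus covers a
#' fraction `alpha` of the meal's integrated glucose appearance, the rest
#' being cleared by glucose effectiveness.  Balancing the integrated
#' insulin-driven disposal at basal glucose against the meal input gives
#' grams-per-unit
#' `CR = V * Gb * SI * 1e6 / (alpha * Ag * 1000 * Vi * ke)`.
#'
#' @param params a [patient_params()].
#' @param alpha covered fraction of the meal appearance.
#' @return Carbohydrate ratio, g per U.
#' @export
carb_ratio <- function(params, alpha = 0.5) {
  with(params, V * Gb * SI * 1e6 / (alpha * Ag * 1000 * Vi * ke))
}

#' Generate an open-loop two-week scenario for one subject
#'
#' Builds the daily 3-meal pattern with meal-time and meal-size
#' variability, carbohydrate-counting errors, per-meal absorption
#' perturbations, sampled absorption classes, boluses from the subject's
#' carbohydrate ratio applied to the *logged* (miscounted) grams, and a
#' daily perturbation of the insulin absorption time.  The *truth* schedule
#' (actual grams, perturbed kinetics) drives the simulation; the *logged*
#' schedule (miscounted grams, nominal kinetics) is what the forecaster
#' sees.
#'
#' @param cfg a [cohort_config()].
#' @param params the subject's true [patient_params()].
#' @param days scenario length, days.
#' @return List of class `glucast_scenario` with elements `truth` and
#'   `logged` ([event_schedule()]s) and `meals` (per-meal bookkeeping).
#' @export
generate_scenario <- function(cfg, params, days = 14) {
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  horizon <- days * 1440
  n_day <- length(cfg$meal_times)
  rows <- list()
  for (d in seq_len(days) - 1) {
    for (j in seq_len(n_day)) {
      jit <- min(max(rnorm(1, 0, cfg$meal_time_sd), -60), 60)
      tt <- d * 1440 + cfg$meal_times[j] + round(jit)
      true_g <- max(cfg$meal_grams[j] * (1 + rnorm(1, 0, cfg$meal_cv)), 5)
      logged_g <- true_g * (1 + runif(1, cfg$carb_err[1], cfg$carb_err[2]))
      slot <- if (cfg$meal_times[j] %% 1440 < 660) "breakfast" else "main"
      w <- cfg$class_probs[[slot]]
      cls <- sample(c("fast", "medium", "slow"), 1, prob = w / sum(w))
      rows[[length(rows) + 1]] <- data.frame(
        time_min = tt, true_grams = true_g, logged_grams = logged_g,
        class = cls,
        tmaxg_mult = runif(1, 1 - cfg$kabs_pert, 1 + cfg$kabs_pert),
        ag_mult = runif(1, 1 - cfg$ag_pert, 1 + cfg$ag_pert))
    }
  }
  meals <- do.call(rbind, rows)
  meals <- meals[meals$time_min >= 0 & meals$time_min < horizon, ]
  cr <- carb_ratio(params, cfg$bolus_fraction)
  # boluses are taken up to 10 min ahead of the meal, as in usual practice
  boluses <- data.frame(time_min = pmax(meals$time_min -
                                          round(runif(nrow(meals), 0, 10)),
                                        0),
                        units = meals$logged_grams / cr)
  tmaxi_mult <- data.frame(time_min = (seq_len(days) - 1) * 1440,
                           mult = runif(days, 1 - cfg$ins_pert,
                                        1 + cfg$ins_pert))
  truth <- event_schedule(
    meals = data.frame(time_min = meals$time_min, grams = meals$true_grams,
                       class = meals$class, ag_mult = meals$ag_mult,
                       tmaxg_mult = meals$tmaxg_mult),
    boluses = boluses, horizon = horizon, tmaxi_mult = tmaxi_mult)
  logged <- event_schedule(
    meals = data.frame(time_min = meals$time_min,
                       grams = meals$logged_grams, class = meals$class),
    boluses = boluses, horizon = horizon)
  structure(list(truth = truth, logged = logged, meals = meals,
                 carb_ratio = cr), class = "glucast_scenario")
}

#' Sample a noisy, gappy CGM series from a true glucose trajectory
#'
#' Subsamples the 1-min truth onto the sensor grid, adds (optionally
#' AR(1)-correlated) Gaussian noise with marginal SD `noise_sd`, and deletes
#' gap windows drawn from the gap model (Poisson number of gaps, uniform
#' start and duration).  Deleted samples carry `NA` glucose; the first and
#' last three samples are always kept so gaps never touch the series
#' boundary.
#'
#' @param trajectory data frame from [simulate_model()] (or a numeric
#'   vector of 1-min glucose values starting at time 0).
#' @param cfg a [cohort_config()].
#' @return A [cgm_series()] with `NA` at gap samples.
#' @export
generate_cgm <- function(trajectory, cfg) {
  g <- if (is.data.frame(trajectory)) trajectory$G else trajectory
  idx <- seq(1, length(g), by = cfg$interval)
  times <- (idx - 1)
  truth <- g[idx]
  n <- length(truth)
  if (cfg$noise_sd > 0) {
    z <- rnorm(n)
    e <- numeric(n)
    e[1] <- z[1]
    if (cfg$noise_rho > 0) {
      for (k in 2:n) e[k] <- cfg$noise_rho * e[k - 1] +
          sqrt(1 - cfg$noise_rho^2) * z[k]
    } else e <- z
    noisy <- truth + cfg$noise_sd * e
  } else noisy <- truth
  noisy <- pmin(pmax(noisy, 20), 600)
  days <- length(g) / 1440
  n_gaps <- stats::rpois(1, cfg$gaps_per_day * days)
  if (n_gaps > 0) {
    for (k in seq_len(n_gaps)) {
      len <- round(runif(1, cfg$gap_len[1], cfg$gap_len[2]) / cfg$interval)
      start <- sample.int(n, 1)
      span <- intersect(start:(start + len - 1), 4:(n - 3))
      if (length(span)) noisy[span] <- NA
    }
  }
  cgm_series(times, noisy, imputed = FALSE, interval = cfg$interval)
}

#' Full synthetic data set for one subject
#'
#' Convenience wrapper: scenario, truth simulation from basal steady state,
#' CGM sampling and gap imputation.
#'
#' @param cfg a [cohort_config()].
#' @param params the subject's true [patient_params()].
#' @param days scenario length, days.
#' @param subject_seed seed for this subject's draws.
#' @return List with `scenario`, `trajectory` (truth, 1-min), `cgm_raw`
#'   (with gaps) and `cgm` (imputed).
#' @export
generate_subject_data <- function(cfg, params, days = 14,
                                  subject_seed = cfg$seed) {
  set.seed(subject_seed)
  scen <- generate_scenario(cfg, params, days)
  traj <- simulate_model(model_state(G = params$Gb), params, scen$truth)
  cgm_raw <- generate_cgm(traj, cfg)
  list(scenario = scen, trajectory = traj, cgm_raw = cgm_raw,
       cgm = impute_gaps(cgm_raw))
}

#' Synthetic glucose rate-of-appearance profile for a meal class
#'
#' Impulse response of the two-compartment gut model with the
#' class-adjusted absorption time: `Ra(t) = Ag D t exp(-t / teff) / teff^2`
#' with `D` the carbohydrate load in mg, so the profile integrates to
#' `Ag * D`.  Emulates an average mixed-meal absorption curve of the given
#' class.
#'
#' @param class absorption class (`"fast"`, `"medium"`, `"slow"`).
#' @param grams carbohydrate load, g.
#' @param params a [patient_params()].
#' @param dt profile resolution, min.
#' @return List of class `ra_profile` with `time` (min), `ra` (mg/min),
#'   `grams`, `meal_class`.
#' @export
make_ra_profile <- function(class, grams, params = patient_params(),
                            dt = 1) {
  if (grams <= 0) stop("grams must be positive", call. = FALSE)
  teff <- effective_tmaxg(params, class)
  horizon <- max(480, ceiling(10 * teff))
  tt <- seq(0, horizon, by = dt)
  ra <- params$Ag * grams * 1000 * tt * exp(-tt / teff) / teff^2
  structure(list(time = tt, ra = ra, grams = grams, meal_class = class),
            class = "ra_profile")
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Classify a meal absorption profile
#'
#' Classifies a glucose rate-of-appearance profile by the fraction of its
#' area under the curve appearing early: fast if more than 60% of the AUC
#' lies within the first 2 h, slow if less than 80% lies within 4 h,
#' medium otherwise.  AUC by the trapezoidal rule.
#'
#' @param profile an [make_ra_profile()] object, or a list/data frame with
#'   `time` (min) and `ra` (mg/min).
#' @return `"fast"`, `"medium"` or `"slow"`.
#' @export
classify_meal <- function(profile) {
  tt <- profile$time; ra <- profile$ra
  total <- .trapz(tt, ra)
  if (!is.finite(total) || total <= 0)
    stop("profile AUC must be positive", call. = FALSE)
  frac_to <- function(h) {
    keep <- tt <= h
    .trapz(tt[keep], ra[keep]) / total
  }
  if (frac_to(120) > 0.60) return("fast")
  if (frac_to(240) < 0.80) return("slow")
  "medium"
}
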