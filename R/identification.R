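#' Mean absolute relative difference (MARD)
#'
#' Mean of `|forecast - observation| / observation`, in percent — the
#' identification objective.
#'
#' @param forecasts,observations paired glucose series, mg/dL;
#'   observations must be positive.
#' @param na.rm drop pairs with missing values.
#' @return MARD, percent.
#' @examples
#' mard(c(110, 90), c(100, 100)) # 10
#' @export
mard <- function(forecasts, observations, na.rm = TRUE) {
  if (length(forecasts) != length(observations))
    stop("forecasts and observations must be paired", call. = FALSE)
  if (na.rm) {
    ok <- !is.na(forecasts) & !is.na(observations)
    forecasts <- forecasts[ok]; observations <- observations[ok]
  }
  if (!length(forecasts)) stop("no matched pairs", call. = FALSE)
  if (any(observations <= 0))
    stop("observations must be positive", call. = FALSE)
  mean(abs(forecasts - observations) / observations) * 100
}

#' Default admissible boxes for the identified parameters
#' @return Named list of `c(lower, upper)` bounds.
#' @export
identification_bounds <- function() {
  list(SI = c(0.001, 0.005), tmaxI = c(50, 140), tmaxG = c(50, 140))
}

#' Identify subject-specific model parameters
#'
#' Estimates insulin sensitivity `SI` and the absorption times `tmaxI`,
#' `tmaxG` by constrained minimisation of the MARD between the forecasts at
#' horizon `ph` and the training CGM series.  All other parameters stay at
#' their population or a priori values.  Fusion weights default to
#' `Q1 = Q2 = 0.5` during identification.
#'
#' The objective surface is start-sensitive, so the optimiser is
#' multistarted: the MARD is evaluated on a 3 x 3 x 3 grid spanning the
#' admissible boxes, and `n_refine` local searches (`L-BFGS-B` on
#' box-normalised coordinates) are polished from the best grid points.
#'
#' @param cgm training [cgm_series()] (gap-free; span >= 1 day).
#' @param schedule training [event_schedule()].
#' @param params a [patient_params()] carrying the fixed parameters and the
#'   subject's a priori `Gb` and `W`.  If `Gb` is `NA`, it is set to the
#'   10th percentile of the overnight (00:00-06:00) training CGM.
#' @param ph prediction horizon to identify for, min.
#' @param config fusion configuration for the identification runs.
#' @param bounds admissible boxes, as [identification_bounds()].
#' @param n_refine number of grid starts polished by the local optimiser.
#' @param control passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return List with the identified `SI`, `tmaxI`, `tmaxG`, the achieved
#'   `mard` (percent), the updated `params`, and the optimiser diagnostics
#'   (`starts`, data frame of grid seeds and their objectives).
#' @export
identify_parameters <- function(cgm, schedule, params, ph = 30,
                                config = forecast_config(q1 = 0.5, q2 = 0.5,
                                                         ph = ph),
                                bounds = identification_bounds(),
                                n_refine = 3,
                                control = list(maxit = 60)) {
  if (diff(range(cgm$time_min)) < 1440)
    warning("training span shorter than one day; ",
            "identified parameters may be poorly constrained")
  config$ph <- as.integer(ph)
  if (is.na(params$Gb)) params$Gb <- estimate_gb(cgm)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)

  objective <- function(theta) {
    # theta in [0,1]^3 (box-normalised)
    v <- unname(lo + theta * (hi - lo))
    p <- params
    p$SI <- v[1]; p$tmaxI <- v[2]; p$tmaxG <- v[3]
    rec <- run_forecaster(cgm, schedule, p, config)
    mard(rec$g_forecast, rec$g_observed)
  }

  grid1 <- c(0, 0.5, 1)
  seeds <- as.matrix(expand.grid(SI = grid1, tmaxI = grid1, tmaxG = grid1))
  seed_obj <- apply(seeds, 1, objective)
  ord <- order(seed_obj)

  best <- list(par = seeds[ord[1], ], value = seed_obj[ord[1]])
  for (s in head(ord, n_refine)) {
    fit <- tryCatch(
      optim(seeds[s, ], objective, method = "L-BFGS-B",
            lower = rep(0, 3), upper = rep(1, 3), control = control),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best$value)
      best <- list(par = fit$par, value = fit$value)
  }
  v <- lo + best$par * (hi - lo)
  params$SI <- v[[1]]; params$tmaxI <- v[[2]]; params$tmaxG <- v[[3]]
  list(SI = v[[1]], tmaxI = v[[2]], tmaxG = v[[3]], mard = best$value,
       params = params, ph = ph,
       starts = data.frame(SI = lo[1] + seeds[, 1] * (hi[1] - lo[1]),
                           tmaxI = lo[2] + seeds[, 2] * (hi[2] - lo[2]),
                           tmaxG = lo[3] + seeds[, 3] * (hi[3] - lo[3]),
                           mard = seed_obj))
}

#' Basal glucose from overnight training data
#'
#' Robust a priori estimate of the basal glucose: the 10th percentile of
#' the overnight (00:00-06:00 clock time) training CGM values, falling back
#' to the 10th percentile of the whole series when no overnight samples
#' exist.
#'
#' @param cgm a [cgm_series()].
#' @return Basal glucose, mg/dL.
#' @export
estimate_gb <- function(cgm) {
  tod <- cgm$time_min %% 1440
  night <- cgm$glucose[tod < 360]
  vals <- if (length(night) >= 12) night else cgm$glucose
  as.numeric(quantile(vals, 0.10, na.rm = TRUE, names = FALSE))
}
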