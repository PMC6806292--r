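#' Forecaster configuration
#'
#' Fusion weights, prediction horizon and behavioural switches of the
#' per-sample forecast cycle.  The population defaults are `Q1 = Q2 = 0.7`
#' for testing; identification uses `Q1 = Q2 = 0.5`.
#'
#' @param q1 gut-state fusion weight in `[0, 1]` (1 = trust deconvolution).
#' @param q2 glucose fusion weight in `[0, 1]` (1 = anchor to CGM).
#' @param ph prediction horizon, min (evaluation uses 30/60/90/120).
#' @param announce_meals use future scheduled meals within the horizon when
#'   propagating the forecast (insulin doses are always used).
#' @param absorption_info apply the per-meal absorption-class adjustment of
#'   the glucose absorption time; `FALSE` treats every meal as medium.
#' @param n_filter moving-average window, samples.
#' @param warmup CGM samples required before the first forecast (3 is the
#'   minimum for the regression derivative).
#' @return A list of class `forecast_config`.
#' @export
forecast_config <- function(q1 = 0.7, q2 = 0.7, ph = 30,
                            announce_meals = TRUE, absorption_info = TRUE,
                            n_filter = 3, warmup = 3) {
  if (q1 < 0 || q1 > 1 || q2 < 0 || q2 > 1)
    stop("fusion weights must lie in [0, 1]", call. = FALSE)
  if (ph < 0) stop("prediction horizon must be non-negative", call. = FALSE)
  if (n_filter < 1) stop("filter window must be >= 1", call. = FALSE)
  structure(list(q1 = q1, q2 = q2, ph = as.integer(ph),
                 announce_meals = isTRUE(announce_meals),
                 absorption_info = isTRUE(absorption_info),
                 n_filter = as.integer(n_filter),
                 warmup = as.integer(warmup)),
            class = "forecast_config")
}

#' Initialise the model state from the first CGM sample
#'
#' @param cgm0 first CGM measurement, mg/dL.
#' @return A [model_state()] with `G = cgm0` and all other states 0.
#' @export
initialize_state <- function(cgm0) {
  if (!is.finite(cgm0) || cgm0 <= 0)
    stop("initial CGM value must be positive", call. = FALSE)
  model_state(G = cgm0)
}

#' Fuse model states with deconvolution estimates and the CGM value
#'
#' Weighted average of the model's gut states with the deconvolution
#' estimates (weight `q1`) and of the model glucose with the CGM measurement
#' (weight `q2`).  The insulin states `X`, `S1`, `S2`, `I` pass through
#' unchanged.
#'
#' @param state current model state ([model_state()]).
#' @param deconv list (or one-row data frame) with `ra_filtered` and `ra1`,
#'   mg/min.
#' @param cgm current CGM measurement, mg/dL.
#' @param config a [forecast_config()].
#' @return The fused state.
#' @export
fuse <- function(state, deconv, cgm, config = forecast_config()) {
  q1 <- config$q1; q2 <- config$q2
  state["G"] <- q2 * cgm + (1 - q2) * state["G"]
  state["Ra"] <- q1 * deconv$ra_filtered + (1 - q1) * state["Ra"]
  state["Ra1"] <- q1 * deconv$ra1 + (1 - q1) * state["Ra1"]
  state
}

# R-level euler on per-minute arrays; mirrors the compiled kernel so the two
# forecaster engines can be compared.
.euler_arr <- function(x, p, ucho, uins, tmaxg, tmaxi, dt = 1) {
  dx <- c(-(p[1] + x[2]) * x[1] + p[1] * p[3] + x[7] / (p[4] * p[6]),
          -p[10] * x[2] + p[10] * p[2] * x[5],
          uins - x[3] / tmaxi,
          (x[3] - x[4]) / tmaxi,
          -p[9] * x[5] + 1000 * x[4] / (p[5] * p[6] * tmaxi),
          -(x[6] - p[11] * ucho) / tmaxg,
          -(x[7] - x[6]) / tmaxg)
  pmax(x + dt * dx, 0)
}

.par_idx <- c(SG = 1, SI = 2, Gb = 3, V = 4, Vi = 5, W = 6, tmaxI = 7,
              tmaxG = 8, ke = 9, p2 = 10, Ag = 11)

#' One per-sample cycle of the forecasting algorithm
#'
#' Executes the cycle run every time a CGM value arrives: advance the model
#' by the elapsed minutes, deconvolve the CGM history into gut-state
#' estimates, fuse, and propagate the fused state over the prediction
#' horizon.  This is the reference R implementation; [run_forecaster()]
#' drives the same cycle in compiled code.
#'
#' @param cycle cycle carrier created by [new_cycle()] (holds the model
#'   state, the CGM and filter history, and the input arrays).
#' @param time,glucose the new CGM sample (min, mg/dL).
#' @return The updated cycle; `cycle$record` holds the forecast record of
#'   this sample (`NULL` during warm-up).
#' @export
step_cycle <- function(cycle, time, glucose) {
  cfg <- cycle$config
  p <- cycle$parvec
  arr <- cycle$arrays
  x <- cycle$state
  i <- length(cycle$t_hist) + 1L
  if (i > 1) {
    t_prev <- cycle$t_hist[i - 1]
    if (time <= t_prev) stop("samples must advance in time", call. = FALSE)
    for (k in t_prev:(time - 1))
      x <- .euler_arr(x, p, arr$ucho[k + 1], arr$uins[k + 1],
                      arr$tmaxg[k + 1], arr$tmaxi[k + 1])
  }
  t_hist <- c(cycle$t_hist, time)
  g_hist <- c(cycle$g_hist, glucose)
  idx <- max(1, i - 2):i
  slope <- bounded_derivative(t_hist[idx], g_hist[idx])
  rhat <- (slope + (p[1] + x[2]) * glucose - p[1] * p[3]) * p[4] * p[6]
  rt_raw <- moving_average(cycle$rt_hist, rhat, cfg$n_filter)
  rt_hist <- c(cycle$rt_hist, rt_raw)
  ra_filt <- max(rt_raw, 0)
  ra1 <- estimate_ra1(t_hist[idx], rt_hist[idx], p[8])
  x <- fuse(stats::setNames(x, .state_names),
            list(ra_filtered = ra_filt, ra1 = ra1), glucose, cfg)
  x <- unname(x)
  record <- NULL
  if (i >= cfg$warmup) {
    xf <- x
    if (cfg$ph > 0)
      for (k in time:(time + cfg$ph - 1))
        xf <- .euler_arr(xf, p,
                         if (cfg$announce_meals) arr$ucho[k + 1] else 0,
                         arr$uins[k + 1], arr$tmaxg[k + 1],
                         arr$tmaxi[k + 1])
    record <- list(time_min = time, g_forecast = xf[1], ph_min = cfg$ph,
                   rhat = rhat, ra_filtered = ra_filt, ra1 = ra1)
  }
  cycle$state <- x
  cycle$t_hist <- t_hist
  cycle$g_hist <- g_hist
  cycle$rt_hist <- rt_hist
  cycle$deconv <- rbind(cycle$deconv,
                        data.frame(time_min = time, ra_raw = rhat,
                                   ra_filtered = ra_filt, ra1 = ra1))
  cycle$record <- record
  cycle
}

#' @rdname step_cycle
#' @param params a [patient_params()] object.
#' @param schedule an [event_schedule()].
#' @param config a [forecast_config()].
#' @param horizon length of the input arrays to prepare, min.
#' @export
new_cycle <- function(params, schedule, config = forecast_config(),
                      horizon = schedule$horizon + config$ph) {
  arr <- schedule_arrays(schedule, params, horizon = horizon,
                         absorption_info = config$absorption_info)
  list(params = params, parvec = .par_vec(params), config = config,
       arrays = arr, state = NULL, t_hist = numeric(), g_hist = numeric(),
       rt_hist = numeric(), deconv = NULL, record = NULL)
}

#' Run the forecasting algorithm over a CGM series
#'
#' Executes the per-sample prediction cycle for every CGM sample: M forward
#' Euler steps of the composite model (M = minutes between samples), gut
#' state estimation by deconvolution of the CGM signal, weighted state
#' fusion, and open-loop propagation over the prediction horizon.
#' Forecasts start once 3 samples are available (regression warm-up).
#'
#' @param cgm a gap-free [cgm_series()] on a regular grid (run
#'   [impute_gaps()] first if the series has gaps).
#' @param schedule the [event_schedule()] of meals and insulin doses.
#' @param params a [patient_params()] object.
#' @param config a [forecast_config()].
#' @param engine `"cpp"` (compiled batch driver, default) or `"r"`
#'   (reference composition of the exported cycle operations).
#' @param details if `TRUE`, also return the deconvolution series and the
#'   fused states.
#' @return A data frame of forecast records: `time_min` (anchor sample),
#'   `g_forecast` (mg/dL at anchor + `ph`), `g_observed` (matched CGM value
#'   when available, else `NA`), `obs_imputed`, `ph_min`.  With
#'   `details = TRUE`, a list with elements `records`, `deconvolution`,
#'   `fused`.
#' @examples
#' p <- patient_params()
#' sched <- event_schedule(horizon = 240)
#' traj <- simulate_model(model_state(G = p$Gb), p, sched)
#' cgm <- cgm_series(seq(0, 240, by = 5), traj$G[seq(1, 241, by = 5)])
#' fc <- run_forecaster(cgm, sched, p, forecast_config(ph = 30))
#' head(fc)
#' @export
run_forecaster <- function(cgm, schedule, params,
                           config = forecast_config(),
                           engine = c("cpp", "r"), details = FALSE) {
  engine <- match.arg(engine)
  validate_params(params)
  if (!nrow(cgm)) stop("empty CGM series", call. = FALSE)
  if (anyNA(cgm$glucose))
    stop("CGM series contains gaps; run impute_gaps() first", call. = FALSE)
  times <- cgm$time_min
  M <- cgm_interval(cgm)
  if (nrow(cgm) > 1 && any(diff(times) != M))
    stop("CGM series is not on a regular ", M,
         "-min grid; run impute_gaps() first", call. = FALSE)
  if (any(times != floor(times)))
    stop("sample times must be whole minutes", call. = FALSE)
  horizon <- max(schedule$horizon, times[length(times)] + config$ph)
  N <- nrow(cgm)

  if (engine == "cpp") {
    arr <- schedule_arrays(schedule, params, horizon = horizon,
                           absorption_info = config$absorption_info)
    res <- .forecaster_core(as.integer(times), cgm$glucose,
                            .par_vec(params), arr$ucho, arr$uins,
                            arr$tmaxg, arr$tmaxi, config$q1, config$q2,
                            config$ph, config$announce_meals,
                            config$n_filter, config$warmup)
    forecast <- res$forecast
    deconv <- data.frame(time_min = times, ra_raw = res$rhat,
                         ra_filtered = res$rtilde, ra1 = res$ra1)
    fused <- res$fused
  } else {
    cyc <- new_cycle(params, schedule, config, horizon = horizon)
    cyc$state <- unname(initialize_state(cgm$glucose[1]))
    forecast <- rep(NA_real_, N)
    fused <- matrix(NA_real_, N, 7)
    for (i in seq_len(N)) {
      cyc <- step_cycle(cyc, times[i], cgm$glucose[i])
      fused[i, ] <- cyc$state
      if (!is.null(cyc$record)) forecast[i] <- cyc$record$g_forecast
    }
    deconv <- cyc$deconv
  }
  colnames(fused) <- .state_names

  keep <- seq_len(N) >= config$warmup
  match_idx <- seq_len(N) + if (config$ph %% M == 0) config$ph / M else NA
  obs <- ifelse(!is.na(match_idx) & match_idx <= N,
                cgm$glucose[pmin(match_idx, N)], NA_real_)
  obs_imp <- ifelse(!is.na(match_idx) & match_idx <= N,
                    cgm$imputed[pmin(match_idx, N)], NA)
  records <- data.frame(time_min = times, g_forecast = forecast,
                        g_observed = obs, obs_imputed = obs_imp,
                        ph_min = config$ph)[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (!details) return(records)
  list(records = records, deconvolution = deconv, fused = fused)
}
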