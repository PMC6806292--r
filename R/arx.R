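#' Fit a third-order ARX glucose forecaster
#'
#' Baseline data-driven forecaster: an autoregressive model of order 3 with
#' exogenous inputs, fitted by ordinary least squares on the 1-step-ahead
#' prediction error.  The exogenous channels are, by default, the insulin
#' and carbohydrate dose trains binned per sampling interval (3 lags each),
#' the standard discrete-time input construction for dosing logs;
#' `filtered_inputs = TRUE` instead uses plasma-insulin and gut-absorption
#' curves obtained by running the event schedule through the composite
#' model's insulin and gut subsystems at population parameters, which hands
#' the baseline the physiological kinetics and makes it a hybrid model
#' rather than a pure ARX.
#'
#' @param cgm a gap-free [cgm_series()] on a regular grid.
#' @param schedule the matching [event_schedule()].
#' @param params population [patient_params()] used to build the filtered
#'   exogenous channels.
#' @param order autoregressive (and exogenous) order.
#' @param filtered_inputs use physiologically filtered exogenous channels
#'   instead of binned dose trains.
#' @return An object of class `arx_model`: coefficients, order, sampling
#'   interval and fitting metadata.
#' @export
fit_arx <- function(cgm, schedule, params = patient_params(),
                    order = 3, filtered_inputs = FALSE) {
  if (anyNA(cgm$glucose))
    stop("CGM series contains gaps; run impute_gaps() first", call. = FALSE)
  M <- cgm_interval(cgm)
  if (any(diff(cgm$time_min) != M))
    stop("CGM series must be on a regular grid", call. = FALSE)
  y <- cgm$glucose
  N <- length(y)
  exo <- .arx_channels(cgm$time_min, schedule, params,
                       filtered_inputs, M)
  npar <- 1 + order * (1 + ncol(exo))
  if (N - order < 10 * npar)
    warning("fewer than 10 samples per ARX parameter; ",
            "coefficients may be unstable")
  rows <- (order + 1):N
  Xmat <- matrix(NA_real_, length(rows), npar - 1)
  k <- 0
  for (lag in seq_len(order)) {
    k <- k + 1; Xmat[, k] <- y[rows - lag]
  }
  for (j in seq_len(ncol(exo))) for (lag in seq_len(order)) {
    k <- k + 1; Xmat[, k] <- exo[rows - lag, j]
  }
  fit <- lm.fit(cbind(1, Xmat), y[rows])
  if (fit$rank < npar)
    stop("rank-deficient ARX regression (constant inputs?)", call. = FALSE)
  structure(list(coef = fit$coefficients, order = order, interval = M,
                 filtered_inputs = filtered_inputs, params = params,
                 residuals = fit$residuals,
                 exo_names = colnames(exo)),
            class = "arx_model")
}

# Exogenous channels sampled at the CGM times: either the dose trains
# binned per sampling interval (each sample carries the doses delivered
# since the previous sample), or the composite model's plasma insulin and
# Ra responses to the schedule (population parameters).
.arx_channels <- function(times, schedule, params, filtered_inputs, M) {
  horizon <- max(schedule$horizon, max(times) + 1)
  arr <- schedule_arrays(schedule, params, horizon = horizon)
  if (!filtered_inputs) {
    csi <- cumsum(arr$uins); csc <- cumsum(arr$ucho)
    binsum <- function(cs, t) {
      prev <- cs[pmax(t - M + 1, 1)]
      prev[t - M < 0] <- 0
      cs[t + 1] - prev
    }
    return(cbind(ins = binsum(csi, times), cho = binsum(csc, times)))
  }
  x0 <- c(1e-12, 0, 0, 0, 0, 0, 0)  # glucose feedback unused by I and Ra
  traj <- .sim_core(x0, .par_vec(params), arr$ucho, arr$uins,
                    arr$tmaxg, arr$tmaxi, 1)
  cbind(ins = traj[times + 1, 5], cho = traj[times + 1, 7])
}

#' @export
print.arx_model <- function(x, ...) {
  cat(sprintf("ARX(%d) model, %g-min sampling, %s exogenous inputs\n",
              x$order, x$interval,
              if (x$filtered_inputs) "filtered" else "binned-dose"))
  print(signif(x$coef, 4))
  invisible(x)
}

#' Multi-step ARX forecast
#'
#' Iterates the fitted one-step model `ph / M` times, feeding predictions
#' back as autoregressive lags; future exogenous inputs are taken from the
#' schedule (announced meals and doses).
#'
#' @param model an [fit_arx()] model.
#' @param cgm CGM history ([cgm_series()], regular grid).
#' @param schedule the [event_schedule()] (must cover the horizon).
#' @param ph prediction horizon, min; must be a positive multiple of the
#'   sampling interval.
#' @return Data frame of forecast records as in [run_forecaster()].
#' @export
predict_arx <- function(model, cgm, schedule, ph = 30) {
  M <- model$interval
  if (ph %% M != 0 || ph <= 0)
    stop("ph must be a positive multiple of the sampling interval",
         call. = FALSE)
  if (nrow(cgm) < model$order)
    stop("need at least `order` history samples", call. = FALSE)
  times <- cgm$time_min
  y <- cgm$glucose
  N <- length(y)
  steps <- ph %/% M
  horizon <- max(schedule$horizon, max(times) + ph + 1)
  exo_times <- seq(min(times), max(times) + ph, by = M)
  exo <- .arx_channels(exo_times, schedule, model$params,
                       model$filtered_inputs, M)
  ord <- model$order
  cf <- model$coef
  forecast <- rep(NA_real_, N)
  for (i in ord:N) {
    lags <- y[i:(i - ord + 1)]
    for (s in seq_len(steps)) {
      pos <- i + s  # index into exo_times
      v <- cf[1] + sum(cf[2:(ord + 1)] * lags)
      k <- ord + 1
      for (j in seq_len(ncol(exo))) {
        ch <- exo[(pos - 1):(pos - ord), j]
        v <- v + sum(cf[(k + 1):(k + ord)] * ch)
        k <- k + ord
      }
      lags <- c(v, lags[-ord])
    }
    forecast[i] <- v
  }
  match_idx <- seq_len(N) + steps
  obs <- ifelse(match_idx <= N, y[pmin(match_idx, N)], NA_real_)
  out <- data.frame(time_min = times, g_forecast = forecast,
                    g_observed = obs,
                    obs_imputed = ifelse(match_idx <= N,
                                         cgm$imputed[pmin(match_idx, N)],
                                         NA),
                    ph_min = ph)[ord:N, , drop = FALSE]
  rownames(out) <- NULL
  out
}
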