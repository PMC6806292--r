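#' Bounded regression derivative of the CGM signal
#'
#' Slope of the ordinary-least-squares regression of (up to) three
#' consecutive glucose values against their timestamps, clipped to
#' +/- 1 mg/dL per min to limit the influence of sensor noise.  During
#' start-up, two samples fall back to the two-point difference and a single
#' sample yields 0.
#'
#' @param times sample times, min (distinct, at most 3 used).
#' @param values glucose values, mg/dL.
#' @param bound derivative bound, mg/dL per min.
#' @return Clipped slope, mg/dL per min.
#' @examples
#' bounded_derivative(c(0, 5, 10), c(100, 110, 125)) # OLS slope 2.5 -> 1
#' @export
bounded_derivative <- function(times, values, bound = 1) {
  n <- length(times)
  if (length(values) != n) stop("times/values length mismatch", call. = FALSE)
  if (anyDuplicated(times)) stop("duplicate timestamps", call. = FALSE)
  if (n > 3) {
    times <- tail(times, 3); values <- tail(values, 3); n <- 3
  }
  slope <- if (n < 2) 0 else .ols_slope(times, values)
  min(max(slope, -bound), bound)
}

.ols_slope <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  sum((t - tm) * (y - ym)) / sum((t - tm)^2)
}

#' Raw glucose rate of appearance by deconvolution
#'
#' Inverts the glucose-disappearance equation at one CGM sample: given the
#' CGM value, its bounded derivative and the model's current insulin action,
#' solves for the glucose rate of appearance that would produce the observed
#' excursion.  The raw estimate may be negative; flooring happens after
#' filtering.
#'
#' @param cgm_value CGM glucose, mg/dL.
#' @param cgm_slope bounded CGM derivative, mg/dL per min.
#' @param X current insulin action, 1/min.
#' @param params a [patient_params()] object.
#' @return Raw rate-of-appearance estimate, mg/min.
#' @examples
#' p <- patient_params(SG = 0.02, Gb = 120, V = 0.9, W = 70)
#' estimate_ra(150, 1, 0, p) # (1 + 0.02*150 - 0.02*120) * 63 = 100.8
#' @export
estimate_ra <- function(cgm_value, cgm_slope, X, params) {
  if (!all(is.finite(c(cgm_value, cgm_slope, X))))
    stop("non-finite input", call. = FALSE)
  (cgm_slope + (params$SG + X) * cgm_value - params$SG * params$Gb) *
    params$V * params$W
}

#' Recursive moving-average filter
#'
#' One update of the rate-of-appearance filter: the current raw estimate is
#' averaged with the previous `n - 1` *filtered* values (a recursive, not
#' FIR, filter).  Missing history at start-up counts as 0.
#'
#' @param prev_filtered previous filtered values, most recent last; only the
#'   last `n - 1` are used, shorter history is zero-padded.
#' @param raw current raw estimate, mg/min.
#' @param n window length in samples (default 3).
#' @return Current filtered value, mg/min (unfloored).
#' @examples
#' moving_average(c(0, 0), 30) # 10
#' @export
moving_average <- function(prev_filtered, raw, n = 3) {
  if (n < 1) stop("window length must be >= 1", call. = FALSE)
  hist <- tail(prev_filtered, n - 1)
  (sum(hist) + raw) / n
}

#' First gut compartment from the filtered rate of appearance
#'
#' Reconstructs the first gut compartment by inverting the second gut
#' equation: the regression derivative of (up to) three consecutive filtered
#' values times `tmaxG`, plus the current filtered value; floored at 0.
#'
#' @param times sample times of the filtered values, min.
#' @param filtered filtered rate-of-appearance values, mg/min (most recent
#'   last; at most 3 used).
#' @param tmaxG time-to-maximum glucose absorption, min.
#' @return First-compartment estimate, mg/min (non-negative).
#' @examples
#' estimate_ra1(c(0, 5, 10), c(10, 20, 30), 85) # 2 * 85 + 30 = 200
#' @export
estimate_ra1 <- function(times, filtered, tmaxG) {
  n <- length(times)
  if (n > 3) { times <- tail(times, 3); filtered <- tail(filtered, 3); n <- 3 }
  slope <- if (n < 2) 0 else .ols_slope(times, filtered)
  max(slope * tmaxG + filtered[n], 0)
}

#' Deconvolve a CGM series into gut-state estimates
#'
#' Runs the full per-sample forecast cycle over a CGM series and returns the
#' deconvolution by-products: the raw rate-of-appearance estimate, its
#' filtered version, and the reconstructed first gut compartment at every
#' sample.  The model propagation supplies the insulin-action state the
#' deconvolution needs, so the event schedule (insulin doses) must be given.
#'
#' @inheritParams run_forecaster
#' @return A data frame with columns `time_min`, `ra_raw`, `ra_filtered`,
#'   `ra1` (mg/min).
#' @export
deconvolve_cgm <- function(cgm, schedule, params,
                           config = forecast_config()) {
  res <- run_forecaster(cgm, schedule, params, config, details = TRUE)
  res$deconvolution
}
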