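#' Root mean square error of matched forecast pairs
#'
#' @param forecasts,observations paired glucose series, mg/dL.
#' @param na.rm drop unmatched pairs.
#' @return RMSE, mg/dL.
#' @examples
#' rmse(c(110, 120), c(100, 100)) # sqrt(250)
#' @export
rmse <- function(forecasts, observations, na.rm = TRUE) {
  if (length(forecasts) != length(observations))
    stop("forecasts and observations must be paired", call. = FALSE)
  if (na.rm) {
    ok <- !is.na(forecasts) & !is.na(observations)
    forecasts <- forecasts[ok]; observations <- observations[ok]
  }
  if (!length(forecasts)) stop("no matched pairs", call. = FALSE)
  sqrt(mean((forecasts - observations)^2))
}

#' Error-grid region of one forecast/observation pair
#'
#' Rule-based error-grid analysis: region A holds accurate predictions
#' (deviation within 20% of the observation, or both values hypoglycaemic,
#' i.e. <= 70 mg/dL); E holds dangerous confusions of hypo- and
#' hyperglycaemia; C large underestimates (forecast at least 100 mg/dL
#' below the observation, or predicted hypoglycaemia while the observation
#' is 130-180 mg/dL); D in-target forecasts while the observation is out of
#' target (70-180 mg/dL); B is the benign remainder.  Overlapping rules are
#' resolved with precedence A, E, D, C, B, so an in-target forecast with an
#' out-of-target observation is always a detection failure (D) even when it
#' also lies more than 100 mg/dL below the observation.
#'
#' @param forecast,observation glucose values, mg/dL (vectorised).
#' @return Factor with levels `A`-`E`.
#' @examples
#' ega_region(c(100, 60, 65, 60, 100), c(100, 60, 150, 200, 220))
#' @export
ega_region <- function(forecast, observation) {
  if (any(forecast <= 0 | observation <= 0, na.rm = TRUE))
    stop("glucose values must be positive", call. = FALSE)
  n <- max(length(forecast), length(observation))
  forecast <- rep_len(forecast, n); observation <- rep_len(observation, n)
  a <- abs(forecast - observation) <= 0.2 * observation |
    (forecast <= 70 & observation <= 70)
  e <- (forecast <= 70 & observation >= 180) |
    (forecast >= 180 & observation <= 70)
  cc <- forecast <= observation - 100 |
    (forecast <= 70 & observation >= 130 & observation <= 180)
  d <- forecast >= 70 & forecast <= 180 &
    (observation < 70 | observation > 180)
  out <- rep("B", n)
  out[cc] <- "C"; out[d] <- "D"; out[e] <- "E"; out[a] <- "A"
  factor(out, levels = c("A", "B", "C", "D", "E"))
}

#' Error-grid region percentages of a forecast record set
#'
#' @param records forecast records (data frame with `g_forecast`,
#'   `g_observed`), or two vectors via `observations`.
#' @param observations optional observation vector when `records` is a
#'   forecast vector.
#' @return Named numeric vector of percentages A-E (summing to 100).
#' @export
ega_summary <- function(records, observations = NULL) {
  if (is.null(observations)) {
    f <- records$g_forecast; o <- records$g_observed
  } else {
    f <- records; o <- observations
  }
  ok <- !is.na(f) & !is.na(o)
  if (!any(ok)) stop("no matched pairs", call. = FALSE)
  tab <- table(ega_region(f[ok], o[ok]))
  stats::setNames(100 * as.numeric(tab) / sum(tab), names(tab))
}

#' Detect hypoglycaemic events in a glucose series
#'
#' A hypoglycaemic event is a maximal run of at least 3 consecutive samples
#' below 70 mg/dL.
#'
#' @param glucose glucose series on the regular sampling grid, mg/dL.
#' @param threshold hypoglycaemia threshold, mg/dL.
#' @param min_run minimum run length, samples.
#' @return Data frame with one row per event: `start`, `end` (sample
#'   indices, inclusive) and `length`.
#' @examples
#' detect_hypo_events(c(100, 65, 64, 63, 80)) # one event, samples 2-4
#' @export
detect_hypo_events <- function(glucose, threshold = 70, min_run = 3) {
  below <- !is.na(glucose) & glucose < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# indicator vector: inside any detected event
.in_event <- function(glucose, n, threshold, min_run) {
  ev <- detect_hypo_events(glucose, threshold, min_run)
  ind <- rep(FALSE, n)
  for (i in seq_len(nrow(ev))) ind[ev$start[i]:ev$end[i]] <- TRUE
  ind
}

#' Hypoglycaemia prediction confusion counts
#'
#' Compares hypoglycaemic events detected in the forecast series against
#' events in the observed series.  With `level = "sample"` (default) each
#' time-aligned sample pair is scored by its in-event indicators; with
#' `level = "event"` any overlap between a predicted and an observed event
#' counts as one true positive, unmatched events as false
#' positives/negatives, and event-free samples as one true negative each.
#'
#' @param forecasts,observations time-aligned glucose series, mg/dL.
#' @param level matching granularity, `"sample"` or `"event"`.
#' @param threshold,min_run event definition (see [detect_hypo_events()]).
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
hypo_confusion <- function(forecasts, observations, level = c("sample",
                                                              "event"),
                           threshold = 70, min_run = 3) {
  level <- match.arg(level)
  if (length(forecasts) != length(observations))
    stop("forecast and observation series must be time-aligned",
         call. = FALSE)
  ok <- !is.na(forecasts) & !is.na(observations)
  f <- forecasts; f[!ok] <- NA
  o <- observations; o[!ok] <- NA
  n <- length(f)
  pred <- .in_event(f, n, threshold, min_run)
  act <- .in_event(o, n, threshold, min_run)
  if (level == "sample") {
    pred <- pred[ok]; act <- act[ok]
    return(c(TP = sum(pred & act), FP = sum(pred & !act),
             TN = sum(!pred & !act), FN = sum(!pred & act)))
  }
  pe <- detect_hypo_events(f, threshold, min_run)
  oe <- detect_hypo_events(o, threshold, min_run)
  overlap <- function(a, b) a$start <= b$end & a$end >= b$start
  tp <- 0; matched_obs <- rep(FALSE, nrow(oe))
  for (i in seq_len(nrow(pe))) {
    hits <- which(overlap(pe[i, ], oe))
    if (length(hits)) { tp <- tp + 1; matched_obs[hits] <- TRUE }
  }
  fp <- nrow(pe) - tp
  fn <- sum(!matched_obs)
  tn <- sum(!pred & !act & ok)
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Matthews correlation coefficient
#'
#' Balanced score of binary event prediction; 0 is returned when any
#' marginal total is zero (the standard degenerate-case convention).
#'
#' @param TP,TN,FP,FN confusion counts, or a named vector as first
#'   argument.
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(TP = 6, TN = 9, FP = 1, FN = 2) # 52 / sqrt(6160)
#' @export
mcc <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.null(TN) && length(TP) == 4) {
    v <- TP; TP <- v[["TP"]]; TN <- v[["TN"]]
    FP <- v[["FP"]]; FN <- v[["FN"]]
  }
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative",
                                       call. = FALSE)
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Full metrics report for a set of forecast records
#'
#' @param records forecast records from [run_forecaster()] or
#'   [predict_arx()].
#' @param level hypoglycaemia matching granularity (see
#'   [hypo_confusion()]).
#' @return A list of class `metrics_report`: `rmse`, `mard`, `ega`
#'   (percentages A-E), `confusion`, `mcc`, `ph`, `n`.
#' @export
metrics_report <- function(records, level = "sample") {
  ok <- !is.na(records$g_forecast) & !is.na(records$g_observed)
  rec <- records[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no matched pairs", call. = FALSE)
  conf <- hypo_confusion(rec$g_forecast, rec$g_observed, level = level)
  structure(list(rmse = rmse(rec$g_forecast, rec$g_observed),
                 mard = mard(rec$g_forecast, rec$g_observed),
                 ega = ega_summary(rec),
                 confusion = conf,
                 mcc = mcc(conf),
                 ph = rec$ph_min[1], n = nrow(rec)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Forecast metrics (PH = %d min, N = %d pairs)\n", x$ph, x$n))
  cat(sprintf("  RMSE %.2f mg/dL   MARD %.2f %%   MCC %.3f\n",
              x$rmse, x$mard, x$mcc))
  cat("  EGA %:", paste(sprintf("%s=%.1f", names(x$ega), x$ega),
                        collapse = " "), "\n")
  invisible(x)
}
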