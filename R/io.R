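#' Read / write CGM CSV files
#'
#' CGM files are comma-separated with a mandatory header and columns
#' `time_min`, `glucose_mgdl` and optional `imputed` (0/1).  Values outside
#' 20-600 mg/dL and non-increasing timestamps are rejected with the
#' offending row number.
#'
#' @param path file path.
#' @param cgm a [cgm_series()] (for writing).
#' @return [read_cgm_csv()] returns a [cgm_series()].
#' @export
read_cgm_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "glucose_mgdl")
  if (!all(need %in% names(df)))
    stop("CGM file must have columns time_min, glucose_mgdl", call. = FALSE)
  if (anyNA(df$time_min))
    stop("malformed time_min at row(s) ",
         paste(head(which(is.na(df$time_min)), 5), collapse = ", "),
         call. = FALSE)
  dup <- which(diff(df$time_min) <= 0)
  if (length(dup))
    stop("non-increasing timestamps at row(s) ",
         paste(head(dup + 1, 5), collapse = ", "), call. = FALSE)
  bad <- which(!is.na(df$glucose_mgdl) &
                 (df$glucose_mgdl < 20 | df$glucose_mgdl > 600))
  if (length(bad))
    stop("glucose outside [20, 600] mg/dL at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  imputed <- if ("imputed" %in% names(df)) as.logical(df$imputed) else FALSE
  cgm_series(df$time_min, df$glucose_mgdl, imputed)
}

#' @rdname read_cgm_csv
#' @export
write_cgm_csv <- function(cgm, path) {
  write.csv(data.frame(time_min = cgm$time_min,
                       glucose_mgdl = cgm$glucose,
                       imputed = as.integer(cgm$imputed)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Meal-class default when the log carries no composition information:
# lunch- and dinner-time meals (11:00-21:00) are medium absorption,
# breakfast and snacks fast.
.default_meal_class <- function(time_min) {
  tod <- time_min %% 1440
  ifelse(tod >= 660 & tod < 1260, "medium", "fast")
}

#' Read / write event CSV files
#'
#' Event files are comma-separated with a mandatory header and columns
#' `time_min`, `type` (`meal`/`bolus`/`basal`), `value` (grams, units or
#' units/h) and `abs_class` (meal absorption class; blank entries default
#' by clock time: breakfast and snacks fast, lunch and dinner medium).
#'
#' @param path file path.
#' @param schedule an [event_schedule()] (for writing).
#' @param horizon schedule horizon, min; defaults to the last event time
#'   rounded up to a whole day.
#' @return [read_events_csv()] returns an [event_schedule()].
#' @export
read_events_csv <- function(path, horizon = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "type", "value")
  if (!all(need %in% names(df)))
    stop("event file must have columns time_min, type, value",
         call. = FALSE)
  bad_type <- which(!df$type %in% c("meal", "bolus", "basal"))
  if (length(bad_type))
    stop("unknown event type at row(s) ",
         paste(head(bad_type, 5), collapse = ", "), call. = FALSE)
  bad_val <- which(is.na(df$value) | df$value < 0)
  if (length(bad_val))
    stop("negative or missing value at row(s) ",
         paste(head(bad_val, 5), collapse = ", "), call. = FALSE)
  if (is.null(horizon))
    horizon <- max(1440, ceiling(max(df$time_min) / 1440) * 1440)
  m <- df[df$type == "meal", , drop = FALSE]
  cls <- if ("abs_class" %in% names(df)) as.character(m$abs_class)
         else rep(NA_character_, nrow(m))
  blank <- is.na(cls) | !nzchar(trimws(cls))
  cls[blank] <- .default_meal_class(m$time_min[blank])
  b <- df[df$type == "bolus", , drop = FALSE]
  bs <- df[df$type == "basal", , drop = FALSE]
  event_schedule(
    meals = if (nrow(m)) data.frame(time_min = m$time_min,
                                    grams = m$value, class = cls),
    boluses = if (nrow(b)) data.frame(time_min = b$time_min,
                                      units = b$value),
    basal = if (nrow(bs)) data.frame(time_min = bs$time_min,
                                     rate_Uh = bs$value),
    horizon = horizon)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(schedule, path) {
  m <- schedule$meals; b <- schedule$boluses; bs <- schedule$basal
  df <- rbind(
    if (nrow(m)) data.frame(time_min = m$time_min, type = "meal",
                            value = m$grams, abs_class = m$class),
    if (nrow(b)) data.frame(time_min = b$time_min, type = "bolus",
                            value = b$units, abs_class = ""),
    if (nrow(bs)) data.frame(time_min = bs$time_min, type = "basal",
                             value = bs$rate_Uh, abs_class = ""))
  df <- df[order(df$time_min), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write forecast records or a metrics report
#'
#' @param records forecast records (data frame).
#' @param report a [metrics_report()].
#' @param path output path.
#' @export
write_forecasts_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forecasts_csv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
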