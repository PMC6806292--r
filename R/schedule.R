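#' Exogenous event schedule: meals, boluses, basal insulin
#'
#' Collects the time-indexed exogenous inputs of a scenario on a 1-min grid:
#' discrete carbohydrate intakes (grams, with an absorption class), discrete
#' insulin boluses (units) and a piecewise-constant basal rate (units/h).
#' Meals and boluses are delivered as single 1-min impulses (1 g -> 1000
#' mg/min for one minute; 1 U -> 1000 mU/min for one minute).
#'
#' Meals may carry optional `ag_mult` / `tmaxg_mult` columns used by the
#' virtual-patient generator to perturb per-meal bioavailability and
#' absorption rate of the simulated truth; they default to 1.
#'
#' @param meals data frame with columns `time_min`, `grams`, `class`
#'   (`"fast"`, `"medium"`, `"slow"`).
#' @param boluses data frame with columns `time_min`, `units`.
#' @param basal data frame with columns `time_min`, `rate_Uh`; each rate
#'   holds from its `time_min` until the next row (piecewise constant).
#' @param horizon scenario length, min.
#' @param tmaxi_mult optional data frame (`time_min`, `mult`) of
#'   piecewise-constant multipliers on the insulin absorption time, used to
#'   emulate intra-subject variability of insulin absorption.
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(meals = NULL, boluses = NULL, basal = NULL,
                           horizon = 1440, tmaxi_mult = NULL) {
  empty_meals <- data.frame(time_min = numeric(), grams = numeric(),
                            class = character())
  meals <- if (is.null(meals) || !nrow(meals)) empty_meals else meals
  boluses <- if (is.null(boluses) || !nrow(boluses))
    data.frame(time_min = numeric(), units = numeric()) else boluses
  basal <- if (is.null(basal) || !nrow(basal))
    data.frame(time_min = numeric(), rate_Uh = numeric()) else basal
  if (horizon < 1) stop("horizon must be at least 1 min", call. = FALSE)
  if (nrow(meals)) {
    meals$class <- match.arg(as.character(meals$class),
                             c("fast", "medium", "slow"),
                             several.ok = TRUE)
    if (is.null(meals$ag_mult)) meals$ag_mult <- 1
    if (is.null(meals$tmaxg_mult)) meals$tmaxg_mult <- 1
    meals <- meals[order(meals$time_min), , drop = FALSE]
  }
  ev_times <- c(meals$time_min, boluses$time_min, basal$time_min)
  if (length(ev_times) && (any(ev_times < 0) || any(ev_times > horizon)))
    stop("event times must lie within [0, horizon]", call. = FALSE)
  if (any(meals$grams < 0) || any(boluses$units < 0) ||
      any(basal$rate_Uh < 0))
    stop("grams, units and basal rates must be non-negative", call. = FALSE)
  structure(list(meals = meals, boluses = boluses, basal = basal,
                 horizon = horizon, tmaxi_mult = tmaxi_mult),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Event schedule over %d min: %d meal(s), %d bolus(es), %d basal segment(s)\n",
              x$horizon, nrow(x$meals), nrow(x$boluses), nrow(x$basal)))
  invisible(x)
}

# Per-minute input arrays over [0, horizon): uCHO (mg/min), uINS (mU/min),
# effective tmaxG and tmaxI (min).  Minute k of the arrays covers
# [k-1, k) in scenario time (1-based R indexing).
# A meal's class (and per-meal kinetics perturbation) applies from its start
# until 8 h later or the next meal, whichever comes first; when meals
# overlap in that sense with different classes the later meal wins.
schedule_arrays <- function(schedule, params, horizon = schedule$horizon,
                            absorption_info = TRUE) {
  n <- as.integer(horizon)
  ucho <- numeric(n)
  uins <- numeric(n)
  tmaxg <- rep(params$tmaxG, n)
  tmaxi <- rep(params$tmaxI, n)

  m <- schedule$meals
  if (nrow(m)) {
    cls_prev_end <- -Inf
    n_overlap <- 0L
    for (i in seq_len(nrow(m))) {
      idx <- floor(m$time_min[i]) + 1L
      if (idx >= 1 && idx <= n)
        ucho[idx] <- ucho[idx] + m$grams[i] * 1000 * m$ag_mult[i]
      cls <- if (absorption_info) m$class[i] else "medium"
      from <- idx
      until <- min(idx + 480L - 1L,
                   if (i < nrow(m)) floor(m$time_min[i + 1]) else n, n)
      if (i > 1 && from <= cls_prev_end && m$class[i] != m$class[i - 1])
        n_overlap <- n_overlap + 1L
      if (from <= until) {
        val <- max(effective_tmaxg(params, cls) * m$tmaxg_mult[i], 5)
        tmaxg[from:until] <- val
      }
      cls_prev_end <- idx + 480L - 1L
    }
    if (n_overlap > 0 && isTRUE(getOption("glucast.verbose", FALSE)))
      message(n_overlap, " meal(s) start inside an earlier meal's ",
              "absorption window with a different class; the later ",
              "meal's class wins from its start time")
  }
  b <- schedule$boluses
  if (nrow(b)) for (i in seq_len(nrow(b))) {
    idx <- floor(b$time_min[i]) + 1L
    if (idx >= 1 && idx <= n) uins[idx] <- uins[idx] + b$units[i] * 1000
  }
  bs <- schedule$basal
  if (nrow(bs)) {
    bs <- bs[order(bs$time_min), , drop = FALSE]
    for (i in seq_len(nrow(bs))) {
      from <- floor(bs$time_min[i]) + 1L
      until <- if (i < nrow(bs)) floor(bs$time_min[i + 1]) else n
      if (from <= until)
        uins[from:until] <- uins[from:until] + bs$rate_Uh[i] * 1000 / 60
    }
  }
  tm <- schedule$tmaxi_mult
  if (!is.null(tm) && nrow(tm)) {
    tm <- tm[order(tm$time_min), , drop = FALSE]
    for (i in seq_len(nrow(tm))) {
      from <- floor(tm$time_min[i]) + 1L
      until <- if (i < nrow(tm)) floor(tm$time_min[i + 1]) else n
      if (from <= until) tmaxi[from:until] <- params$tmaxI * tm$mult[i]
    }
  }
  list(ucho = ucho, uins = uins, tmaxg = tmaxg, tmaxi = tmaxi)
}
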