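#' Cohort benchmark: physiological forecaster vs ARX baseline
#'
#' Generates (or accepts) a virtual cohort, splits each subject's scenario
#' into an identification week and a testing week, identifies the
#' subject-specific parameters on the first week, forecasts the second week
#' with the requested methods at each prediction horizon, and reports the
#' evaluation metrics per subject together with cohort mean +/- SD rows.
#'
#' Methods: `"pm"` — physiological forecaster without meal-absorption
#' information (all meals medium); `"pmma"` — with per-meal absorption
#' classes; `"arx"` — third-order ARX baseline.
#'
#' @param cfg a [cohort_config()]; its seed drives everything.
#' @param days scenario length, days (split in half for train/test).
#' @param ph_list prediction horizons, min.
#' @param methods subset of `c("pm", "pmma", "arx")`.
#' @param identify_ph `NULL` to identify parameters per prediction horizon
#'   (the identification protocol used for the reported results), or a
#'   single horizon whose identified parameters are shared across
#'   `ph_list`.
#' @param q_test fusion weights used for testing (identification always
#'   uses 0.5).
#' @param progress print per-subject progress lines.
#' @return A list of class `benchmark_result`: `per_subject` (one row per
#'   subject x method x PH), `summary` (cohort mean and SD per method x
#'   PH), `cohort` (the sampled parameter sets) and `identified` (per
#'   subject/PH identification results).
#' @export
run_benchmark <- function(cfg, days = 14,
                          ph_list = c(30, 60, 90, 120),
                          methods = c("pm", "pmma", "arx"),
                          identify_ph = NULL, q_test = 0.7,
                          progress = interactive()) {
  methods <- match.arg(methods, several.ok = TRUE)
  cohort <- sample_cohort(cfg)
  split_min <- floor(days / 2) * 1440
  rows <- list(); ident_log <- list()

  for (s in seq_along(cohort)) {
    truth <- cohort[[s]]
    dat <- generate_subject_data(cfg, truth, days,
                                 subject_seed = cfg$seed + 1000 * s)
    cgm <- dat$cgm
    train <- cgm[cgm$time_min < split_min, , drop = FALSE]
    test <- cgm[cgm$time_min >= split_min, , drop = FALSE]
    if (!nrow(train) || !nrow(test))
      stop("train/test split is empty; increase `days`", call. = FALSE)
    sched <- dat$scenario$logged

    # a priori subject information (weight and basal glucose are known per
    # subject, as in the identification protocol)
    prior <- cfg$base
    prior$W <- truth$W
    prior$Gb <- truth$Gb

    id_phs <- if (is.null(identify_ph)) ph_list else identify_ph
    idents <- lapply(id_phs, function(ph)
      identify_parameters(train, sched, prior, ph = ph))
    names(idents) <- as.character(id_phs)
    ident_log[[s]] <- idents

    arx <- if ("arx" %in% methods) fit_arx(train, sched, cfg$base)
    for (ph in ph_list) {
      id <- if (is.null(identify_ph)) idents[[as.character(ph)]]
            else idents[[1]]
      for (m in methods) {
        rec <- switch(m,
          pm = run_forecaster(test, sched, id$params,
                              forecast_config(q1 = q_test, q2 = q_test,
                                              ph = ph,
                                              absorption_info = FALSE)),
          pmma = run_forecaster(test, sched, id$params,
                                forecast_config(q1 = q_test, q2 = q_test,
                                                ph = ph)),
          arx = predict_arx(arx, test, sched, ph = ph))
        rep <- metrics_report(rec)
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, method = m, ph = ph, rmse = rep$rmse,
          mard = rep$mard, ega_A = rep$ega[["A"]], ega_B = rep$ega[["B"]],
          ega_C = rep$ega[["C"]], ega_D = rep$ega[["D"]],
          ega_E = rep$ega[["E"]], mcc = rep$mcc, n = rep$n)
      }
    }
    if (progress)
      message(sprintf("subject %d/%d done", s, length(cohort)))
  }
  per_subject <- do.call(rbind, rows)
  metric_cols <- c("rmse", "mard", "ega_A", "ega_B", "ega_C", "ega_D",
                   "ega_E", "mcc")
  agg <- function(f, tag) {
    out <- stats::aggregate(per_subject[metric_cols],
                            per_subject[c("method", "ph")], f)
    out$stat <- tag
    out
  }
  summary <- rbind(agg(mean, "mean"), agg(sd, "sd"))
  summary <- summary[order(summary$ph, summary$method, summary$stat), ]
  rownames(summary) <- NULL
  structure(list(per_subject = per_subject, summary = summary,
                 cohort = cohort, identified = ident_log),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Cohort benchmark (", length(x$cohort), " subjects)\n", sep = "")
  m <- x$summary[x$summary$stat == "mean",
                 c("method", "ph", "rmse", "ega_A", "mcc")]
  print(transform(m, rmse = round(rmse, 2), ega_A = round(ega_A, 1),
                  mcc = round(mcc, 3)), row.names = FALSE)
  invisible(x)
}
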