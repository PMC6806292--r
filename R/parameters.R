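#' Patient parameters for the composite glucose-insulin model
#'
#' Constructs and validates the full parameter set of the composite minimal
#' model: the Bergman glucose-disappearance parameters, the Hovorka-type
#' subcutaneous insulin and gut absorption constants, and the fast/slow meal
#' shifts applied to the time-to-maximum glucose absorption.
#'
#' Defaults are the fixed population values used by the forecasting
#' algorithm; `SI`, `tmaxI` and `tmaxG` are the subject-specific parameters
#' normally obtained by [identify_parameters()], and `Gb`/`W` come from a
#' priori subject information.
#'
#' @param SG fractional glucose effectiveness, 1/min.
#' @param SI insulin sensitivity, 1/min per uU/mL; admissible box
#'   `[0.001, 0.005]`.
#' @param Gb basal glucose, mg/dL.
#' @param V glucose distribution volume, dL/kg.
#' @param Vi insulin distribution volume, mL/kg.
#' @param W body weight, kg.
#' @param tmaxI time-to-maximum insulin absorption, min; box `[50, 140]`.
#' @param tmaxG time-to-maximum glucose appearance, min; box `[50, 140]`.
#' @param ke plasma insulin decay rate, 1/min.
#' @param p2 insulin action rate, 1/min.
#' @param Ag carbohydrate bioavailability, in (0, 1].
#' @param tl fast-meal shift subtracted from `tmaxG`, min.
#' @param td slow-meal shift added to `tmaxG`, min.
#'
#' @return An object of class `patient_params` (a named list).
#' @examples
#' p <- patient_params(SI = 0.003, Gb = 120, W = 70)
#' p$tmaxG
#' effective_tmaxg(p, "fast")
#' @export
patient_params <- function(SG = 0.02, SI = 0.003, Gb = 120, V = 0.9,
                           Vi = 1.2, W = 70, tmaxI = 75, tmaxG = 85,
                           ke = 1.5, p2 = 0.02, Ag = 0.85,
                           tl = 20, td = 20) {
  p <- list(SG = SG, SI = SI, Gb = Gb, V = V, Vi = Vi, W = W,
            tmaxI = tmaxI, tmaxG = tmaxG, ke = ke, p2 = p2, Ag = Ag,
            tl = tl, td = td)
  validate_params(p)
  structure(p, class = "patient_params")
}

validate_params <- function(p) {
  num <- unlist(p)
  if (!all(is.finite(num)))
    stop("patient parameters must all be finite", call. = FALSE)
  pos <- c("SG", "SI", "Gb", "V", "Vi", "W", "tmaxI", "tmaxG", "ke", "p2")
  if (any(num[pos] <= 0))
    stop("rates, volumes and times must be strictly positive", call. = FALSE)
  if (p$Ag <= 0 || p$Ag > 1)
    stop("Ag must lie in (0, 1]", call. = FALSE)
  if (p$tl < 0 || p$td < 0)
    stop("meal shifts tl, td must be non-negative", call. = FALSE)
  if (p$tl >= p$tmaxG)
    stop("fast-meal shift tl must be smaller than tmaxG", call. = FALSE)
  invisible(p)
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Composite-model patient parameters:\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 6), " = ", signif(v, 6)),
      sep = "\n")
  invisible(x)
}

# Parameter vector in the fixed order the compiled core expects.
.par_vec <- function(p) {
  c(p$SG, p$SI, p$Gb, p$V, p$Vi, p$W, p$tmaxI, p$tmaxG, p$ke, p$p2, p$Ag)
}

#' Effective time-to-maximum glucose absorption for a meal class
#'
#' Adjusts `tmaxG` for the absorption class of a meal: fast meals shift it
#' earlier by `tl`, slow meals delay it by `td`, medium meals leave it
#' unchanged. Both shifts default to 20 min.
#'
#' @param params a [patient_params()] object.
#' @param meal_class one of `"fast"`, `"medium"`, `"slow"`.
#' @return Effective time-to-maximum absorption, min.
#' @examples
#' p <- patient_params(tmaxG = 85)
#' effective_tmaxg(p, "slow") # 105
#' @export
effective_tmaxg <- function(params, meal_class) {
  meal_class <- match.arg(meal_class, c("fast", "medium", "slow"))
  out <- switch(meal_class,
                fast = params$tmaxG - params$tl,
                medium = params$tmaxG,
                slow = params$tmaxG + params$td)
  if (out <= 0)
    stop("effective tmaxG must remain positive", call. = FALSE)
  out
}

#' Read / write a flat key-value parameter file
#'
#' Parameter files are flat YAML mappings mirroring the [patient_params()]
#' field names; missing keys take the package defaults.
#'
#' @param path file path.
#' @param params a [patient_params()] object (for writing).
#' @return [read_params()] returns a `patient_params` object;
#'   [write_params()] returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(patient_params))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    warning("ignoring unknown parameter keys: ",
            paste(extra, collapse = ", "))
  do.call(patient_params, vals[intersect(names(vals), known)])
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}
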