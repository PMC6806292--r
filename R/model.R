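#' Model state vector
#'
#' The seven states of the composite model: plasma glucose `G` (mg/dL),
#' insulin action `X` (1/min), subcutaneous insulin compartments `S1`, `S2`
#' (mU), plasma insulin `I` (uU/mL), and the two gut compartments `Ra1`,
#' `Ra` (mg/min).
#'
#' @param G,X,S1,S2,I,Ra1,Ra state values; all non-negative, `G > 0`.
#' @return Named numeric vector of length 7.
#' @export
model_state <- function(G, X = 0, S1 = 0, S2 = 0, I = 0, Ra1 = 0, Ra = 0) {
  x <- c(G = G, X = X, S1 = S1, S2 = S2, I = I, Ra1 = Ra1, Ra = Ra)
  if (!all(is.finite(x))) stop("model state must be finite", call. = FALSE)
  if (G <= 0) stop("glucose must be positive", call. = FALSE)
  if (any(x[-1] < 0)) stop("compartments must be non-negative", call. = FALSE)
  x
}

.state_names <- c("G", "X", "S1", "S2", "I", "Ra1", "Ra")

# Effective tmaxG for an instantaneous input description.
.input_tmaxg <- function(params, uABS) {
  if (is.null(uABS) || uABS == "none") params$tmaxG
  else effective_tmaxg(params, uABS)
}

#' Time derivatives of the composite minimal model
#'
#' Evaluates the right-hand side of the composite model: Bergman glucose
#' disappearance driven by insulin action and the gut glucose rate of
#' appearance, the two-compartment subcutaneous insulin absorption chain,
#' plasma insulin decay, and the two-compartment gut absorption chain.
#'
#' @param state named state vector from [model_state()].
#' @param params a [patient_params()] object.
#' @param input list with `uCHO` (mg/min), `uINS` (mU/min) and `uABS`
#'   (absorption class of a meal currently being absorbed, or `"none"`).
#' @return Named numeric vector `dx/dt` in state units per minute.
#' @examples
#' p <- patient_params()
#' x <- model_state(G = p$Gb)
#' derivatives(x, p, list(uCHO = 0, uINS = 0, uABS = "none")) # all zero
#' @export
derivatives <- function(state, params, input = list(uCHO = 0, uINS = 0,
                                                    uABS = "none")) {
  if (!all(is.finite(state))) stop("non-finite state", call. = FALSE)
  validate_params(params)
  if (input$uCHO < 0 || input$uINS < 0)
    stop("inputs must be non-negative", call. = FALSE)
  tmaxg <- .input_tmaxg(params, input$uABS)
  x <- unname(state)
  with(params, c(
    G   = -(SG + x[2]) * x[1] + SG * Gb + x[7] / (V * W),
    X   = -p2 * x[2] + p2 * SI * x[5],
    S1  = input$uINS - x[3] / tmaxI,
    S2  = (x[3] - x[4]) / tmaxI,
    I   = -ke * x[5] + 1000 * x[4] / (Vi * W * tmaxI),
    Ra1 = -(x[6] - Ag * input$uCHO) / tmaxg,
    Ra  = -(x[7] - x[6]) / tmaxg
  ))
}

#' One forward-Euler step of the composite model
#'
#' Advances the state by `dt` minutes with a single explicit Euler step.
#' States driven negative by the discretisation (the plasma insulin decay is
#' stiff at the 1-min step) are clamped to zero.
#'
#' @inheritParams derivatives
#' @param dt step size, min; the forecasting algorithm always uses 1.
#' @return The state after one step.
#' @export
euler_step <- function(state, params, input = list(uCHO = 0, uINS = 0,
                                                   uABS = "none"),
                       dt = 1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  x <- state + dt * derivatives(state, params, input)
  pmax(x, 0)
}

#' Simulate the composite model over an event schedule
#'
#' Integrates the discretised model at 1-min resolution with the schedule's
#' meals, boluses and basal profile as inputs.  Each meal's absorption class
#' adjusts the time-to-maximum glucose absorption (via [effective_tmaxg()])
#' from the meal's start until 8 h later or the next meal, whichever comes
#' first.
#'
#' @param state0 initial state from [model_state()].
#' @param params a [patient_params()] object.
#' @param schedule an [event_schedule()].
#' @param absorption_info if `FALSE`, all meals are treated as medium
#'   absorption (no meal-class adjustment).
#' @param dt integration step, min (default 1).
#' @return A data frame with columns `time` (min, starting at 0) and the
#'   seven state variables; `horizon + 1` rows at `dt = 1`.
#' @examples
#' p <- patient_params()
#' sched <- event_schedule(
#'   meals = data.frame(time_min = 60, grams = 60, class = "fast"),
#'   horizon = 480)
#' traj <- simulate_model(model_state(G = p$Gb), p, sched)
#' max(traj$Ra) # peak glucose rate of appearance, mg/min
#' @export
simulate_model <- function(state0, params, schedule, absorption_info = TRUE,
                           dt = 1) {
  validate_params(params)
  if (schedule$horizon < 1) stop("horizon must be >= 1 min", call. = FALSE)
  arr <- schedule_arrays(schedule, params,
                         absorption_info = absorption_info)
  if (dt != 1) {
    # refine arrays onto the dt grid (oracle tests only)
    rep_n <- round(1 / dt)
    # rates are held constant across each minute, so repeating them on the
    # finer grid preserves the delivered mass
    arr <- lapply(arr, function(v) rep(v, each = rep_n))
  }
  traj <- .sim_core(unname(state0), .par_vec(params),
                    arr$ucho, arr$uins, arr$tmaxg, arr$tmaxi, dt)
  colnames(traj) <- .state_names
  out <- data.frame(time = seq(0, by = dt, length.out = nrow(traj)), traj)
  out
}
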