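# Shared fixture builders (everything is generated in code).

# a plain one-day scenario: three meals with boluses, no basal
day_schedule <- function(horizon = 1440,
                         classes = c("fast", "medium", "medium")) {
  event_schedule(
    meals = data.frame(time_min = c(420, 780, 1140),
                       grams = c(70, 100, 80), class = classes),
    boluses = data.frame(time_min = c(418, 775, 1138),
                         units = c(0.25, 0.35, 0.28)),
    horizon = horizon)
}

# noiseless CGM sampled from a simulated trajectory
noiseless_cgm <- function(traj, M = 5) {
  idx <- seq(1, nrow(traj), by = M)
  cgm_series(traj$time[idx], pmin(pmax(traj$G[idx], 20), 600), interval = M)
}

default_test_params <- function() patient_params(Gb = 120, W = 70)
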