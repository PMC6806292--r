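# Adaptive-step ODE oracle for the composite model, independent of the
# package's forward-Euler integrator.  Integrates the continuous-time
# right-hand side with lsoda over 1-min segments (inputs are piecewise
# constant per minute).
ode_oracle <- function(state0, params, schedule, absorption_info = TRUE) {
  arr <- glucast:::schedule_arrays(schedule, params,
                                   absorption_info = absorption_info)
  rhs <- function(t, x, p) {
    with(p, list(c(
      -(SG + x[2]) * x[1] + SG * Gb + x[7] / (V * W),
      -p2 * x[2] + p2 * SI * x[5],
      uins_c - x[3] / tmaxi_c,
      (x[3] - x[4]) / tmaxi_c,
      -ke * x[5] + 1000 * x[4] / (Vi * W * tmaxi_c),
      -(x[6] - Ag * ucho_c) / tmaxg_c,
      -(x[7] - x[6]) / tmaxg_c)))
  }
  n <- length(arr$ucho)
  out <- matrix(NA_real_, n + 1, 7)
  x <- unname(state0)
  out[1, ] <- x
  base <- unclass(params)
  for (k in seq_len(n)) {
    p <- c(base, list(uins_c = arr$uins[k], ucho_c = arr$ucho[k],
                      tmaxg_c = arr$tmaxg[k], tmaxi_c = arr$tmaxi[k]))
    sol <- deSolve::ode(y = x, times = c(0, 1), func = rhs, parms = p,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    x <- as.numeric(sol[2, -1])
    out[k + 1, ] <- x
  }
  colnames(out) <- c("G", "X", "S1", "S2", "I", "Ra1", "Ra")
  data.frame(time = 0:n, out)
}
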