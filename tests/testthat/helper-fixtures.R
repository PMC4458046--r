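# Shared fixtures: calibrated constants, random positive parameter
# sets, and random admissible states, all generated in code.

calib <- default_parameters()

# Random strictly positive parameter set: each calibrated constant
# jittered around its calibrated value on the log scale (keeps the
# set in a physically plausible regime); physical constants fixed.
random_parameters <- function() {
  jitter <- stats::rnorm(length(calibrated_parameter_names()), 0, 0.3)
  vals <- as.numeric(calib[calibrated_parameter_names()]) * 10^jitter
  names(vals) <- calibrated_parameter_names()
  do.call(model_parameters, as.list(vals))
}

# Random admissible state spanning the magnitudes the model visits.
random_state <- function() {
  state_vector(
    t_n = stats::runif(1, 0, 0.2),
    t_e1 = stats::runif(1, 0, 2e3),
    lv = stats::runif(1, 0, 2e6),
    t_e2 = stats::runif(1, 0, 5e3),
    c_pos = stats::runif(1, 0, 5e9),
    c_neg = stats::runif(1, 0, 5e9),
    t_e3 = stats::runif(1, 0, 1e4),
    ifng = stats::runif(1, 0, 1e13),
    tnfa = stats::runif(1, 0, 1e12)
  )
}

# Central finite-difference Jacobian of the model RHS.
fd_jacobian <- function(state, p, h_rel = 1e-6) {
  y <- as.numeric(state)
  J <- matrix(0, 9, 9)
  for (j in 1:9) {
    h <- h_rel * max(abs(y[j]), 1e-8)
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    J[, j] <- (model_rhs(0, yp, p) - model_rhs(0, ym, p)) / (2 * h)
  }
  J
}

single_vax <- function(dose = 1.1e6) vaccination_schedule(5, dose)
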