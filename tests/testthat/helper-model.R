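# shared fixtures and independent oracles for the test suite

# coarse 21-channel grid for Monte-Carlo-heavy checks
params21 <- function(...) {
  model_params(n_channels = 21, ...)
}

# central-difference gradient of the trial loss over (w, w_c); independent
# of the analytic gradient used by gradient_step()
num_gradient <- function(state, trial, params, h = 1e-4) {
  n <- length(state$w)
  g <- numeric(n + 1L)
  for (i in seq_len(n)) {
    wp <- state$w
    wm <- state$w
    wp[i] <- wp[i] + h
    wm[i] <- wm[i] - h
    g[i] <- (trial_loss(model_state(wp, state$w_c), trial, params) -
             trial_loss(model_state(wm, state$w_c), trial, params)) / (2 * h)
  }
  g[n + 1L] <- (trial_loss(model_state(state$w, state$w_c + h), trial, params) -
                trial_loss(model_state(state$w, state$w_c - h), trial,
                           params)) / (2 * h)
  g
}

# brute-force planar geometry: place every point in 2-D coordinates and
# measure the shoulder->target angle directly
geom_oracle <- function(theta_T, pivot_to_shoulder, target_distance) {
  th <- theta_T * pi / 180
  target <- c(target_distance * sin(th), target_distance * cos(th))
  shoulder <- c(0, -pivot_to_shoulder)
  v <- target - shoulder
  atan2(v[1], v[2]) * 180 / pi
}

# exponential-with-offset series on the block grid (the analysis model)
decay_series <- function(B, d1, d_off, tau_b, noise_sd = 0) {
  b <- seq_len(B)
  v <- d_off + d1 * exp(-(b - 1) / tau_b)
  if (noise_sd > 0) v <- v + rnorm(B, 0, noise_sd)
  data.frame(block = b, value = v)
}
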