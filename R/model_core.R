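# Forward model: Gaussian population input, weighted readout, gain-modulated
# output stage, and the planar pointing geometry.

# internal: Gaussian activation profile centred on `center` (deg); no
# on-grid check (callers validate via trial_spec / input_activation)
gauss_activation <- function(center, params) {
  params$A0 * exp(-(params$theta - center)^2 / (2 * params$sigma_input^2))
}

#' Input-stage activation profile
#'
#' Activation of the input populations for one trial: a Gaussian of length
#' scale `sigma_input` centred on the (possibly shifted) target angle
#' `theta_T + s`, sampled on the channel grid.
#'
#' @param trial A [trial_spec()].
#' @param params A [model_params()].
#' @return Nonnegative numeric vector of length `n_channels`.
#' @examples
#' p <- model_params()
#' a <- input_activation(trial_spec(0), p)
#' channel_angles(p)[which.max(a)]  # peak at the target
#' @export
input_activation <- function(trial, params) {
  stopifnot(inherits(trial, "trial_spec"), inherits(params, "model_params"))
  center <- trial$theta_T + trial$cond$s
  if (center < params$angle_min || center > params$angle_max) {
    stop(sprintf(
      "shifted target %.3g deg lies outside the channel grid span [%g, %g]",
      center, params$angle_min, params$angle_max))
  }
  gauss_activation(center, params)
}

#' Readout: encoded target location signal
#'
#' Scalar product between the activation profile and the nonnegative spatial
#' weight vector (linear perceptron). Always nonnegative.
#'
#' @param state A [model_state()].
#' @param activation Activation vector from [input_activation()].
#' @return Scalar readout signal `r`.
#' @export
readout <- function(state, activation) {
  stopifnot(inherits(state, "model_state"))
  if (length(activation) != length(state$w)) {
    stop("activation length does not match the number of spatial weights")
  }
  sum(state$w * activation)
}

#' Output stage: pointing angle
#'
#' Maps the readout to a pointing angle,
#' `phi = (1 + w_c * c) * r - phi0 + noise`. The cue-gated multiplicative
#' gain `(1 + w_c * c)` is the cognitive input pathway: with the cue off
#' (`c = 0`) the output is independent of `w_c`. The constant `phi0`
#' converts the always-positive readout into a signed angle.
#'
#' With `output_stage = "additive"` in `params`, the control stage
#' `phi = r + w_c * c - phi0 + noise` is used instead (a learned additive
#' shift rather than a gain); it exists only to demonstrate which phenomena
#' require the multiplicative form.
#'
#' @param state A [model_state()].
#' @param r Readout signal (nonnegative scalar).
#' @param c Binary cue (0 or 1).
#' @param params A [model_params()].
#' @param noise Motor noise draw in degrees (default 0).
#' @return Pointing angle in degrees.
#' @export
pointing_angle <- function(state, r, c, params, noise = 0) {
  stopifnot(inherits(state, "model_state"), r >= 0, c %in% c(0, 1))
  if (params$output_stage == "additive") {
    r + state$w_c * c - params$phi0 + noise
  } else {
    (1 + state$w_c * c) * r - params$phi0 + noise
  }
}

#' Pointing displacement (error)
#'
#' Signed horizontal distance, in degrees, from the pointing location to the
#' true target: `d = phi - theta_T`. Positive is rightward. The learning
#' loss is `d^2`.
#'
#' @param phi Pointing angle, degrees.
#' @param theta_T True target angle, degrees.
#' @return Signed displacement in degrees.
#' @export
displacement <- function(phi, theta_T) {
  phi - theta_T
}

#' Noise-free pointing error of a state in a given condition
#'
#' Convenience forward pass: activation, readout, output stage, and
#' displacement in one call, with no motor noise and no exploration.
#'
#' @param state A [model_state()].
#' @param theta_T Target angle, degrees.
#' @param s Visual shift, degrees.
#' @param c Binary cue.
#' @param params A [model_params()].
#' @return Signed displacement in degrees.
#' @export
pointing_error <- function(state, theta_T, s, c, params) {
  trial <- trial_spec(theta_T, condition(s, c), params)
  a <- input_activation(trial, params)
  r <- readout(state, a)
  displacement(pointing_angle(state, r, trial$cond$c, params), theta_T)
}

#' Exact planar pointing geometry
#'
#' The angle of the shoulder-to-target ray when the target sits at angle
#' `theta_T` and distance `target_distance` from the head pivot, with the
#' shoulder displaced `pivot_to_shoulder` behind the pivot along the
#' midline. The visuo-motor mapping from perceived target angle to required
#' pointing angle is almost linear, with a small nonlinear correction
#' controlled by the ratio of `pivot_to_shoulder` to the reach distance;
#' the model's linear output stage exploits this. The returned angle
#' converges to `theta_T` as `pivot_to_shoulder` shrinks.
#'
#' @param theta_T Target angle from the head pivot, degrees.
#' @param pivot_to_shoulder Distance from head pivot to shoulder (same
#'   length units as `target_distance`), `>= 0`.
#' @param arm_length Arm length, `> 0` (validity check only; the ray angle
#'   does not depend on it).
#' @param target_distance Distance from head pivot to target, must exceed
#'   `pivot_to_shoulder`.
#' @return Required pointing angle at the shoulder, degrees.
#' @examples
#' required_pointing_angle(15, 0, 0.6, 0.5)           # == 15 exactly
#' required_pointing_angle(15, 0.05, 0.6, 0.5)        # small deviation
#' @export
required_pointing_angle <- function(theta_T, pivot_to_shoulder, arm_length,
                                    target_distance) {
  stopifnot(pivot_to_shoulder >= 0, arm_length > 0,
            target_distance > pivot_to_shoulder)
  th <- theta_T * pi / 180
  # head pivot at origin, midline along +y, shoulder at (0, -pivot_to_shoulder)
  tx <- target_distance * sin(th)
  ty <- target_distance * cos(th)
  dy <- ty + pivot_to_shoulder
  if (abs(tx) < .Machine$double.eps && abs(dy) < .Machine$double.eps) {
    stop("degenerate geometry: target coincides with the shoulder")
  }
  atan2(tx, dy) * 180 / pi
}
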