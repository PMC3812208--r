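#' Adaptable state of the network
#'
#' The state holds everything the learning rule may change: the vector of
#' nonnegative spatial weights `w` (one per input channel) and the
#' nonnegative cognitive gain weight `w_c`. All other quantities are fixed
#' structural parameters ([model_params()]).
#'
#' @param w Numeric vector of spatial weights, all `>= 0`.
#' @param w_c Scalar cognitive gain weight, `>= 0`.
#' @return An object of class `model_state`.
#' @export
model_state <- function(w, w_c = 0) {
  stopifnot(is.numeric(w), length(w) >= 3L, all(is.finite(w)),
            is.numeric(w_c), length(w_c) == 1L, is.finite(w_c))
  if (any(w < 0) || w_c < 0) {
    stop("weights must be nonnegative (they are clamped at zero by learning)")
  }
  structure(list(w = as.numeric(w), w_c = as.numeric(w_c)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> %d spatial weights (mean %.4g), w_c = %.4g\n",
              length(x$w), mean(x$w), x$w_c))
  invisible(x)
}

#' A viewing condition
#'
#' A condition is a visual shift `s` (degrees of image displacement; negative
#' is leftward) together with a binary cognitive cue `c` signalling which
#' mapping is in force. In the canonical paradigm the cue is on exactly when
#' the shift is on.
#'
#' @param s Visual shift in degrees (0 in the normal condition).
#' @param c Binary cue, 0 (prisms OFF) or 1 (prisms ON).
#' @return An object of class `condition`.
#' @export
condition <- function(s = 0, c = as.integer(s != 0)) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s), c %in% c(0L, 1L))
  structure(list(s = as.numeric(s), c = as.integer(c)), class = "condition")
}

#' One trial specification
#'
#' @param theta_T True target angle in degrees.
#' @param cond A [condition()]; defaults to the normal viewing condition.
#' @param params A [model_params()] used to check that the shifted target
#'   stays on the channel grid.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(theta_T, cond = condition(), params = NULL) {
  stopifnot(is.numeric(theta_T), length(theta_T) == 1L, is.finite(theta_T),
            inherits(cond, "condition"))
  if (!is.null(params)) {
    shifted <- theta_T + cond$s
    if (shifted < params$angle_min || shifted > params$angle_max) {
      stop(sprintf(
        "shifted target %.3g deg is outside the channel grid span [%g, %g]",
        shifted, params$angle_min, params$angle_max))
    }
  }
  structure(list(theta_T = as.numeric(theta_T), cond = cond),
            class = "trial_spec")
}

#' Analytic state implementing the normal visuo-motor mapping
#'
#' Constructs spatial weights that realize the identity mapping from target
#' angle to pointing angle under the normal viewing condition, without any
#' training. The weight profile is linear in channel angle,
#' `w_i = (phi0 + theta_i) / Z` with `Z` the Gaussian activation mass, which
#' makes the readout `r(theta) = theta + phi0` to very high accuracy away
#' from the grid edges; the profile is then rescaled so that the pointing
#' error at `reference_target` is exactly zero in floating point.
#'
#' @param params A [model_params()].
#' @param reference_target Target angle (degrees) at which the mapping is
#'   made exact.
#' @return A [model_state()] with `w_c = 0`.
#' @export
analytic_normal_state <- function(params, reference_target = 0) {
  stopifnot(inherits(params, "model_params"))
  z <- params$A0 * params$sigma_input * sqrt(2 * pi) / params$delta_theta
  w <- (params$phi0 + params$theta) / z
  w[w < 0] <- 0
  a <- gauss_activation(reference_target, params)
  r <- sum(w * a)
  w <- w * (reference_target + params$phi0) / r
  model_state(w = w, w_c = 0)
}

#' Analytic solution of the dual-mapping problem at one target
#'
#' At a single target angle an exact dual solution exists: spatial weights
#' `w*` that satisfy the normal condition (`r_OFF - phi0 = theta_T`) and a
#' gain weight `w_c* = (theta_T + phi0) / r_ON - 1` that makes the shifted
#' condition exact as well, where `r_ON` is the readout of the shifted
#' activation through `w*`. Both residual pointing errors are zero to
#' numerical precision.
#'
#' Only shifts that reduce the readout (leftward image displacements under
#' the default grid orientation) admit a nonnegative `w_c*`; otherwise an
#' error is raised, mirroring the clamping constraint of the learning rule.
#'
#' @param params A [model_params()].
#' @param theta_T Trained target angle, degrees.
#' @param shift Visual shift, degrees.
#' @return A list with elements `state` (a [model_state()]),
#'   `residual_off` and `residual_on` (the noise-free pointing errors in the
#'   two conditions, degrees).
#' @export
dual_solution <- function(params, theta_T = 0, shift = -15) {
  stopifnot(inherits(params, "model_params"))
  st <- analytic_normal_state(params, reference_target = theta_T)
  a_on <- gauss_activation(theta_T + shift, params)
  r_on <- sum(st$w * a_on)
  w_c <- (theta_T + params$phi0) / r_on - 1
  if (w_c < 0) {
    stop(sprintf(
      paste0("shift %.3g deg increases the readout at this target; the ",
             "required gain weight would be negative and is not ",
             "representable with a zero-clamped w_c"), shift))
  }
  state <- model_state(w = st$w, w_c = w_c)
  list(
    state = state,
    residual_off = pointing_error(state, theta_T, s = 0, c = 0L,
                                  params = params),
    residual_on = pointing_error(state, theta_T, s = shift, c = 1L,
                                 params = params)
  )
}
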