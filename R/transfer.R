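# Spatial transfer and generalization: adapt at a single target, then
# predict the direct effect at untrained test targets across the grid.

#' Adapt at a single target
#'
#' Runs `n_trials` consecutive shifted-condition (cue on) learning trials at
#' one target and returns the adapted state. This is the model analogue of
#' single-target prism adaptation experiments whose transfer is then probed
#' at other locations.
#'
#' @param state A pre-trained [model_state()].
#' @param shift Visual shift, degrees.
#' @param n_trials Number of adaptation movements.
#' @param params A [model_params()].
#' @param theta_T Trained target angle, degrees.
#' @return The adapted [model_state()].
#' @export
adapt_single_target <- function(state, shift, n_trials, params, theta_T = 0) {
  stopifnot(n_trials >= 0)
  if (n_trials == 0L) return(state)
  a_on <- input_activation(
    trial_spec(theta_T, condition(shift, 1L), params), params)
  res <- phase_core(state$w, state$w_c, a_on, 1L, theta_T, params,
                    n = n_trials, learn = TRUE)
  model_state(res$w, res$wc)
}

#' Predicted transfer curve of the direct effect
#'
#' For each test angle, the noise-free shifted-condition (cue on)
#' displacement of the adapted state: the pointing error the model would
#' make if, immediately after adapting at `trained_angle`, it pointed at a
#' target elsewhere. The curve combines a local dip of width set by
#' `sigma_input` (the spatial weights only changed where the adapting
#' activation lived) with a global, readout-proportional gain modulation.
#'
#' Testing at an angle left/right of the trained target is equivalent to
#' rotating the body right/left while testing at the trained target, which
#' is how transfer was probed in rotation experiments; the curve metadata
#' records this equivalence (`rotation_deg = -(test_angle - trained_angle)`).
#'
#' @param state The adapted [model_state()] (see [adapt_single_target()]).
#' @param test_angles Numeric vector of test target angles, degrees; each
#'   shifted test target must remain on the channel grid.
#' @param shift Visual shift used during adaptation, degrees.
#' @param params A [model_params()].
#' @param trained_angle Trained target angle, degrees.
#' @return An object of class `transfer_curve`: data.frame with columns
#'   `test_angle_deg` and `direct_effect_deg`, with attributes
#'   `trained_angle`, `shift` and `rotation_convention`.
#' @export
transfer_curve <- function(state, test_angles, shift, params,
                           trained_angle = 0) {
  stopifnot(length(test_angles) >= 1)
  eff <- vapply(test_angles, function(th) {
    pointing_error(state, th, s = shift, c = 1L, params = params)
  }, numeric(1))
  structure(
    data.frame(test_angle_deg = test_angles, direct_effect_deg = eff),
    trained_angle = trained_angle,
    shift = shift,
    rotation_convention = "rotation_deg = -(test_angle_deg - trained_angle)",
    class = c("transfer_curve", "data.frame"))
}

#' Transfer asymmetry index
#'
#' Quantifies the left/right asymmetry of the transfer curve around the
#' trained target, outside the local dip: the mean `|direct effect|` over
#' test angles on the side the image was displaced toward, minus the mean
#' over the opposite side, within `inner < |angle - trained| <= window`.
#'
#' The gain mechanism corrects pointing in proportion to the readout, which
#' grows toward one end of the workspace; its corrections are therefore too
#' small on the side the (compensable) shift displaced the image toward,
#' leaving larger residual errors there. In the prism literature that side
#' is described as contrary to the prism direction (prisms displace the
#' image away from their base), and the index is positive exactly when the
#' effect is enhanced there. A purely spatial adaptation (`eta_c = 0`) or
#' an additive-shift output stage produces a symmetric curve and an index
#' near zero.
#'
#' @param curve A [transfer_curve()].
#' @param window Half-width of the evaluation band, degrees.
#' @param inner Inner exclusion radius around the trained angle (to exclude
#'   the local dip); defaults to `2 * sigma_input` when `params` is given,
#'   else 20 degrees.
#' @param params Optional [model_params()] supplying `sigma_input`.
#' @return Scalar index in degrees.
#' @export
asymmetry_index <- function(curve, window = 40, inner = NULL, params = NULL) {
  stopifnot(inherits(curve, "transfer_curve"))
  if (is.null(inner)) {
    inner <- if (!is.null(params)) 2 * params$sigma_input else 20
  }
  trained <- attr(curve, "trained_angle")
  shift <- attr(curve, "shift")
  if (shift == 0) stop("asymmetry is undefined for a zero shift")
  off <- curve$test_angle_deg - trained
  band <- abs(off) > inner & abs(off) <= window
  shifted_side <- band & sign(off) == sign(shift)
  other_side <- band & sign(off) == -sign(shift)
  if (!any(shifted_side) || !any(other_side)) {
    stop("evaluation window contains no test angles outside the dip")
  }
  mean(abs(curve$direct_effect_deg[shifted_side])) -
    mean(abs(curve$direct_effect_deg[other_side]))
}

#' @export
plot.transfer_curve <- function(x, ...) {
  trained <- attr(x, "trained_angle")
  plot(x$test_angle_deg, abs(x$direct_effect_deg), type = "l",
       xlab = "test target angle (deg)", ylab = "|direct effect| (deg)", ...)
  graphics::abline(v = trained, lty = 2, col = "grey40")
  invisible(x)
}
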