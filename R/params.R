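#' Parameters of the perceptron-gain adaptation model
#'
#' Bundles every structural and learning constant of the network: the input
#' channel grid, the Gaussian tuning scale of the input populations, the
#' output offset angle, the learning and exploration rates of the
#' weight-perturbation rule, and the motor noise level.
#'
#' The defaults encode the canonical configuration used throughout the
#' package: 181 input channels spanning -90..+90 degrees at 1 degree
#' resolution (the resolution can be refined without changing results),
#' `sigma_input = 10` degrees, and `phi0 = 90` degrees, which maps the
#' always-positive readout symmetrically onto pointing angles in
#' -90..+90. The four learning-rule constants (`eta_w`, `eta_c`,
#' `sigma_w`, `sigma_c`) were calibrated once on the P = 30 alternating
#' schedule and are frozen at those values for every other schedule and
#' experiment; see the methods vignette.
#'
#' @param n_channels Integer number of input populations (>= 3).
#' @param angle_min,angle_max Span of the channel grid, degrees.
#' @param sigma_input Gaussian length scale of the input activation, degrees.
#' @param phi0 Constant output offset angle, degrees. Converts the positive
#'   readout signal into a signed pointing angle.
#' @param A0 Activation amplitude (unitless). Its absolute scale is
#'   arbitrary: learning absorbs it into the weights.
#' @param eta_w,eta_c Learning rates for the spatial weights and the
#'   cognitive gain weight (unitless).
#' @param sigma_w,sigma_c Exploration (perturbation) standard deviations for
#'   spatial and cognitive weights.
#' @param sigma_motor Standard deviation of additive zero-mean motor noise on
#'   the executed pointing angle, degrees. Zero by default so that forward
#'   passes are deterministic.
#' @param output_stage `"gain"` for the canonical multiplicative-gain output
#'   stage, or `"additive"` for the additive-shift control stage used only to
#'   probe which features require a multiplicative gain.
#' @param w_c_init Length-2 numeric: the uniform interval from which the
#'   cognitive weight is initialized at the start of a dual-adaptation run.
#'   A positive mean acts as a prior on the compensatory gain and makes the
#'   first pointing error smaller than the optical shift, as in humans.
#'
#' @return An object of class `model_params`: a validated list with the
#'   above fields plus `delta_theta` (grid resolution) and `theta` (the
#'   channel grid angles).
#' @examples
#' p <- model_params()
#' p$delta_theta
#' @export
model_params <- function(n_channels = 181L,
                         angle_min = -90,
                         angle_max = 90,
                         sigma_input = 10,
                         phi0 = 90,
                         A0 = 1,
                         eta_w = 0.3,
                         eta_c = 3e-2,
                         sigma_w = 0.03,
                         sigma_c = 5e-3,
                         sigma_motor = 0,
                         output_stage = c("gain", "additive"),
                         w_c_init = c(0, 0.1)) {
  output_stage <- match.arg(output_stage)
  n_channels <- as.integer(n_channels)
  stopifnot(
    n_channels >= 3L,
    is.numeric(angle_min), is.numeric(angle_max), angle_min < angle_max,
    sigma_input > 0,
    is.numeric(phi0), length(phi0) == 1L,
    A0 > 0,
    eta_w >= 0, eta_c >= 0, sigma_w >= 0, sigma_c >= 0, sigma_motor >= 0,
    length(w_c_init) == 2L, w_c_init[1] <= w_c_init[2], w_c_init[1] >= 0
  )
  delta_theta <- (angle_max - angle_min) / (n_channels - 1L)
  p <- list(
    n_channels = n_channels,
    angle_min = angle_min,
    angle_max = angle_max,
    delta_theta = delta_theta,
    theta = seq(angle_min, angle_max, length.out = n_channels),
    sigma_input = sigma_input,
    phi0 = phi0,
    A0 = A0,
    eta_w = eta_w,
    eta_c = eta_c,
    sigma_w = sigma_w,
    sigma_c = sigma_c,
    sigma_motor = sigma_motor,
    output_stage = output_stage,
    w_c_init = as.numeric(w_c_init)
  )
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  grid: %d channels, %g..%g deg (delta %g deg)\n",
              x$n_channels, x$angle_min, x$angle_max, x$delta_theta))
  cat(sprintf("  sigma_input: %g deg   phi0: %g deg   A0: %g\n",
              x$sigma_input, x$phi0, x$A0))
  cat(sprintf("  learning: eta_w %g, eta_c %g, sigma_w %g, sigma_c %g\n",
              x$eta_w, x$eta_c, x$sigma_w, x$sigma_c))
  cat(sprintf("  sigma_motor: %g deg   output stage: %s   w_c init: U(%g, %g)\n",
              x$sigma_motor, x$output_stage, x$w_c_init[1], x$w_c_init[2]))
  invisible(x)
}

#' Channel grid angles
#'
#' @param params A [model_params()] object.
#' @return Numeric vector of the angular positions (degrees) of the input
#'   channels.
#' @export
channel_angles <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$theta
}

#' Write or read a model configuration as JSON
#'
#' One JSON document holds every [model_params()] field (plus an optional RNG
#' seed), so a full simulation is reproducible from the file alone.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @param seed Optional integer seed stored alongside the parameters.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a list with elements `params` ([model_params()]) and `seed`
#'   (integer or `NULL`).
#' @export
write_params_json <- function(params, path, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  x <- unclass(params)
  x$theta <- NULL
  x$delta_theta <- NULL
  x$seed <- seed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- x$seed
  x$seed <- NULL
  params <- do.call(model_params, x)
  list(params = params, seed = if (is.null(seed)) NULL else as.integer(seed))
}
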