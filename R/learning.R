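# Adaptation of the model state: exact gradient descent (verification
# oracle) and the weight-perturbation reinforcement rule, plus pre-training
# of the normal mapping.

#' Squared pointing loss of a trial
#'
#' `L = d^2` with `d` the noise-free displacement of the state on the trial.
#'
#' @param state A [model_state()].
#' @param trial A [trial_spec()].
#' @param params A [model_params()].
#' @return Scalar loss (degrees squared).
#' @export
trial_loss <- function(state, trial, params) {
  pointing_error(state, trial$theta_T, trial$cond$s, trial$cond$c, params)^2
}

#' One exact gradient-descent step
#'
#' Deterministic reference rule: moves every weight against the analytic
#' gradient of the squared pointing error and clamps at zero,
#' `w_i <- max(0, w_i - eta_w * dL/dw_i)`, likewise for `w_c` with `eta_c`.
#' With the cue off the gradient on `w_c` is exactly zero. The stochastic
#' rule ([stochastic_step()]) equals this rule in expectation (scaled by the
#' exploration variance); that equivalence is what makes the perturbation
#' rule a stochastic gradient descent.
#'
#' @inheritParams trial_loss
#' @return The updated [model_state()].
#' @export
gradient_step <- function(state, trial, params) {
  a <- input_activation(trial, params)
  r <- readout(state, a)
  cue <- trial$cond$c
  phi <- pointing_angle(state, r, cue, params)
  d <- displacement(phi, trial$theta_T)
  if (params$output_stage == "additive") {
    dphi_dw <- a
    dphi_dc <- cue
  } else {
    dphi_dw <- (1 + state$w_c * cue) * a
    dphi_dc <- cue * r
  }
  w <- state$w - params$eta_w * 2 * d * dphi_dw
  w[w < 0] <- 0
  w_c <- max(0, state$w_c - params$eta_c * 2 * d * dphi_dc)
  model_state(w = w, w_c = w_c)
}

# internal engine: run `n` consecutive perturbation-learning trials at a
# fixed condition. `A` is the precomputed activation profile. Returns the
# updated weights and the executed (perturbed, noisy) displacements.
# RNG draw order per trial: spatial perturbations, cognitive perturbation,
# motor noise. With learn = FALSE (or both exploration SDs zero) no
# perturbation is applied and the state is unchanged.
phase_core <- function(w, wc, A, c_on, theta_T, params, n, learn = TRUE) {
  eta_w <- params$eta_w
  eta_c <- params$eta_c
  sw <- params$sigma_w
  sc <- params$sigma_c
  sm <- params$sigma_motor
  phi0 <- params$phi0
  additive <- params$output_stage == "additive"
  nw <- length(w)
  d <- numeric(n)
  explore <- learn && (sw > 0 || sc > 0)
  for (j in seq_len(n)) {
    r <- sum(w * A)
    phi <- if (additive) r + wc * c_on - phi0 else (1 + wc * c_on) * r - phi0
    if (explore) {
      xw <- rnorm(nw, 0, sw)
      xc <- rnorm(1L, 0, sc)
      rp <- r + sum(xw * A)
      phip <- if (additive) {
        rp + (wc + xc) * c_on - phi0
      } else {
        (1 + (wc + xc) * c_on) * rp - phi0
      }
      eps <- if (sm > 0) rnorm(1L, 0, sm) else 0
      dj <- phip + eps - theta_T
      dl <- dj * dj - (phi - theta_T)^2
      w <- w - (eta_w * dl) * xw
      w[w < 0] <- 0
      if (c_on == 1L) {
        wc <- max(0, wc - eta_c * dl * xc)
      }
      d[j] <- dj
    } else {
      eps <- if (sm > 0) rnorm(1L, 0, sm) else 0
      d[j] <- phi + eps - theta_T
    }
  }
  list(w = w, wc = wc, d = d)
}

#' One weight-perturbation (reinforcement) learning step
#'
#' The biologically motivated rule: all synaptic weights are jointly
#' perturbed by independent zero-mean Gaussian draws
#' (`xi_w ~ N(0, sigma_w^2)` per spatial weight, `xi_c ~ N(0, sigma_c^2)`),
#' the perturbed movement is executed, and the resulting change in squared
#' error relative to the unperturbed loss on the same trial,
#' `dL = L(state + xi) - L(state)`, is fed back as a global reinforcement
#' signal. Each weight then moves by `-eta * xi * dL` and is clamped at
#' zero. A perturbation that lowered the error is thus partially retained; a
#' perturbation that raised it is reverted. With the cue off, fluctuations
#' of `w_c` have no effect on the output and `w_c` is left unchanged.
#'
#' The executed movement reported for the trial is the perturbed (and, if
#' `sigma_motor > 0`, motor-noisy) one.
#'
#' @inheritParams trial_loss
#' @return A list with elements `state` (updated [model_state()]),
#'   `displacement` (executed displacement, degrees) and `loss` (squared
#'   executed displacement).
#' @export
stochastic_step <- function(state, trial, params) {
  a <- input_activation(trial, params)
  res <- phase_core(state$w, state$w_c, a, trial$cond$c, trial$theta_T,
                    params, n = 1L, learn = TRUE)
  list(state = model_state(res$w, res$wc),
       displacement = res$d,
       loss = res$d^2)
}

#' Monte-Carlo expectation of the stochastic update
#'
#' Repeatedly applies [stochastic_step()] from the same fixed state and
#' returns the mean weight change. In expectation the perturbation rule
#' equals `-eta * sigma^2 * grad L` (to leading order in the exploration
#' SDs), which this function makes measurable against a finite-difference
#' gradient.
#'
#' @inheritParams trial_loss
#' @param n_draws Number of independent perturbation draws.
#' @return A list with `dw` (mean spatial-weight change vector) and `dw_c`
#'   (mean cognitive-weight change).
#' @export
stochastic_update_expectation <- function(state, trial, params,
                                          n_draws = 1e5) {
  a <- input_activation(trial, params)
  cue <- trial$cond$c
  acc_w <- numeric(length(state$w))
  acc_c <- 0
  for (k in seq_len(n_draws)) {
    res <- phase_core(state$w, state$w_c, a, cue, trial$theta_T, params,
                      n = 1L, learn = TRUE)
    acc_w <- acc_w + (res$w - state$w)
    acc_c <- acc_c + (res$wc - state$w_c)
  }
  list(dw = acc_w / n_draws, dw_c = acc_c / n_draws)
}

#' Pre-train the normal visuo-motor mapping
#'
#' Before any dual-adaptation schedule, the model learns weights that map
#' every target to its correct motor response under normal viewing
#' (cue off, no shift): targets are drawn uniformly at random from the grid
#' points inside `target_range`, each presented for `iters_per_target`
#' consecutive steps of the perturbation rule. Spatial weights are
#' initialized uniformly at random on `(0, w_init_max)`. Because the cue is
#' off throughout, `w_c` is irrelevant to the output during this stage.
#'
#' With `n_runs > 1` the final weights are averaged over independent runs
#' and the averaged state is returned; averaging reduces run-to-run
#' variability of the subsequent dual-adaptation ensembles (single-run
#' initializations are noisier).
#'
#' Convergence is probed on a regular grid of `probe_n` targets spanning
#' `target_range` shrunk by `3 * sigma_input` on each side: at the boundary
#' of the training range the uniform target distribution no longer
#' surrounds a probe, so the mapping there is systematically biased and is
#' not part of the usable workspace. If the maximum absolute noise-free
#' probe error of the returned state exceeds `tol`, a warning is raised and
#' the state is flagged.
#'
#' @param params A [model_params()].
#' @param target_range Length-2 numeric, degrees; must lie inside the grid.
#' @param n_targets Number of training targets per run.
#' @param iters_per_target Learning steps per target.
#' @param n_runs Number of independent runs to average.
#' @param w_init_max Upper end of the uniform weight-initialization
#'   interval. Default `2 * phi0 / Z` with `Z` the Gaussian activation
#'   mass, which puts the initial mean readout near `phi0`.
#' @param probe_n Number of probe targets for the convergence check.
#' @param tol Convergence tolerance on the probe errors, degrees.
#' @return A [model_state()] (with `w_c = 0`) carrying attributes
#'   `probe_errors` (named numeric), `probe_max_abs_error` and `converged`.
#' @export
pretrain <- function(params, target_range = c(-70, 70), n_targets = 12000,
                     iters_per_target = 10, n_runs = 1, w_init_max = NULL,
                     probe_n = 13, tol = 1) {
  stopifnot(inherits(params, "model_params"),
            length(target_range) == 2L,
            target_range[1] >= params$angle_min,
            target_range[2] <= params$angle_max,
            n_targets >= 1, iters_per_target >= 1, n_runs >= 1)
  if (is.null(w_init_max)) {
    z <- params$A0 * params$sigma_input * sqrt(2 * pi) / params$delta_theta
    w_init_max <- 2 * params$phi0 / z
  }
  grid <- params$theta
  candidates <- grid[grid >= target_range[1] & grid <= target_range[2]]
  w_sum <- numeric(params$n_channels)
  for (run in seq_len(n_runs)) {
    w <- runif(params$n_channels, 0, w_init_max)
    wc <- 0
    targets <- sample(candidates, n_targets, replace = TRUE)
    for (t in targets) {
      a <- gauss_activation(t, params)
      res <- phase_core(w, wc, a, 0L, t, params, n = iters_per_target,
                        learn = TRUE)
      w <- res$w
    }
    w_sum <- w_sum + w
  }
  state <- model_state(w = w_sum / n_runs, w_c = 0)
  margin <- 3 * params$sigma_input
  lo <- target_range[1] + margin
  hi <- target_range[2] - margin
  if (lo >= hi) {
    lo <- target_range[1]
    hi <- target_range[2]
  }
  probes <- seq(lo, hi, length.out = probe_n)
  errs <- vapply(probes, function(t) {
    pointing_error(state, t, s = 0, c = 0L, params = params)
  }, numeric(1))
  names(errs) <- sprintf("%.1f", probes)
  max_err <- max(abs(errs))
  attr(state, "probe_errors") <- errs
  attr(state, "probe_max_abs_error") <- max_err
  attr(state, "converged") <- max_err <= tol
  if (max_err > tol) {
    warning(sprintf(
      "pre-training did not reach tolerance: max |probe error| = %.3g deg (tol %.3g)",
      max_err, tol))
  }
  state
}
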