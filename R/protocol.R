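# Dual-adaptation schedules: familiarization followed by alternating
# blocks of shifted (prisms ON) and original (prisms OFF) phases.

#' Define a dual-adaptation schedule
#'
#' A schedule is `B` blocks, each consisting of `P` movements in the shifted
#' mapping (ON) followed by `P` movements in the original mapping (OFF),
#' preceded by a familiarization phase in the original mapping. The total
#' number of post-familiarization movements `M = 2 * P * B` is held constant
#' across the canonical schedules so that schedules differ only in how the
#' same number of movements is distributed over phase changes.
#'
#' @param P Movements per phase.
#' @param B Number of blocks; defaults to `M / (2 * P)`.
#' @param M Total post-familiarization movements (used only when `B` is not
#'   given; must then be divisible by `2 * P`).
#' @param familiarization Number of initial normal-condition movements.
#' @param shift Visual shift of the ON condition, degrees (negative =
#'   leftward image displacement).
#' @param s_off Visual shift of the OFF condition, degrees (0 in the
#'   canonical paradigm; nonzero for dual-shifted-condition experiments).
#' @param theta_T Target angle, degrees.
#' @param schedule_id Label; defaults to `"P<P>"`.
#' @return An object of class `adaptation_schedule`.
#' @export
make_schedule <- function(P, B = NULL, M = 1200, familiarization = 15,
                          shift = -15, s_off = 0, theta_T = 0,
                          schedule_id = sprintf("P%d", P)) {
  P <- as.integer(P)
  stopifnot(P >= 1L, familiarization >= 0)
  if (is.null(B)) {
    if (M %% (2L * P) != 0L) {
      stop(sprintf("M = %d is not divisible by 2*P = %d", M, 2L * P))
    }
    B <- M %/% (2L * P)
  }
  B <- as.integer(B)
  stopifnot(B >= 1L)
  structure(list(schedule_id = schedule_id, P = P, B = B,
                 M = 2L * P * B,
                 familiarization = as.integer(familiarization),
                 shift = shift, s_off = s_off, theta_T = theta_T),
            class = "adaptation_schedule")
}

#' @export
print.adaptation_schedule <- function(x, ...) {
  cat(sprintf(
    "<adaptation_schedule %s> P = %d, B = %d (M = %d), fam = %d, shift = %g deg (OFF %g), target %g deg\n",
    x$schedule_id, x$P, x$B, x$M, x$familiarization, x$shift, x$s_off,
    x$theta_T))
  invisible(x)
}

#' The five canonical schedules
#'
#' Phase lengths P = 5, 15, 30, 60 and 120 movements, all with the same
#' total of `M` post-familiarization movements (default 1200), so block
#' counts run from 120 down to 5.
#'
#' @param shift Visual shift of the ON condition, degrees.
#' @param M Total post-familiarization movements.
#' @param familiarization Familiarization movements per run.
#' @param theta_T Target angle, degrees.
#' @return Named list of [make_schedule()] objects.
#' @export
canonical_schedules <- function(shift = -15, M = 1200, familiarization = 15,
                                theta_T = 0) {
  ps <- c(5L, 15L, 30L, 60L, 120L)
  out <- lapply(ps, function(p) {
    make_schedule(P = p, M = M, familiarization = familiarization,
                  shift = shift, theta_T = theta_T)
  })
  names(out) <- vapply(out, `[[`, character(1), "schedule_id")
  out
}

#' Run a single trial of a schedule phase
#'
#' Executes one pointing movement under the condition implied by `phase`
#' (`"ON"` maps to the shifted condition with the cue on, `"OFF"` and
#' `"FAM"` to the original condition with the cue off) and, if `learn` is
#' `TRUE`, applies one [stochastic_step()]. The recorded displacement is the
#' executed (perturbed, noisy) one.
#'
#' @param state A [model_state()].
#' @param schedule An [make_schedule()] object.
#' @param phase `"ON"`, `"OFF"` or `"FAM"`.
#' @param params A [model_params()].
#' @param learn Apply a learning update?
#' @return A list with `state` (possibly updated) and `displacement`
#'   (degrees).
#' @export
run_trial <- function(state, schedule, phase = c("ON", "OFF", "FAM"), params,
                      learn = TRUE) {
  phase <- match.arg(phase)
  s <- if (phase == "ON") schedule$shift else schedule$s_off
  cue <- if (phase == "ON") 1L else 0L
  trial <- trial_spec(schedule$theta_T, condition(s, cue), params)
  a <- input_activation(trial, params)
  res <- phase_core(state$w, state$w_c, a, cue, schedule$theta_T, params,
                    n = 1L, learn = learn)
  list(state = model_state(res$w, res$wc), displacement = res$d)
}

#' Run one full dual-adaptation schedule
#'
#' Familiarization trials (original mapping, learning on) followed by `B`
#' blocks of `P` ON trials and `P` OFF trials, all with one learning step
#' per movement. Movement records carry the global post-familiarization
#' movement index `m` (1-based; familiarization rows have `m = NA` and
#' `block = NA`) and the raw, baseline-uncorrected executed displacement.
#'
#' @param state A pre-trained [model_state()]; its `w_c` is used as the
#'   initial cognitive weight.
#' @param schedule An [make_schedule()] object.
#' @param params A [model_params()].
#' @param run_id Identifier stored in the records.
#' @param learn Apply learning updates (default `TRUE`).
#' @return A list with `records` (a data.frame with columns `run_id`,
#'   `schedule_id`, `m`, `block`, `phase`, `theta_T_deg`,
#'   `displacement_deg`) and `state` (the final [model_state()]).
#' @export
run_schedule <- function(state, schedule, params, run_id = 1L, learn = TRUE) {
  stopifnot(inherits(state, "model_state"),
            inherits(schedule, "adaptation_schedule"),
            inherits(params, "model_params"))
  th <- schedule$theta_T
  a_on <- input_activation(
    trial_spec(th, condition(schedule$shift, 1L), params), params)
  a_off <- input_activation(
    trial_spec(th, condition(schedule$s_off, 0L), params), params)
  P <- schedule$P
  B <- schedule$B
  fam <- schedule$familiarization
  n_tot <- fam + schedule$M
  d_all <- numeric(n_tot)
  w <- state$w
  wc <- state$w_c
  if (fam > 0L) {
    res <- phase_core(w, wc, a_off, 0L, th, params, n = fam, learn = learn)
    w <- res$w
    wc <- res$wc
    d_all[seq_len(fam)] <- res$d
  }
  pos <- fam
  for (b in seq_len(B)) {
    res <- phase_core(w, wc, a_on, 1L, th, params, n = P, learn = learn)
    w <- res$w
    wc <- res$wc
    d_all[pos + seq_len(P)] <- res$d
    pos <- pos + P
    res <- phase_core(w, wc, a_off, 0L, th, params, n = P, learn = learn)
    w <- res$w
    wc <- res$wc
    d_all[pos + seq_len(P)] <- res$d
    pos <- pos + P
  }
  m <- c(rep(NA_integer_, fam), seq_len(schedule$M))
  block <- c(rep(NA_integer_, fam), rep(seq_len(B), each = 2L * P))
  phase <- c(rep("FAM", fam),
             rep(rep(c("ON", "OFF"), each = P), times = B))
  records <- data.frame(
    run_id = run_id,
    schedule_id = schedule$schedule_id,
    m = m,
    block = block,
    phase = phase,
    theta_T_deg = th,
    displacement_deg = d_all,
    stringsAsFactors = FALSE
  )
  list(records = records, state = model_state(w, wc))
}

#' Simulate an ensemble of dual-adaptation runs
#'
#' Runs the same schedule `n_runs` times from the shared pre-trained spatial
#' weights, with each run's cognitive weight drawn independently from the
#' uniform prior `params$w_c_init` and its own reproducible RNG stream.
#' Per-run seeds are derived deterministically from `seed`, so the whole
#' ensemble is a pure function of (configuration, master seed).
#'
#' @param schedule An [make_schedule()] object.
#' @param params A [model_params()].
#' @param state0 Pre-trained [model_state()] supplying the shared initial
#'   spatial weights (see [pretrain()] or [analytic_normal_state()]).
#' @param n_runs Number of runs.
#' @param seed Master seed (integer).
#' @return An object of class `ensemble_run`: a list with `records` (all
#'   runs stacked), `mean_displacement` (per-movement-index mean raw
#'   displacement across runs, length `M`), `final_states` (list of
#'   [model_state()]), `schedule`, `n_runs` and `seed`.
#' @export
ensemble_run <- function(schedule, params, state0, n_runs = 100, seed = 1L) {
  stopifnot(n_runs >= 1, inherits(state0, "model_state"))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  recs <- vector("list", n_runs)
  finals <- vector("list", n_runs)
  d_sum <- numeric(schedule$M)
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[i])
    wc0 <- runif(1L, params$w_c_init[1], params$w_c_init[2])
    st <- model_state(state0$w, wc0)
    rr <- run_schedule(st, schedule, params, run_id = i)
    recs[[i]] <- rr$records
    finals[[i]] <- rr$state
    d_sum <- d_sum + rr$records$displacement_deg[!is.na(rr$records$m)]
  }
  structure(list(
    records = do.call(rbind, recs),
    mean_displacement = d_sum / n_runs,
    final_states = finals,
    schedule = schedule,
    n_runs = n_runs,
    seed = seed
  ), class = "ensemble_run")
}

#' @export
print.ensemble_run <- function(x, ...) {
  cat(sprintf("<ensemble_run> %s: %d runs x %d movements (seed %d)\n",
              x$schedule$schedule_id, x$n_runs, x$schedule$M, x$seed))
  invisible(x)
}

#' Movements needed to master a pair of viewing conditions
#'
#' Runs an alternating schedule on an arbitrary pair of conditions (the
#' cue-on condition with shift `s_on`, the cue-off condition with shift
#' `s_off`) and reports the number of movements after which the noise-free
#' pointing error of the current state is below `tol` in *both* conditions,
#' evaluated at the end of every block. Used to compare, e.g., learning one
#' normal and one shifted condition against learning two oppositely shifted
#' conditions of the same angular separation.
#'
#' @param state0 Initial [model_state()] (pre-trained for the unshifted
#'   mapping).
#' @param params A [model_params()].
#' @param s_on,s_off Shifts (degrees) of the cue-on / cue-off conditions.
#' @param theta_T Target angle, degrees.
#' @param P Movements per phase.
#' @param tol Error criterion, degrees.
#' @param max_blocks Give up after this many blocks.
#' @return Number of movements (2 * P * blocks) to criterion, or `NA` if the
#'   criterion was not reached within `max_blocks` blocks.
#' @export
movements_to_criterion <- function(state0, params, s_on, s_off = 0,
                                   theta_T = 0, P = 30, tol = 2,
                                   max_blocks = 100) {
  a_on <- input_activation(
    trial_spec(theta_T, condition(s_on, 1L), params), params)
  a_off <- input_activation(
    trial_spec(theta_T, condition(s_off, 0L), params), params)
  w <- state0$w
  wc <- state0$w_c
  for (b in seq_len(max_blocks)) {
    res <- phase_core(w, wc, a_on, 1L, theta_T, params, n = P, learn = TRUE)
    w <- res$w
    wc <- res$wc
    res <- phase_core(w, wc, a_off, 0L, theta_T, params, n = P, learn = TRUE)
    w <- res$w
    wc <- res$wc
    st <- model_state(w, wc)
    e_on <- pointing_error(st, theta_T, s_on, 1L, params)
    e_off <- pointing_error(st, theta_T, s_off, 0L, params)
    if (abs(e_on) < tol && abs(e_off) < tol) {
      return(2L * P * b)
    }
  }
  NA_integer_
}

#' Write or read movement records as CSV
#'
#' The on-disk dialect is the data.frame produced by [run_schedule()]:
#' columns `run_id`, `schedule_id`, `m`, `block`, `phase` (FAM/ON/OFF),
#' `theta_T_deg`, `displacement_deg`, with a header row.
#'
#' @param records Movement-record data.frame.
#' @param path File path.
#' @return `write_records` returns `path` invisibly; `read_records` returns
#'   the records data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
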