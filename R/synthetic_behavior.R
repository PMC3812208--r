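# Synthetic subject-like behavioural datasets with known ground truth:
# exponentially decaying direct effect with offset, within-phase dynamics,
# per-subject bias and additive noise. Used to validate the analysis
# pipeline independently of the neural simulator.

#' Specification of a synthetic subject
#'
#' Ground-truth parameters of one simulated observer. The first ON movement
#' of block `b` has expectation
#' `d_off + d1 * exp(-(b - 1) * 2P / tau_m) + baseline_bias`; within each
#' phase the error decays toward the current mapping's asymptote (the final
#' offset during ON phases, zero during OFF phases) with its own
#' movement-scale constant `tau_within`. `tau_m` is shared across schedules
#' when emulating movement-count-invariant adaptation.
#'
#' @param d1 Initial decaying amplitude of the direct effect, degrees.
#' @param d_off Final offset, degrees.
#' @param tau_m Decay constant of the across-block decay, in movements.
#' @param noise_sd SD of additive Gaussian noise on every movement, degrees.
#' @param baseline_bias Constant per-subject pointing bias, degrees.
#' @param tau_within Within-phase decay constant, movements; defaults to
#'   `tau_m / 4` (it does not affect the first-movement analysis).
#' @param after_ratio Aftereffect amplitude as a fraction of the direct
#'   effect amplitude of the same block (opposite sign).
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(d1, d_off, tau_m, noise_sd = 0, baseline_bias = 0,
                         tau_within = tau_m / 4, after_ratio = 0.6) {
  stopifnot(tau_m > 0, noise_sd >= 0, tau_within > 0, after_ratio >= 0)
  structure(list(d1 = d1, d_off = d_off, tau_m = tau_m, noise_sd = noise_sd,
                 baseline_bias = baseline_bias, tau_within = tau_within,
                 after_ratio = after_ratio),
            class = "subject_spec")
}

#' Generate one synthetic subject's movement records
#'
#' Produces a complete movement-record table for `schedule` under `spec`:
#' familiarization trials at the baseline bias, then per block an ON phase
#' starting at the direct-effect expectation and decaying toward `d_off`,
#' and an OFF phase starting at the (negative) aftereffect and decaying
#' toward zero, all plus bias and noise. Uses the current RNG state; seed
#' with [set.seed()] for reproducibility.
#'
#' @param spec A [subject_spec()].
#' @param schedule An [make_schedule()] object.
#' @param subject_id Identifier stored in `run_id`.
#' @return Movement-record data.frame in the [run_schedule()] dialect.
#' @export
gen_subject <- function(spec, schedule, subject_id = 1L) {
  stopifnot(inherits(spec, "subject_spec"),
            inherits(schedule, "adaptation_schedule"))
  P <- schedule$P
  B <- schedule$B
  fam <- schedule$familiarization
  j <- seq_len(P) - 1L
  within <- exp(-j / spec$tau_within)
  d <- numeric(fam + 2L * P * B)
  d[seq_len(fam)] <- 0
  pos <- fam
  for (b in seq_len(B)) {
    amp <- spec$d1 * exp(-(b - 1L) * 2L * P / spec$tau_m)
    d[pos + seq_len(P)] <- spec$d_off + amp * within
    pos <- pos + P
    d[pos + seq_len(P)] <- (-spec$after_ratio * amp) * within
    pos <- pos + P
  }
  n <- length(d)
  d <- d + spec$baseline_bias
  if (spec$noise_sd > 0) d <- d + rnorm(n, 0, spec$noise_sd)
  data.frame(
    run_id = subject_id,
    schedule_id = schedule$schedule_id,
    m = c(rep(NA_integer_, fam), seq_len(2L * P * B)),
    block = c(rep(NA_integer_, fam), rep(seq_len(B), each = 2L * P)),
    phase = c(rep("FAM", fam), rep(rep(c("ON", "OFF"), each = P), times = B)),
    theta_T_deg = schedule$theta_T,
    displacement_deg = d,
    stringsAsFactors = FALSE
  )
}

#' Generate a group of synthetic subjects
#'
#' @param specs List of [subject_spec()] objects, one per subject.
#' @param schedule An [make_schedule()] object.
#' @return A list with `records` (all subjects stacked, `run_id` 1..n) and
#'   `mean_direct` (the across-subject mean direct-effect series, matching
#'   the average-then-fit analysis order).
#' @export
gen_group <- function(specs, schedule) {
  stopifnot(length(specs) >= 1L)
  recs <- do.call(rbind, lapply(seq_along(specs), function(i) {
    gen_subject(specs[[i]], schedule, subject_id = i)
  }))
  list(records = recs,
       mean_direct = extract_effect(recs, kind = "direct", P = schedule$P))
}
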