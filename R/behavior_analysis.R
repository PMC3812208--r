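# Behavioural analysis pipeline: baseline correction, direct-effect and
# aftereffect extraction, exponential-plus-offset decay fits, normalization
# and time-constant unit conversion.

#' Baseline-correct movement records
#'
#' Subtracts, separately for every run/subject, the mean displacement of its
#' first `baseline_n` familiarization trials from all of its displacements.
#' The baseline is a constant per-subject pointing bias; removing it makes
#' displacements comparable across subjects.
#'
#' @param records Movement-record data.frame (see [run_schedule()]).
#' @param baseline_n Number of familiarization trials used for the baseline.
#' @return The records with corrected `displacement_deg`.
#' @export
baseline_correct <- function(records, baseline_n = 15) {
  stopifnot(is.data.frame(records), baseline_n >= 1)
  for (id in unique(records$run_id)) {
    sel <- records$run_id == id
    fam <- which(sel & records$phase == "FAM")
    if (length(fam) < baseline_n) {
      stop(sprintf(
        "run %s has %d familiarization trials; %d required for the baseline",
        id, length(fam), baseline_n))
    }
    base <- mean(records$displacement_deg[fam[seq_len(baseline_n)]])
    records$displacement_deg[sel] <- records$displacement_deg[sel] - base
  }
  records
}

#' Extract the direct-effect or aftereffect series
#'
#' The direct effect of block `b` is the displacement of the first movement
#' of its ON phase, global index `m = (b - 1) * 2P + 1`; the aftereffect is
#' the first movement after the original mapping is restored,
#' `m = (b - 1) * 2P + P + 1`. With several runs/subjects present the
#' displacements are averaged across them at each block (averaging before
#' fitting, the default) unless `average_runs = FALSE`, in which case a list
#' of per-run series is returned.
#'
#' @param records Movement-record data.frame (baseline-corrected or raw).
#' @param kind `"direct"` or `"after"`.
#' @param P Movements per phase; inferred from the records when omitted.
#' @param average_runs Average across runs before returning?
#' @return An `effect_series`: a data.frame with columns `block` and
#'   `value`, with attributes `kind`, `P` and `schedule_id` (or a list of
#'   such data.frames when `average_runs = FALSE`).
#' @export
extract_effect <- function(records, kind = c("direct", "after"), P = NULL,
                           average_runs = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(records))
  main <- records[!is.na(records$m), , drop = FALSE]
  if (nrow(main) == 0L) stop("records contain no post-familiarization movements")
  if (is.null(P)) {
    P <- max(main$m[main$block == 1L]) / 2L
  }
  B <- max(main$block)
  target_m <- (seq_len(B) - 1L) * 2L * P + if (kind == "direct") 1L else P + 1L
  one_series <- function(df) {
    idx <- match(target_m, df$m)
    if (anyNA(idx)) {
      stop(sprintf("records are missing movement index %d",
                   target_m[which(is.na(idx))[1]]))
    }
    structure(
      data.frame(block = seq_len(B), value = df$displacement_deg[idx]),
      kind = kind, P = P, schedule_id = df$schedule_id[1],
      class = c("effect_series", "data.frame"))
  }
  runs <- split(main, main$run_id)
  if (!average_runs) {
    return(lapply(runs, one_series))
  }
  per_run <- vapply(runs, function(df) one_series(df)$value, numeric(B))
  vals <- if (is.matrix(per_run)) rowMeans(per_run) else per_run
  structure(
    data.frame(block = seq_len(B), value = vals),
    kind = kind, P = P, schedule_id = main$schedule_id[1],
    class = c("effect_series", "data.frame"))
}

#' Fit an exponential decay plus offset to an effect series
#'
#' Nonlinear least squares fit of
#' `d(b) = d_off + d1 * exp(-(b - 1) / tau_b)` to the per-block series:
#' `d_off` is the final constant offset, `d1` the decaying amplitude
#' anchored at the first block, and `tau_b` the decay constant in block
#' units. Fitting uses Levenberg-Marquardt with a fixed, deterministic
#' initialization policy: `d_off` starts at the mean of the last quartile of
#' the series, `d1` at the first value minus that, and `tau_b` at `B / 3`.
#' The time constant is fitted on the log scale, which keeps it positive
#' without box constraints; its confidence interval is delta-method
#' transformed from the log scale and therefore asymmetric.
#' Confidence intervals are asymptotic (estimate +- 1.96 standard errors
#' from the least-squares covariance). Non-convergence or a degenerate
#' series yields a flagged fit (`converged = FALSE`, `NA` estimates) with
#' the failure message retained, never a silent fallback.
#'
#' @param series An `effect_series` from [extract_effect()], or any
#'   data.frame with columns `block` and `value` (length >= 4).
#' @return An object of class `decay_fit`: a list with elements `d1`,
#'   `d_off`, `tau_b`, `tau_pc`, `tau_m` (the latter two populated when the
#'   series carries its phase length, see [convert_tau()]), `ci` (3 x 2
#'   matrix), `gof` (list with `r_squared` and `sigma`), `converged`,
#'   `message`, `init`, `n_blocks`, `kind` and `P`.
#' @export
fit_exp_offset <- function(series) {
  stopifnot(is.data.frame(series), all(c("block", "value") %in% names(series)))
  B <- nrow(series)
  if (B < 4L) stop("need at least 4 blocks to fit 3 parameters")
  v <- series$value
  b <- series$block
  last_q <- v[b > stats::quantile(b, 0.75)]
  if (length(last_q) == 0L) last_q <- v[B]
  init <- c(d1 = v[1] - mean(last_q), d_off = mean(last_q), tau_b = B / 3)
  # residuals and analytic Jacobian in (d1, d_off, log_tau); the log
  # parameterization keeps tau positive without box constraints
  # log_tau is clamped to a generous range inside the model functions so
  # extreme optimizer excursions cannot overflow the exponentials
  lt_range <- c(log(1e-3), log(1e4 * B))
  res_fn <- function(p) {
    k <- exp(-min(max(p[3], lt_range[1]), lt_range[2]))
    v - (p[2] + p[1] * exp(-(b - 1) * k))
  }
  jac_fn <- function(p) {
    k <- exp(-min(max(p[3], lt_range[1]), lt_range[2]))
    e <- exp(-(b - 1) * k)
    -cbind(e, 1, p[1] * e * (b - 1) * k)
  }
  # deterministic multi-start: the policy start plus extreme-amplitude and
  # slow-decay alternatives, keeping the lowest-deviance solution; guards
  # against the degenerate single-point local minimum when the first block
  # is atypical
  d_off0 <- init[["d_off"]]
  starts <- expand.grid(
    d1 = unique(c(init[["d1"]], max(v) - d_off0, min(v) - d_off0)),
    log_tau = log(c(B / 3, B))
  )
  fit <- NULL
  for (si in seq_len(nrow(starts))) {
    cand <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(starts$d1[si], d_off0, starts$log_tau[si]),
        fn = res_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) e
    )
    if (inherits(cand, "error")) {
      if (is.null(fit)) fit <- cand
      next
    }
    if (!is.finite(cand$deviance)) next
    if (is.null(fit) || inherits(fit, "error") ||
        cand$deviance < fit$deviance) {
      fit <- cand
    }
  }
  out <- list(d1 = NA_real_, d_off = NA_real_, tau_b = NA_real_,
              tau_pc = NA_real_, tau_m = NA_real_,
              ci = matrix(NA_real_, 3, 2,
                          dimnames = list(c("d1", "d_off", "tau_b"),
                                          c("lower", "upper"))),
              gof = list(r_squared = NA_real_, sigma = NA_real_),
              converged = FALSE, message = NULL, init = init,
              n_blocks = B,
              kind = attr(series, "kind"), P = attr(series, "P"),
              schedule_id = attr(series, "schedule_id"))
  class(out) <- "decay_fit"
  if (is.null(fit)) {
    out$message <- "optimization produced no finite solution"
    return(out)
  }
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  est <- fit$par
  est[3] <- min(max(est[3], lt_range[1]), lt_range[2])
  out$d1 <- est[1]
  out$d_off <- est[2]
  out$tau_b <- exp(est[3])
  res <- res_fn(est)
  # asymptotic covariance of the least-squares estimate
  se <- tryCatch({
    J <- jac_fn(est)
    s2 <- sum(res^2) / max(1L, B - 3L)
    sqrt(diag(s2 * solve(crossprod(J))))
  }, error = function(e) rep(NA_real_, 3))
  out$ci <- rbind(
    d1 = c(est[1] - 1.96 * se[1], est[1] + 1.96 * se[1]),
    d_off = c(est[2] - 1.96 * se[2], est[2] + 1.96 * se[2]),
    tau_b = exp(c(est[3] - 1.96 * se[3], est[3] + 1.96 * se[3]))
  )
  colnames(out$ci) <- c("lower", "upper")
  ss_tot <- sum((v - mean(v))^2)
  out$gof <- list(
    r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
    sigma = sqrt(sum(res^2) / max(1L, B - 3L))
  )
  # a vanishing amplitude or an unbounded time constant means the decay is
  # unidentifiable on this series; keep estimates but flag the fit
  identifiable <- fit$info %in% 1:4 && is.finite(out$tau_b) &&
    out$tau_b < 100 * B && out$tau_b > 1e-2 &&
    abs(out$d1) > 1e-8 * max(1, abs(out$d_off))
  out$converged <- identifiable
  if (!identifiable) out$message <- "decay unidentifiable (flat series or unbounded tau)"
  if (!is.null(out$P) && is.finite(out$tau_b)) {
    out$tau_pc <- 2 * out$tau_b
    out$tau_m <- 2 * out$P * out$tau_b
  }
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", if (!x$converged) "(flagged)" else "", "\n")
  cat(sprintf("  d1 = %.4g deg, d_off = %.4g deg, tau_b = %.4g blocks\n",
              x$d1, x$d_off, x$tau_b))
  if (is.finite(x$tau_m)) {
    cat(sprintf("  tau_pc = %.4g phase changes, tau_m = %.4g movements (P = %d)\n",
                x$tau_pc, x$tau_m, x$P))
  }
  cat(sprintf("  R^2 = %.4g, residual sigma = %.4g (%d blocks)\n",
              x$gof$r_squared, x$gof$sigma, x$n_blocks))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' Normalize an effect series by its fitted decay
#'
#' Removes the estimated offset and divides by the estimated first-block
#' amplitude: `(d(b) - d_off) / d1`. The fitted curve itself normalizes to
#' `exp(-(b - 1) / tau_b)`, starting at 1 and decaying to 0, which makes
#' series from different schedules directly comparable.
#'
#' @param series An `effect_series`.
#' @param fit The corresponding [fit_exp_offset()] result.
#' @return The series with normalized `value`.
#' @export
normalize_series <- function(series, fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!fit$converged) stop("cannot normalize by a flagged fit")
  if (abs(fit$d1) < 1e-12) stop("fitted first-block amplitude is near zero")
  series$value <- (series$value - fit$d_off) / fit$d1
  series
}

#' Convert a decay constant between unit systems
#'
#' `tau_b` (blocks) converts to `tau_pc = 2 * tau_b` phase changes (each
#' block contains an ON-to-OFF and an OFF-to-ON switch) and to
#' `tau_m = 2 * P * tau_b` movements. If adaptation speed depended only on
#' phase changes, `tau_pc` would be constant across schedules; if it
#' depended only on executed movements, `tau_m` would be.
#'
#' @param fit A [fit_exp_offset()] result.
#' @param P Movements per phase.
#' @return The fit with `tau_pc` and `tau_m` populated.
#' @export
convert_tau <- function(fit, P) {
  stopifnot(inherits(fit, "decay_fit"), P >= 1)
  fit$P <- as.integer(P)
  fit$tau_pc <- 2 * fit$tau_b
  fit$tau_m <- 2 * P * fit$tau_b
  fit
}

#' Compare decay constants across schedules
#'
#' Summarizes per-schedule decay fits in both unit systems and reports the
#' max/min ratio of `tau_m` and of `tau_pc` together with a
#' confidence-interval overlap flag. The movement-invariance hypothesis
#' (adaptation speed set by the number of executed movements, not by the
#' number of phase changes) is supported when the `tau_m` intervals overlap
#' while `tau_pc` spreads in proportion to P.
#'
#' @param fits List of [fit_exp_offset()] results (each with `P` set).
#' @return An object of class `schedule_comparison`: list with `table`
#'   (per-schedule data.frame), `tau_m_ratio`, `tau_pc_ratio` and
#'   `tau_m_ci_overlap`.
#' @export
compare_schedules <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "decay_fit")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    if (is.null(f$P)) stop("every fit needs its phase length P (convert_tau)")
    data.frame(
      schedule_id = if (is.null(f$schedule_id)) NA_character_ else f$schedule_id,
      P = f$P,
      tau_b = f$tau_b,
      tau_pc = f$tau_pc,
      tau_m = f$tau_m,
      tau_m_lower = 2 * f$P * f$ci["tau_b", "lower"],
      tau_m_upper = 2 * f$P * f$ci["tau_b", "upper"],
      converged = f$converged,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  overlap <- TRUE
  n <- nrow(tab)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (tab$tau_m_lower[i] > tab$tau_m_upper[j] ||
          tab$tau_m_lower[j] > tab$tau_m_upper[i]) {
        overlap <- FALSE
      }
    }
  }
  structure(list(
    table = tab,
    tau_m_ratio = max(tab$tau_m) / min(tab$tau_m),
    tau_pc_ratio = max(tab$tau_pc) / min(tab$tau_pc),
    tau_m_ci_overlap = overlap
  ), class = "schedule_comparison")
}

#' @export
print.schedule_comparison <- function(x, ...) {
  cat("<schedule_comparison>\n")
  print(x$table, digits = 4)
  cat(sprintf("tau_m max/min ratio:  %.3f (CIs %s)\n", x$tau_m_ratio,
              if (x$tau_m_ci_overlap) "overlap" else "do not all overlap"))
  cat(sprintf("tau_pc max/min ratio: %.3f\n", x$tau_pc_ratio))
  invisible(x)
}

#' Write a fit or comparison report as JSON
#'
#' @param x A `decay_fit` or `schedule_comparison`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "decay_fit")) {
    y <- unclass(x)
    y$ci <- as.data.frame(y$ci)
  } else if (inherits(x, "schedule_comparison")) {
    y <- unclass(x)
  } else {
    stop("unsupported report object")
  }
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a decay-fit report back from JSON
#'
#' Inverse of [write_report_json()] for `decay_fit` objects, so fits written
#' by one analysis invocation can be compared by another (see
#' [compare_schedules()]).
#'
#' @param path File path of a JSON fit report.
#' @return A `decay_fit` object.
#' @export
read_fit_json <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  ci <- as.matrix(y$ci)
  rownames(ci) <- c("d1", "d_off", "tau_b")
  colnames(ci) <- c("lower", "upper")
  y$ci <- ci
  y$gof <- as.list(y$gof)
  if (!is.null(y$init)) y$init <- unlist(y$init)
  class(y) <- "decay_fit"
  y
}
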