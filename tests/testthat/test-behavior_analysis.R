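# small synthetic record tables exercise the pipeline end to end

make_records <- function(P = 5, B = 4, fam = 3, fam_val = 0, run_id = 1,
                         values = NULL) {
  M <- 2 * P * B
  if (is.null(values)) values <- seq_len(M)
  data.frame(
    run_id = run_id,
    schedule_id = sprintf("P%d", P),
    m = c(rep(NA_integer_, fam), seq_len(M)),
    block = c(rep(NA_integer_, fam), rep(seq_len(B), each = 2 * P)),
    phase = c(rep("FAM", fam), rep(rep(c("ON", "OFF"), each = P), times = B)),
    theta_T_deg = 0,
    displacement_deg = c(rep(fam_val, fam), values),
    stringsAsFactors = FALSE
  )
}

test_that("baseline correction subtracts the per-run familiarization mean", {
  rec <- make_records(fam = 15, fam_val = 2)
  out <- baseline_correct(rec, baseline_n = 15)
  expect_equal(out$displacement_deg, rec$displacement_deg - 2)
  # zero-mean familiarization leaves records unchanged
  rec0 <- make_records(fam = 15, fam_val = 0)
  expect_equal(baseline_correct(rec0)$displacement_deg,
               rec0$displacement_deg)
  # too few familiarization trials is an error
  expect_error(baseline_correct(make_records(fam = 3)), "familiarization")
  # a known constant bias is removed to within the noise of its estimate
  set.seed(20)
  beta <- 1.7
  noise_sd <- 0.5
  rec_b <- make_records(fam = 15, values = rep(0, 40))
  rec_b$displacement_deg <- beta + rnorm(nrow(rec_b), 0, noise_sd)
  out_b <- baseline_correct(rec_b, baseline_n = 15)
  resid_bias <- mean(out_b$displacement_deg[out_b$phase != "FAM"])
  expect_lt(abs(resid_bias), 4 * noise_sd / sqrt(15))
})

test_that("effect extraction picks the first movement of each phase", {
  # values equal to m, so extracted values reveal the selected indices
  rec <- make_records(P = 5, B = 4)
  direct <- extract_effect(rec, "direct")
  expect_equal(direct$value, c(1, 11, 21, 31))  # m = (b-1)*2P + 1
  after <- extract_effect(rec, "after")
  expect_equal(after$value, c(6, 16, 26, 36))   # m = (b-1)*2P + P + 1
  expect_identical(attr(direct, "kind"), "direct")
  expect_identical(attr(direct, "P"), 5)

  rec120 <- make_records(P = 120, B = 2, fam = 0)
  expect_equal(extract_effect(rec120, "after")$value[1], 121)

  # prepending familiarization records never changes the extracted series
  rec_nofam <- make_records(P = 5, B = 4, fam = 0)
  expect_equal(extract_effect(rec_nofam, "direct")$value, direct$value)

  # missing indices are an error
  broken <- rec[rec$m != 21 | is.na(rec$m), ]
  expect_error(extract_effect(broken, "direct"), "missing")
})

test_that("extraction averages across runs before fitting", {
  r1 <- make_records(values = rep(1, 40))
  r2 <- make_records(values = rep(3, 40), run_id = 2)
  both <- rbind(r1, r2)
  avg <- extract_effect(both, "direct")
  expect_equal(avg$value, rep(2, 4))
  per_run <- extract_effect(both, "direct", average_runs = FALSE)
  expect_length(per_run, 2)
  expect_equal(per_run[[1]]$value, rep(1, 4))
})

test_that("exponential-plus-offset fit recovers noiseless parameters", {
  s <- decay_series(B = 20, d1 = 8, d_off = 2, tau_b = 6)
  f <- fit_exp_offset(s)
  expect_true(f$converged)
  expect_equal(f$d1, 8, tolerance = 1e-6)
  expect_equal(f$d_off, 2, tolerance = 1e-6)
  expect_equal(f$tau_b, 6, tolerance = 1e-6)
  expect_gt(f$gof$r_squared, 1 - 1e-10)
  # deterministic: identical input, identical fit
  expect_identical(fit_exp_offset(s)$tau_b, f$tau_b)
  # negative-going series (a leftward direct effect) works the same
  s_neg <- decay_series(B = 20, d1 = -12, d_off = -1, tau_b = 3)
  f_neg <- fit_exp_offset(s_neg)
  expect_equal(f_neg$d1, -12, tolerance = 1e-6)
  expect_equal(f_neg$tau_b, 3, tolerance = 1e-6)
})

test_that("degenerate series yield a flagged fit, never a silent fallback", {
  flat <- data.frame(block = 1:10, value = rep(2, 10))
  f <- fit_exp_offset(flat)
  expect_false(f$converged)
  expect_true(is.character(f$message))
  expect_error(normalize_series(flat, f), "flagged")
  expect_error(fit_exp_offset(data.frame(block = 1:3, value = 1:3)),
               "at least 4")
})

test_that("fit is scale-equivariant and normalization is scale-free", {
  set.seed(21)
  s <- decay_series(B = 20, d1 = 8, d_off = 2, tau_b = 6, noise_sd = 0.3)
  f <- fit_exp_offset(s)
  s_k <- s
  s_k$value <- 5 * s$value
  f_k <- fit_exp_offset(s_k)
  expect_equal(f_k$d1, 5 * f$d1, tolerance = 1e-6)
  expect_equal(f_k$d_off, 5 * f$d_off, tolerance = 1e-6)
  expect_equal(f_k$tau_b, f$tau_b, tolerance = 1e-6)
  expect_equal(normalize_series(s_k, f_k)$value, normalize_series(s, f)$value,
               tolerance = 1e-6)
})

test_that("normalized fitted curve is exp(-(b-1)/tau)", {
  s <- decay_series(B = 12, d1 = 10, d_off = 3, tau_b = 4)
  f <- fit_exp_offset(s)
  norm <- normalize_series(s, f)
  expect_equal(norm$value, exp(-(s$block - 1) / 4), tolerance = 1e-6)
  expect_equal(norm$value[1], 1, tolerance = 1e-6)
})

test_that("time constants rescale between unit systems", {
  s <- decay_series(B = 20, d1 = 8, d_off = 2, tau_b = 4)
  f <- convert_tau(fit_exp_offset(s), P = 30)
  expect_equal(f$tau_m, 240)
  expect_equal(f$tau_pc, 8)
  f2 <- convert_tau(f, P = 60)
  expect_equal(f2$tau_pc, 8)   # phase-change units are P-independent
  expect_equal(f2$tau_m, 480)
  # equal tau_m with 24-fold different P means 24-fold different tau_pc
  fa <- convert_tau(fit_exp_offset(decay_series(24, 8, 2, tau_b = 12)), 5)
  fb <- convert_tau(fit_exp_offset(decay_series(24, 8, 2, tau_b = 0.5)), 120)
  expect_equal(fa$tau_m, fb$tau_m, tolerance = 1e-6)
  expect_equal(fa$tau_pc / fb$tau_pc, 24, tolerance = 1e-6)
})

test_that("schedule comparison reports tau spreads and CI overlap", {
  f <- convert_tau(fit_exp_offset(decay_series(20, 8, 2, 4)), 30)
  cmp_same <- compare_schedules(list(f, f))
  expect_equal(cmp_same$tau_m_ratio, 1)
  expect_equal(cmp_same$tau_pc_ratio, 1)
  expect_true(cmp_same$tau_m_ci_overlap)

  # one shared movement-scale constant across all five schedules
  tau_m_true <- 300
  fits <- lapply(c(5, 15, 30, 60, 120), function(P) {
    B <- 1200 / (2 * P)
    convert_tau(fit_exp_offset(decay_series(B, 8, 2, tau_m_true / (2 * P))), P)
  })
  cmp <- compare_schedules(fits)
  expect_equal(cmp$tau_m_ratio, 1, tolerance = 1e-4)
  expect_equal(cmp$tau_pc_ratio, 24, tolerance = 1e-4)
})
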