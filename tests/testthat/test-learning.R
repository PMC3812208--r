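test_that("gradient step is stationary at the dual solution and reduces loss", {
  p <- model_params()
  ds <- dual_solution(p, theta_T = 0, shift = -15)
  tr_on <- trial_spec(0, condition(-15, 1L), p)
  tr_off <- trial_spec(0, condition(0, 0L), p)
  s1 <- gradient_step(ds$state, tr_on, p)
  expect_equal(s1$w, ds$state$w, tolerance = 1e-10)
  expect_equal(s1$w_c, ds$state$w_c, tolerance = 1e-10)

  # a perturbed state strictly reduces its loss in one small step
  set.seed(1)
  pert <- model_state(pmax(0, ds$state$w + rnorm(p$n_channels, 0, 0.2)),
                      ds$state$w_c + 0.05)
  p_small <- model_params(eta_w = 1e-3, eta_c = 1e-4)
  s2 <- gradient_step(pert, tr_on, p_small)
  expect_lt(trial_loss(s2, tr_on, p_small), trial_loss(pert, tr_on, p_small))

  # cue off: w_c untouched no matter the error
  s3 <- gradient_step(pert, tr_off, p)
  expect_identical(s3$w_c, pert$w_c)
})

test_that("gradient step matches the central-difference gradient", {
  p <- params21(eta_w = 1e-4, eta_c = 1e-5)
  set.seed(2)
  st <- model_state(analytic_normal_state(p)$w * runif(21, 0.8, 1.2) + 0.3,
                    0.1)
  tr <- trial_spec(10, condition(-15, 1L), p)
  g <- num_gradient(st, tr, p)
  s1 <- gradient_step(st, tr, p)
  expect_equal(s1$w - st$w, -p$eta_w * g[1:21], tolerance = 1e-6)
  expect_equal(s1$w_c - st$w_c, -p$eta_c * g[22], tolerance = 1e-6)
})

test_that("stochastic step without exploration leaves the state unchanged", {
  p <- model_params(sigma_w = 0, sigma_c = 0)
  st <- analytic_normal_state(p)
  tr <- trial_spec(0, condition(-15, 1L), p)
  res <- stochastic_step(st, tr, p)
  expect_identical(res$state$w, st$w)
  expect_identical(res$state$w_c, st$w_c)
  expect_equal(res$displacement, -15)
})

test_that("stochastic update follows -eta * xi * deltaL with clamping", {
  p <- params21()
  set.seed(3)
  st <- model_state(analytic_normal_state(p)$w * runif(21, 0.9, 1.1) + 0.3,
                    0.08)
  tr <- trial_spec(5, condition(-15, 1L), p)
  a <- input_activation(tr, p)
  for (k in 1:20) {
    seed <- 100 + k
    # replay the RNG to reconstruct the perturbation draws
    set.seed(seed)
    xw <- rnorm(p$n_channels, 0, p$sigma_w)
    xc <- rnorm(1, 0, p$sigma_c)
    r <- readout(st, a)
    phi <- (1 + st$w_c) * r - p$phi0
    phip <- (1 + (st$w_c + xc)) * (r + sum(xw * a)) - p$phi0
    dl <- (phip - 5)^2 - (phi - 5)^2
    set.seed(seed)
    res <- stochastic_step(st, tr, p)
    expect_equal(res$state$w, pmax(0, st$w - p$eta_w * dl * xw),
                 tolerance = 1e-12)
    expect_equal(res$state$w_c, max(0, st$w_c - p$eta_c * dl * xc),
                 tolerance = 1e-12)
    expect_equal(res$displacement, phip - 5, tolerance = 1e-12)
    # a loss-reducing perturbation is retained in its own direction
    if (dl < 0) {
      moved <- abs(xw) > 1e-8
      expect_true(all(sign(res$state$w - st$w)[moved] == sign(xw)[moved]))
    }
  }
})

test_that("weights never go negative over random update sequences", {
  # exploration strong enough that raw updates regularly cross zero at the
  # small edge weights
  p <- params21(sigma_w = 0.08, sigma_c = 0.02, eta_w = 0.3, eta_c = 0.03)
  set.seed(4)
  # mis-scaled weights give sizable errors; tiny entries sit right at the
  # clamping boundary
  w0 <- pmax(analytic_normal_state(p)$w * 0.9 + rnorm(21, 0, 0.1), 0.001)
  st <- model_state(w0, 0.05)
  clamped <- 0L
  for (i in 1:300) {
    tr <- trial_spec(sample(seq(-20, 20, 10), 1),
                     condition(sample(c(-15, 0), 1)), p)
    new <- stochastic_step(st, tr, p)$state
    clamped <- clamped + sum(new$w == 0 & st$w > 0)
    st <- new
    expect_true(all(st$w >= 0))
    expect_gte(st$w_c, 0)
  }
  expect_gt(clamped + sum(st$w == 0), 0)  # clamping was actually exercised
})

test_that("expected stochastic update is proportional to the gradient", {
  # quick Monte-Carlo version; the full-precision check lives in the
  # acceptance suite
  p <- params21(sigma_w = 0.002, sigma_c = 0.002)
  set.seed(5)
  st <- model_state(analytic_normal_state(p)$w * runif(21, 0.8, 1.2) + 0.3,
                    0.1)
  tr <- trial_spec(0, condition(-15, 1L), p)
  g <- num_gradient(st, tr, p)

  p_sp <- p; p_sp$sigma_c <- 0
  mc <- stochastic_update_expectation(st, tr, p_sp, n_draws = 2e4)
  pred <- -p$eta_w * p$sigma_w^2 * g[1:21]
  keep <- abs(g[1:21]) > 0.2 * max(abs(g[1:21]))
  expect_lt(max(abs(mc$dw[keep] - pred[keep]) / abs(pred[keep])), 0.2)

  p_c <- p; p_c$sigma_w <- 0
  mcc <- stochastic_update_expectation(st, tr, p_c, n_draws = 2e4)
  expect_equal(mcc$dw_c, -p$eta_c * p$sigma_c^2 * g[22], tolerance = 0.05)
})

test_that("pretraining learns the normal mapping with the cue off", {
  p <- model_params()
  set.seed(6)
  st <- pretrain(p, target_range = c(-50, 50), n_targets = 3000,
                 iters_per_target = 10, n_runs = 2, tol = 2)
  expect_s3_class(st, "model_state")
  expect_identical(st$w_c, 0)  # gain never engaged during pre-training
  expect_lt(attr(st, "probe_max_abs_error"), 2)
  # probe errors are recorded per target
  expect_true(all(is.finite(attr(st, "probe_errors"))))
  # a hopeless budget is flagged, not silent
  set.seed(7)
  expect_warning(
    pretrain(p, target_range = c(-50, 50), n_targets = 5, n_runs = 1,
             tol = 0.5),
    "did not reach tolerance")
})

test_that("run-averaged pretraining is closer to the target mapping", {
  p <- model_params()
  probe <- function(s) {
    max(abs(sapply(seq(-20, 20, 10), function(t) {
      pointing_error(s, t, 0, 0L, p)
    })))
  }
  set.seed(8)
  singles <- replicate(3, {
    probe(suppressWarnings(
      pretrain(p, target_range = c(-50, 50), n_targets = 1200, n_runs = 1)))
  })
  set.seed(8)
  averaged <- probe(suppressWarnings(
    pretrain(p, target_range = c(-50, 50), n_targets = 1200, n_runs = 3)))
  expect_lt(averaged, max(singles))
})
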