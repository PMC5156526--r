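test_that("survival curve counts dwells on the frame grid", {
  s <- dwell_survival(c(0.5, 1.0, 1.5), frame_interval = 0.5)
  expect_equal(s$time_s, c(0.5, 1.0, 1.5))
  expect_equal(s$survival, c(1, 2 / 3, 1 / 3))
  # all dwells equal: a single step
  s2 <- dwell_survival(rep(2, 10), frame_interval = 0.5)
  expect_equal(s2$survival, rep(1, 4))
  expect_error(dwell_survival(numeric(0), frame_interval = 0.5), "empty")
})

test_that("every survival curve starts at 1 and is non-increasing", {
  for (seed in 1:5) {
    dw <- simulate_slow_tracking_dwells(runif(1), 2, 0.1, 0.05, slow_acq(),
                                        500, seed = seed)
    s <- dwell_survival(dw)
    expect_equal(s$survival[1], 1)
    expect_true(all(diff(s$survival) <= 1e-12))
    expect_true(all(s$survival >= 0 & s$survival <= 1))
  }
})

test_that("a noiseless two-exponential curve is recovered to numerical precision", {
  tt <- seq(0.5, 40, by = 0.5)
  truth <- c(F = 0.6, k_ns = 1.2, k_s = 0.1)
  ss <- truth["F"] * exp(-truth["k_ns"] * tt) +
    (1 - truth["F"]) * exp(-truth["k_s"] * tt)
  curve <- structure(data.frame(time_s = tt, survival = ss),
                     n_events = 1000, frame_interval = 0.5,
                     class = c("survival_curve", "data.frame"))
  fit <- fit_two_exponential(curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$F - truth[["F"]]) / truth[["F"]], 1e-6)
  expect_lt(abs(fit$k_off_emp_ns - truth[["k_ns"]]) / truth[["k_ns"]], 1e-6)
  expect_lt(abs(fit$k_off_emp_s - truth[["k_s"]]) / truth[["k_s"]], 1e-6)
  # slower component is always reported as the specific one
  expect_gte(fit$k_off_emp_ns, fit$k_off_emp_s)
})

test_that("single-exponential dwell data yield the generating rate", {
  dw <- simulate_slow_tracking_dwells(0, 1, 0.3, 0, slow_acq(), 5000, seed = 21)
  fit <- fit_two_exponential(dwell_survival(dw))
  expect_lt(abs(fit$k_off_emp_s - 0.30), 0.02)
})

test_that("mixture dwell data recover the slow empirical rate across seeds", {
  for (seed in 1:3) {
    dw <- simulate_slow_tracking_dwells(0.7, 2.0, 0.13, 0, slow_acq(), 5000,
                                        seed = seed)
    fit <- fit_two_exponential(dwell_survival(dw))
    expect_lt(abs(fit$k_off_emp_s - 0.13) / 0.13, 0.15)
  }
})

test_that("photobleaching rate comes from the slow component of the control", {
  acq <- slow_acq()
  # H2B-like control: negligible true unbinding, bleach-limited dwells
  ctrl <- simulate_slow_tracking_dwells(0.3, 0.5, 1e-4, 0.05, acq, 5000,
                                        seed = 31)
  k_pb <- photobleach_rate(dwell_survival(ctrl))
  expect_lt(abs(as.numeric(k_pb) - (0.05 + 1e-4)), 0.005)
  # zero-bleach noiseless control degenerates toward zero, with a warning
  tt <- seq(0.5, 50, by = 0.5)
  flat <- structure(data.frame(time_s = tt,
                               survival = 0.3 * exp(-0.5 * tt) + 0.7),
                    n_events = 1000, frame_interval = 0.5,
                    class = c("survival_curve", "data.frame"))
  expect_warning(k0 <- photobleach_rate(flat), "degenerate")
  expect_lte(as.numeric(k0), 1e-3)
})

test_that("bleach correction follows the printed rate identity", {
  fit <- structure(list(k_off_emp_s = 0.3), class = "twoexp_fit")
  res <- correct_residence(fit, 0.1)
  expect_equal(res$k_off_s, 0.2)
  expect_equal(res$tau_s, 5)
  expect_equal(correct_residence(fit, 0)$tau_s, 1 / 0.3)
  expect_error(correct_residence(structure(list(k_off_emp_s = 0.05),
                                           class = "twoexp_fit"), 0.05),
               "unidentifiable")
})

test_that("relative residence time is a plain percentage ratio", {
  expect_equal(relative_residence(5, 5), 100)
  expect_equal(relative_residence(0.54 * 12.5, 12.5), 54)
  expect_error(relative_residence(0, 1), "> 0")
})

test_that("corrected residence recovers truth while the uncorrected is biased low", {
  # grid of mixtures: corrected tau within 15% of 1/k_s; uncorrected biased
  # by the predictable factor k_s / (k_s + k_pb)
  grid <- expand.grid(k_s = c(0.08, 0.15), k_pb = c(0.05, 0.1))
  for (i in seq_len(nrow(grid))) {
    k_s <- grid$k_s[i]; k_pb <- grid$k_pb[i]
    dw <- simulate_slow_tracking_dwells(0.7, 2.0, k_s, k_pb, slow_acq(400),
                                        5000, seed = 100 + i)
    fit <- fit_two_exponential(dwell_survival(dw))
    res <- correct_residence(fit, k_pb)
    expect_lt(abs(res$tau_s - 1 / k_s) * k_s, 0.15)
    bias <- (1 / fit$k_off_emp_s) / (1 / k_s)
    expect_lt(abs(bias - k_s / (k_s + k_pb)), 0.1)
  }
})
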