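test_that("likelihood matches closed-form binomial terms", {
  # one trial of 2 prey, model predicting exactly half consumed
  one <- make_trials(n0 = 2, ne = 1)
  expect_equal(neg_log_likelihood(one, "holling2", list(a = 0.5, h = 0)),
               -log(2 * 0.5 * 0.5), tolerance = 1e-12)
  # zero attack rate: predicted p clipped at 1e-9, NLL ~ 0
  zero <- make_trials(n0 = 5, ne = 0)
  expect_lt(neg_log_likelihood(zero, "rogers2", list(a = 0, h = 0.1)), 1e-6)
  # impossible parameters are optimizer-safe infinity, not an error
  expect_identical(neg_log_likelihood(one, "rogers2", list(a = NaN, h = 0.1)), Inf)
})

test_that("likelihood is additive over trials (brute-force oracle)", {
  ts <- design_experiment("rogers2", list(a = 0.9, h = 0.015), seed = 9)
  pars <- list(a = 0.7, h = 0.02)
  whole <- neg_log_likelihood(ts, "rogers2", pars)
  per_trial <- vapply(seq_len(nrow(ts)), function(i) {
    p <- predict_rogers2(pars$a, pars$h, ts$n0[i], ts$t_expose[i]) / ts$n0[i]
    -dbinom(ts$ne[i], ts$n0[i], min(max(p, 1e-9), 1 - 1e-9), log = TRUE)
  }, numeric(1))
  expect_equal(whole, sum(per_trial), tolerance = 1e-10)
})

test_that("Wald statistics reproduce printed-table arithmetic", {
  ws <- wald_stats(0.9797, 0.1138)
  expect_equal(ws$z, 8.6089, tolerance = 1e-4)
  expect_lt(ws$p, 1e-4)
  expect_equal(wald_stats(0, 1), list(z = 0, p = 1))
  expect_equal(wald_stats(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  expect_error(wald_stats(1, 0), "positive")
})

test_that("maximum-likelihood fit recovers the generating type II parameters", {
  set.seed(21)
  fits <- lapply(1:40, function(i) {
    ts <- design_experiment("rogers2", list(a = 0.9797, h = 0.0104))
    fit_fr(ts, "rogers2")
  })
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  a_hat <- vapply(fits, function(f) f$estimates[["a"]], numeric(1))
  h_hat <- vapply(fits, function(f) f$estimates[["h"]], numeric(1))
  expect_lt(abs(median(a_hat) / 0.9797 - 1), 0.10)
  expect_lt(abs(median(h_hat) / 0.0104 - 1), 0.25)  # h is noisy at 6 reps
  # AIC and MFr invariants hold on every fit
  for (f in fits[1:5]) {
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$mfr, 1 / (f$estimates[["h"]] * f$t_expose))
    expect_equal(unname(f$z), unname(f$estimates / f$se))
  }
})

test_that("fixed q = 0 flexible fits are reported as the type II model they are", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.02), seed = 31)
  fit <- fit_fr(ts, "flexq", fix_q = 0)
  expect_equal(fit$family, "rogers2")
  expect_named(fit$estimates, c("a", "h"))
  expect_false("q" %in% names(fit$estimates))
  # and it is numerically identical to fitting rogers2 directly
  direct <- fit_fr(ts, "rogers2")
  expect_equal(fit$estimates, direct$estimates, tolerance = 1e-10)
})

test_that("starting handling time follows the 1/Fmax rule", {
  # mean consumption at the top density is exactly 40 -> start h = 0.025
  ts <- make_trials(n0 = rep(c(5, 10, 25, 50, 80), each = 2),
                    ne = c(2, 3, 4, 5, 10, 12, 20, 22, 40, 40))
  fit <- fit_fr(ts, "rogers2")
  expect_equal(fit$starts_used[[1]][["h"]], 1 / 40)
  expect_equal(fit$starts_used[[1]][["a"]], 1)
})

test_that("flexible-q fits recover a strongly sigmoidal truth", {
  set.seed(41)
  ts <- design_experiment("flexq", list(b = 0.0028, q = 2.1645, h = 0.0228),
                          reps = 30)
  fit <- fit_fr(ts, "flexq")
  expect_true(fit$converged)
  expect_gt(fit$estimates[["q"]], 1)
  expect_equal(fit$estimates[["h"]], 0.0228, tolerance = 0.35)
  # nesting: flexible likelihood dominates the fixed-q = 0 likelihood
  fixed <- fit_fr(ts, "flexq", fix_q = 0)
  expect_gte(fit$loglik, fixed$loglik - 1e-6)
})

test_that("fits are deterministic given data and RNG state", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.02), seed = 51)
  f1 <- withr::with_seed(99, fit_fr(ts, "rogers2"))
  f2 <- withr::with_seed(99, fit_fr(ts, "rogers2"))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$se, f2$se)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("bootstrap intervals bracket the estimate and honour the contract", {
  ts <- design_experiment("rogers2", list(a = 0.9797, h = 0.0104), seed = 61)
  fit <- fit_fr(ts, "rogers2")
  bt <- bootstrap_ci(ts, fit = fit, n_boot = 200, seed = 62)
  expect_equal(bt$method, "percentile")
  expect_equal(bt$n_boot, 200L)
  expect_true(all(bt$ci$conf.low <= bt$ci$estimate + 1e-9))
  expect_true(all(bt$ci$conf.high >= bt$ci$estimate - 1e-9))
  expect_lt(bt$frac_nonconverged, 0.5)
  # reproducible under the same seed
  bt2 <- bootstrap_ci(ts, fit = fit, n_boot = 200, seed = 62)
  expect_identical(bt$ci, bt2$ci)
  expect_error(bootstrap_ci(ts, fit = fit, n_boot = 0), "positive")
})

test_that("zero-variance data give degenerate bootstrap intervals", {
  # same consumption in every replicate of every density
  ts <- make_trials(n0 = rep(c(5, 10, 25, 50, 80), each = 4),
                    ne = rep(c(3, 6, 14, 24, 33), each = 4))
  fit <- fit_fr(ts, "rogers2")
  # stratified resampling preserves the density composition, so each
  # resample is literally the original data set here
  bt <- bootstrap_ci(ts, fit = fit, n_boot = 50, seed = 1, stratify = TRUE)
  width <- bt$ci$conf.high - bt$ci$conf.low
  expect_lt(max(width / pmax(bt$ci$estimate, 1e-12)), 1e-6)
})

test_that("tidy and glance carry the fit summaries", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.02), seed = 71)
  fit <- fit_fr(ts, "rogers2")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "h"))
  expect_equal(td$statistic, unname(fit$estimates / fit$se))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$AIC, fit$aic)
})
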