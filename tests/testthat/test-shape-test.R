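test_that("hyperbolically declining consumption is classified as type II shaped", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.01), reps = 20, seed = 101)
  st <- fit_shape_test(ts)
  expect_equal(st$inferred_shape, "hyperbolic")
  lin <- st$coefficients[st$coefficients$term == "linear", ]
  expect_lt(lin$estimate, 0)
  expect_lt(lin$p.value, 0.05)
  # independent check: the raw proportion-vs-density slope is negative too
  slope <- coef(lm(I(ts$ne / ts$n0) ~ ts$n0))[2]
  expect_lt(slope, 0)
})

test_that("density-dependent attack produces a sigmoidal call with power growing in replication", {
  ts <- design_experiment("flexq", list(b = 0.02, q = 1, h = 0.02),
                          reps = 100, seed = 202)
  st <- fit_shape_test(ts)
  expect_equal(st$inferred_shape, "sigmoidal")
  expect_gt(st$coefficients$estimate[st$coefficients$term == "linear"], 0)
})

test_that("published-scale coefficient vectors classify by linear-term sign", {
  expect_equal(classify_shape(-0.5728, p_value = 0.0249), "hyperbolic")
  expect_equal(classify_shape(3.2579, p_value = 1e-7), "sigmoidal")
  expect_equal(classify_shape(-0.5728, p_value = 0.0769), "indeterminate")
  expect_equal(classify_shape(NaN, p_value = 0.01), "indeterminate")
})

test_that("classification is invariant to duplicating the whole data set", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.01), reps = 20, seed = 303)
  st1 <- fit_shape_test(ts)
  doubled <- trial_set(rbind(tibble::as_tibble(as.data.frame(ts)),
                             tibble::as_tibble(as.data.frame(ts))))
  st2 <- fit_shape_test(doubled)
  expect_equal(st2$inferred_shape, st1$inferred_shape)
  # at fixed polynomial degree: estimates unchanged, standard errors shrink
  d1 <- fit_shape_test(ts, max_degree = 1)
  d2 <- fit_shape_test(doubled, max_degree = 1)
  # raw-scale estimates are free of the (n-dependent) standardization, so
  # the duplicated fit reproduces them exactly
  expect_equal(d2$raw_coefficients$estimate, d1$raw_coefficients$estimate,
               tolerance = 1e-8)
  expect_true(all(d2$coefficients$std.error < d1$coefficients$std.error))
})

test_that("backward elimination drops top terms but never the linear one", {
  # nearly density-independent proportions: cubic and quadratic superfluous
  set.seed(404)
  n0 <- rep(c(5, 10, 25, 50, 80), each = 8)
  ts <- make_trials(n0 = n0, ne = rbinom(length(n0), n0, 0.4))
  st <- fit_shape_test(ts)
  expect_lte(st$retained_degree, 3)
  expect_true("linear" %in% st$coefficients$term)
  st1 <- fit_shape_test(ts, max_degree = 1)
  expect_equal(st1$retained_degree, 1)
  expect_error(fit_shape_test(make_trials(c(5, 5), c(1, 2))),
               "two distinct densities")
})

test_that("raw-scale coefficients are an exact reparameterization of the fit", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.01), reps = 20, seed = 55)
  st <- fit_shape_test(ts)
  # rebuild the fitted linear predictor from raw-scale coefficients
  beta <- st$raw_coefficients$estimate
  eta_raw <- vapply(ts$n0, function(x) sum(beta * x^(0:(length(beta) - 1))),
                    numeric(1))
  eta_std <- predict(st$glm_fit, type = "link")
  expect_equal(unname(eta_raw), unname(eta_std), tolerance = 1e-8)
  # degree-1 fits: sign of the linear term agrees across scales
  st1 <- fit_shape_test(ts, max_degree = 1)
  expect_equal(sign(st1$raw_coefficients$estimate[2]),
               sign(st1$coefficients$estimate[2]))
})

test_that("tidy and glance expose the shape-test results", {
  ts <- design_experiment("rogers2", list(a = 1, h = 0.01), reps = 10, seed = 66)
  st <- fit_shape_test(ts)
  td <- tidy(st)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  g <- glance(st)
  expect_equal(g$n_trials, 50)
  expect_true(g$inferred_shape %in% c("hyperbolic", "sigmoidal", "indeterminate"))
})
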