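test_that("Holling disc equation matches hand arithmetic and limits", {
  expect_equal(predict_holling2(a = 1, h = 0.1, N = 10, T_ = 1), 5)
  expect_equal(predict_holling2(a = 0, h = 0.1, N = 50, T_ = 1), 0)
  # saturation: Ne -> T/h as N -> Inf
  expect_equal(predict_holling2(a = 2, h = 0.5, N = 1e12, T_ = 1), 2,
               tolerance = 1e-6)
  expect_error(predict_holling2(a = -1, h = 0.1, N = 10), "non-negative")
  expect_error(predict_holling2(a = 1, h = 0.1, N = 10, T_ = 0), "positive")
})

test_that("Lambert W kernel satisfies the defining identity over 60 decades", {
  x <- c(0, 10^seq(-12, 300, length.out = 200))
  w <- lambert_w0(x)
  expect_true(all(is.finite(w)))
  expect_lt(max(abs(w * exp(w) - x) / pmax(x, 1e-12)), 1e-12)
  # log-domain branch agrees with the direct branch where both are usable
  lx <- seq(500, 690, length.out = 25)
  expect_equal(funcresp:::lambert_w0_log(lx), lambert_w0(exp(lx)),
               tolerance = 1e-12)
  expect_error(lambert_w0(-0.5), "non-negative")
})

test_that("Rogers solution handles the closed-form edge cases", {
  expect_equal(predict_rogers2(a = 0, h = 0.05, N0 = 40), 0)
  expect_equal(predict_rogers2(a = 1, h = 0, N0 = 10), 10 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(predict_rogers2(a = 1, h = 0.01, N0 = 0), 0)
})

test_that("Rogers Lambert-W solution agrees with the fixed-point oracle", {
  # published-magnitude parameter sets
  expect_equal(predict_rogers2(0.9797, 0.0104, 80),
               rogers_oracle(0.9797, 0.0104, 80), tolerance = 1e-8)
  expect_equal(predict_flexq(0.0028, 2.1645, 0.0228, 80),
               rogers_oracle(0.0028 * 80^2.1645, 0.0228, 80), tolerance = 1e-8)
  expect_equal(predict_hassell3(0.3, 0.05, 0.1, 0.02, 50),
               rogers_oracle((0.1 + 0.3 * 50) / (1 + 0.05 * 50), 0.02, 50),
               tolerance = 1e-8)

  # randomized grid with residual verification
  set.seed(42)
  n <- 250
  a <- runif(n, 0.01, 3); h <- runif(n, 0.001, 0.5)
  n0 <- sample(1:200, n, replace = TRUE); T_ <- sample(c(0.5, 1, 2), n, TRUE)
  ne <- predict_rogers2(a, h, n0, T_)
  orac <- mapply(rogers_oracle, a, h, n0, T_)
  expect_lt(max(abs(ne - orac)), 1e-8)
  resid <- abs(ne - n0 * (1 - exp(a * (h * ne - T_))))
  expect_lt(max(resid), 1e-10)
  expect_true(all(ne >= 0 & ne <= n0))
})

test_that("consumption is monotone in density, attack rate and time, and saturates", {
  n0 <- 1:150
  ne <- predict_rogers2(0.8, 0.03, n0)
  expect_true(all(diff(ne) >= -1e-12))
  a_grid <- seq(0.05, 3, length.out = 60)
  expect_true(all(diff(predict_rogers2(a_grid, 0.03, 50)) >= -1e-12))
  T_grid <- seq(0.25, 4, length.out = 40)
  expect_true(all(diff(predict_rogers2(0.8, 0.03, 50, T_grid)) >= -1e-12))
  # saturation limit T/h
  expect_equal(predict_rogers2(1, 0.05, 1e5), 1 / 0.05, tolerance = 1e-3)
})

test_that("flexible-q family reduces exactly to Rogers at q = 0 and nests type III", {
  n0 <- c(5, 10, 25, 50, 80)
  expect_identical(predict_flexq(0.5, 0, 0.02, n0),
                   predict_rogers2(0.5, 0.02, n0))
  # q = 1: effective attack rate b*N0, the Hassell special case d = c = 0
  expect_equal(predict_flexq(0.02, 1, 0.02, n0),
               predict_hassell3(0.02, 0, 0, 0.02, n0), tolerance = 1e-12)
  # proportion consumed rises with density at small N0 when q = 1
  prop <- predict_flexq(0.005, 1, 0.01, 1:20) / (1:20)
  expect_true(all(diff(prop[1:10]) > 0))
  # N0 = 0 with negative q is defined as zero consumption
  expect_equal(predict_flexq(0.5, -1, 0.02, 0), 0)
})

test_that("Hassell type III reduces to Rogers when density dependence vanishes", {
  n0 <- c(5, 25, 80)
  expect_equal(predict_hassell3(b = 0, c = 0, d = 0.7, h = 0.03, N0 = n0),
               predict_rogers2(a = 0.7, h = 0.03, N0 = n0), tolerance = 1e-12)
})

test_that("overflow-prone parameter corners still satisfy the implicit equation", {
  # a*h*N0 pushes the W argument past exp(700)
  ne <- predict_rogers2(a = 800, h = 1.2, N0 = 150, T_ = 2)
  expect_true(ne >= 0 && ne <= 150)
  # slope-normalized residual: the raw residual is amplified ~a*h*N0-fold
  resid <- abs(ne - 150 * (1 - exp(800 * (1.2 * ne - 2)))) / (1 + 800 * 1.2 * 150)
  expect_lt(resid, 1e-10)
  expect_equal(ne, 2 / 1.2, tolerance = 1e-2)  # near the saturation bound T/h
})

test_that("maximum feeding rate is the reciprocal of handling time x time", {
  expect_equal(max_feeding_rate(0.0228), 43.85965, tolerance = 1e-6)
  expect_equal(round(max_feeding_rate(0.0104)), 96)
  expect_equal(max_feeding_rate(1), 1)
  expect_equal(max_feeding_rate(0.05, T_ = 2), 10)
  expect_error(max_feeding_rate(0), "unbounded")
})
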