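#' Holling type II disc equation (no depletion)
#'
#' Expected number of prey eaten when prey are continuously replaced, so that
#' density stays at `N` throughout the trial:
#' \deqn{N_e = \frac{a N T}{1 + a h N}}
#'
#' @param a Attack rate (per day). Non-negative.
#' @param h Handling time (days per prey). Non-negative.
#' @param N Prey density (count). Non-negative.
#' @param T_ Total experimental time (days). Positive. Named `T_` to avoid
#'   masking `base::T`.
#' @return Expected number of prey eaten (same length as the recycled inputs).
#' @examples
#' predict_holling2(a = 1, h = 0.1, N = 10)   # 5 prey
#' @family functional-response predictors
#' @export
predict_holling2 <- function(a, h, N, T_ = 1) {
  check_fr_args(a = a, h = h, N = N, T_ = T_)
  a * N * T_ / (1 + a * h * N)
}

#' Rogers depletion-corrected type II (random-predator equation)
#'
#' Expected number of prey eaten when consumed prey are not replaced. The
#' prediction is the unique root in `[0, N0]` of the implicit random-predator
#' equation
#' \deqn{N_e = N_0\,(1 - \exp(a (h N_e - T)))}
#' obtained in closed form with the principal branch of the Lambert W
#' function:
#' \deqn{N_e = N_0 - \frac{W\!\left(a h N_0\, e^{-a (T - h N_0)}\right)}{a h}.}
#' When the W argument would overflow (exponent beyond ~700), the same root is
#' computed from the log of the argument by a Newton iteration on
#' \eqn{w + \log w = \log x}, so the contract is unchanged.
#'
#' @inheritParams predict_holling2
#' @param N0 Initial prey density (count). Non-negative.
#' @return Expected number eaten, in `[0, N0]`; the implicit-equation residual
#'   at the returned value is below 1e-10.
#' @examples
#' predict_rogers2(a = 1, h = 0, N0 = 10)      # 10 * (1 - exp(-1))
#' predict_rogers2(a = 0.9797, h = 0.0104, N0 = 80)
#' @family functional-response predictors
#' @export
predict_rogers2 <- function(a, h, N0, T_ = 1) {
  check_fr_args(a = a, h = h, N = N0, T_ = T_)
  n <- max(length(a), length(h), length(N0), length(T_))
  a <- rep_len(a, n); h <- rep_len(h, n)
  N0 <- rep_len(N0, n); T_ <- rep_len(T_, n)
  ne <- numeric(n)

  trivial <- a == 0 | N0 == 0
  pure_exp <- !trivial & h == 0
  ne[pure_exp] <- N0[pure_exp] * (-expm1(-a[pure_exp] * T_[pure_exp]))

  gen <- !trivial & !pure_exp
  if (any(gen)) {
    ne[gen] <- rogers_ne_core(a[gen], h[gen], N0[gen], T_[gen], verify = TRUE)
  }
  ne
}

# Closed-form Rogers kernel shared by predict_rogers2() and the fitting
# likelihood. Assumes a > 0, h > 0, N0 > 0, T > 0 elementwise (callers handle
# the degenerate cases). `verify = TRUE` adds the implicit-equation residual
# check with an iterative fallback; the optimizer path skips it because the
# Halley-converged W already gives residuals at solver precision.
rogers_ne_core <- function(a, h, N0, T_, verify = FALSE) {
  # log of the Lambert-W argument a*h*N0 * exp(-a*(T - h*N0))
  logx <- log(a * h * N0) - a * (T_ - h * N0)
  if (any(logx > 700)) {           # exp() would overflow: log-domain branch
    w <- numeric(length(logx))
    hi <- logx > 700
    w[hi] <- lambert_w0_log(logx[hi])
    w[!hi] <- lambert_w0(exp(logx[!hi]))
  } else {
    w <- lambert_w0(exp(logx))
  }
  val <- pmin(pmax(N0 - w / (a * h), 0), N0)
  if (!verify) return(val)
  bad <- !is.finite(val)
  if (any(bad)) {
    val[bad] <- mapply(rogers_fixed_point, a[bad], h[bad], N0[bad], T_[bad])
  }
  resid <- abs(val - N0 * (-expm1(a * (h * val - T_))))
  redo <- resid > 1e-10
  if (any(redo)) {
    val[redo] <- mapply(rogers_fixed_point, a[redo], h[redo], N0[redo], T_[redo])
    resid2 <- abs(val[redo] - N0[redo] * (-expm1(a[redo] * (h[redo] * val[redo] - T_[redo]))))
    # normalize by the implicit equation's slope: the raw residual is the Ne
    # error amplified by ~a*h*N0 for steep responses
    resid2 <- resid2 / (1 + a[redo] * h[redo] * N0[redo])
    if (any(resid2 > 1e-8)) {
      stop("Rogers solver failed to converge for a=", a[redo][which.max(resid2)],
           ", h=", h[redo][which.max(resid2)],
           ", N0=", N0[redo][which.max(resid2)], call. = FALSE)
    }
  }
  val
}

#' Generalized flexible-exponent functional response with depletion
#'
#' The flexible family makes the attack rate density dependent,
#' \eqn{a = b N_0^q}, inside the Rogers random-predator equation. `q = 0`
#' reduces exactly to the Rogers type II model with `a = b`; `q = 1` gives
#' type III behaviour (attack rate proportional to density); intermediate and
#' larger `q` trace a continuum of sigmoidal shapes.
#'
#' @inheritParams predict_rogers2
#' @param b Attack coefficient (per day per prey^q). Non-negative.
#' @param q Scaling exponent (dimensionless, unconstrained).
#' @return Expected number eaten in `[0, N0]`. `N0 = 0` returns 0 for any `q`.
#' @examples
#' predict_flexq(b = 0.0028, q = 2.1645, h = 0.0228, N0 = 80)
#' @family functional-response predictors
#' @export
predict_flexq <- function(b, q, h, N0, T_ = 1) {
  check_fr_args(a = b, h = h, N = N0, T_ = T_)
  n <- max(length(b), length(q), length(h), length(N0), length(T_))
  b <- rep_len(b, n); q <- rep_len(q, n); h <- rep_len(h, n)
  N0 <- rep_len(N0, n); T_ <- rep_len(T_, n)
  a_eff <- ifelse(N0 == 0, 0, b * N0^q)
  predict_rogers2(a = a_eff, h = h, N0 = N0, T_ = T_)
}

#' Hassell type III functional response with depletion
#'
#' Type III model in which the effective attack rate is a saturating function
#' of initial density, \eqn{a_{\mathrm{eff}} = (d + b N_0)/(1 + c N_0)},
#' substituted into the Rogers random-predator equation:
#' \deqn{N_e = N_0\left(1 - \exp\!\left(\frac{(d + b N_0)(h N_e - T)}{1 + c N_0}\right)\right).}
#' With `b = c = 0` it reduces to the Rogers type II model with `a = d`; with
#' `c = d = 0` the effective attack rate is `b * N0`, the classic type III
#' special case (flexible family at `q = 1`).
#'
#' @inheritParams predict_rogers2
#' @param b Attack-rate slope in density (per day per prey). Non-negative.
#' @param c Denominator saturation coefficient (per prey). Non-negative.
#' @param d Baseline attack rate (per day). Non-negative.
#' @return Expected number eaten in `[0, N0]`.
#' @family functional-response predictors
#' @export
predict_hassell3 <- function(b, c, d, h, N0, T_ = 1) {
  check_fr_args(a = b, h = h, N = N0, T_ = T_)
  if (any(c < 0) || any(d < 0)) stop("`c` and `d` must be non-negative", call. = FALSE)
  a_eff <- (d + b * N0) / (1 + c * N0)
  predict_rogers2(a = a_eff, h = h, N0 = N0, T_ = T_)
}

#' Maximum feeding rate
#'
#' The plateau of a saturating functional response, `MFr = 1 / (h * T)`, in
#' prey per day. Reporting layers conventionally round it to the nearest
#' integer.
#'
#' @inheritParams predict_holling2
#' @return `1 / (h * T_)` (prey per day).
#' @examples
#' max_feeding_rate(h = 0.0228)  # ~43.9, reported as 44 prey/day
#' @export
max_feeding_rate <- function(h, T_ = 1) {
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("`h` must be strictly positive: the feeding rate is unbounded at h = 0",
         call. = FALSE)
  }
  if (any(T_ <= 0)) stop("`T_` must be positive", call. = FALSE)
  1 / (h * T_)
}

#' Predict from any functional-response family
#'
#' Dispatches on a family name to the corresponding predictor, reading the
#' active parameters from a named list. Used by the fitting, simulation and
#' plotting layers so parameter naming stays in one place.
#'
#' @param family One of `"holling2"`, `"rogers2"`, `"flexq"`, `"hassell3"`.
#' @param pars Named list or vector with the family's active parameters
#'   (`a`, `h` for holling2/rogers2; `b`, `q`, `h` for flexq;
#'   `b`, `c`, `d`, `h` for hassell3).
#' @param N0 Initial prey densities.
#' @param T_ Experimental time (days).
#' @return Expected number eaten per density.
#' @export
predict_fr <- function(family, pars, N0, T_ = 1) {
  family <- match.arg(family, fr_families())
  pars <- as.list(pars)
  switch(family,
    holling2 = predict_holling2(pars$a, pars$h, N0, T_),
    rogers2  = predict_rogers2(pars$a, pars$h, N0, T_),
    flexq    = predict_flexq(pars$b, pars$q, pars$h, N0, T_),
    hassell3 = predict_hassell3(pars$b, pars$c, pars$d, pars$h, N0, T_)
  )
}

#' Supported functional-response family names
#' @return Character vector of family identifiers.
#' @export
fr_families <- function() c("rogers2", "flexq", "hassell3", "holling2")

# active parameter names per family (fitting order)
fr_family_pars <- function(family) {
  switch(family,
    holling2 = c("a", "h"),
    rogers2  = c("a", "h"),
    flexq    = c("b", "h", "q"),
    hassell3 = c("b", "c", "d", "h")
  )
}

check_fr_args <- function(a, h, N, T_) {
  if (any(!is.finite(a)) || any(a < 0)) stop("attack rate must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(h)) || any(h < 0)) stop("handling time must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(N)) || any(N < 0)) stop("prey density must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(T_)) || any(T_ <= 0)) stop("experimental time must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Principal branch of the Lambert W function (non-negative arguments)
#'
#' Solves `w * exp(w) = x` for `x >= 0` by Halley iteration from the starting
#' guess `log1p(x)`, converging to near machine precision in a handful of
#' steps. This is the kernel of the closed-form Rogers random-predator
#' solution, so it is implemented here vectorized and allocation-light.
#'
#' @param x Numeric vector, `x >= 0`.
#' @return `W0(x)`, same length as `x`.
#' @export
lambert_w0 <- function(x) {
  if (any(x < 0)) stop("`x` must be non-negative (principal branch, x >= 0)", call. = FALSE)
  w <- log1p(x)
  for (i in 1:30) {
    ew <- exp(w)
    f <- w * ew - x
    # Halley step: f / (f'(w) - f * f''(w) / (2 f'(w)))
    delta <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    w <- w - delta
    if (all(abs(delta) <= 1e-14 * (1 + abs(w)))) break
  }
  w
}

# Principal-branch Lambert W from the log of its argument: solves
# w + log(w) = logx by Newton iteration. Only used when exp(logx) would
# overflow, where W(x) ~ logx - log(logx) is already an excellent start.
lambert_w0_log <- function(logx) {
  w <- logx - log(logx)
  for (i in 1:50) {
    delta <- (w + log(w) - logx) * w / (w + 1)
    w <- w - delta
    if (all(abs(delta) < 1e-12 * pmax(w, 1))) break
  }
  w
}

# Root-bracketing solution of the Rogers implicit equation; fallback path for
# arguments where the closed form is ill-conditioned. Bisection is used
# rather than fixed-point iteration because the map Ne -> N0(1 - exp(a(hNe-T)))
# has derivative -a*h*N0*exp(.) which exceeds 1 in magnitude for steep
# (large a*h*N0) responses, where damped iteration oscillates; the bracket
# [0, N0] always contains the unique root.
rogers_fixed_point <- function(a, h, N0, T_) {
  g <- function(ne) {
    e <- a * (h * ne - T_)
    if (e > 700) return(ne)  # exp overflow: g is hugely positive there
    ne - N0 * (-expm1(e))
  }
  r <- stats::uniroot(g, c(0, N0), tol = 1e-12, maxiter = 5000L)
  r$root
}
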