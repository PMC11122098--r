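#' Negative log-likelihood of a functional-response model
#'
#' Binomial consumption likelihood: each trial contributes
#' \eqn{\log \mathrm{Binom}(n_e \mid n_0, \hat p)} with
#' \eqn{\hat p = \hat N_e / n_0} the depletion-corrected predicted proportion
#' consumed, clipped to `[1e-9, 1 - 1e-9]` so boundary parameter values stay
#' finite for the optimizer. Invalid parameters return `+Inf` rather than
#' erroring, so the function is safe inside optimization.
#'
#' @param trials Trial table (see [trial_set()]).
#' @param family Model family (see [fr_families()]).
#' @param pars Named list/vector of the family's natural-scale parameters.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(trials, family, pars) {
  validate_trials(trials)
  family <- match.arg(family, fr_families())
  T_ <- unique_t_expose(trials)
  nll <- make_nll(family, trials$n0, trials$ne, T_)
  nll(as.numeric(unlist(pars)))
}

# closure over precomputed data; evaluates at natural-scale parameters
# supplied as a numeric vector in fr_family_pars() order
make_nll <- function(family, n0, ne, T_) {
  u <- sort(unique(n0))
  idx <- match(n0, u)
  lch <- lchoose(n0, ne)
  n_miss <- n0 - ne
  # effective attack rate per unique density; handling time is the last-but-
  # one or family-specific slot (see fr_family_pars)
  a_eff <- switch(family,
    holling2 = ,
    rogers2  = function(p) rep.int(p[1], length(u)),
    flexq    = function(p) p[1] * u^p[3],
    hassell3 = function(p) (p[3] + p[1] * u) / (1 + p[2] * u)
  )
  h_slot <- switch(family, holling2 = 2L, rogers2 = 2L, flexq = 2L, hassell3 = 4L)
  no_depletion <- family == "holling2"
  function(par) {
    if (any(!is.finite(par))) return(Inf)
    a <- a_eff(par)
    h <- par[h_slot]
    if (any(!is.finite(a))) return(Inf)
    ne_hat <- if (no_depletion) {
      a * u * T_ / (1 + a * h * u)
    } else if (h == 0) {
      u * -expm1(-a * T_)
    } else if (any(a == 0)) {
      out <- numeric(length(u))
      out[a > 0] <- rogers_ne_core(a[a > 0], h, u[a > 0], T_)
      out
    } else {
      rogers_ne_core(a, h, u, T_)
    }
    if (any(!is.finite(ne_hat))) return(Inf)
    p <- pmin(pmax(ne_hat / u, 1e-9), 1 - 1e-9)[idx]
    val <- -sum(lch + ne * log(p) + n_miss * log1p(-p))
    if (!is.finite(val)) Inf else val
  }
}

#' Wald statistic and two-sided normal p-value
#'
#' @param estimate Parameter estimate.
#' @param se Standard error (> 0).
#' @return List with `z = estimate / se` and the two-sided standard-normal
#'   tail probability `p`.
#' @examples
#' wald_stats(0.9797, 0.1138)  # z ~ 8.61
#' @export
wald_stats <- function(estimate, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be strictly positive", call. = FALSE)
  }
  z <- estimate / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Internal MLE engine shared by fit_fr() and the bootstrap: works on raw
# vectors, optimizes log-transformed positive parameters (q untransformed),
# optionally computes the Hessian-based covariance. `fixed` holds fixed
# parameter values (e.g. q for fix_q fits); `free` names the free parameters.
fr_mle <- function(family, n0, ne, T_, free, fixed = list(),
                   start_nat, restarts = 10, hessian = TRUE, reltol = 1e-10) {
  is_log <- free != "q"
  all_pars <- fr_family_pars(family)
  nll_core <- make_nll(family, n0, ne, T_)
  fixed_vec <- unlist(fixed)
  slot_free <- match(free, all_pars)
  slot_fixed <- if (length(fixed_vec)) match(names(fixed_vec), all_pars) else integer(0)
  full <- numeric(length(all_pars))
  if (length(slot_fixed)) full[slot_fixed] <- fixed_vec

  objective <- function(theta) {
    nat <- theta
    nat[is_log] <- exp(theta[is_log])
    full[slot_free] <- nat
    nll_core(full)
  }
  theta_from_nat <- function(nat) {
    th <- nat
    th[is_log] <- log(pmax(nat[is_log], 1e-12))
    th
  }

  attempt <- function(theta0) {
    opt <- tryCatch(
      stats::optim(theta0, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    conv <- opt$convergence == 0 && is.finite(opt$value)
    V <- NULL
    if (conv && hessian) {
      H <- tryCatch(stats::optimHess(opt$par, objective), error = function(e) NULL)
      conv <- FALSE
      if (!is.null(H) && all(is.finite(H))) {
        ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                       error = function(e) NA)
        if (all(is.finite(ev)) && all(ev > 0)) {
          V <- tryCatch(solve(H), error = function(e) NULL)
          conv <- !is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)
        }
      }
    }
    list(opt = opt, V = V, converged = conv)
  }

  best <- attempt(theta_from_nat(start_nat))
  starts_used <- list(start_nat)
  tries <- 0
  while ((is.null(best) || !best$converged) && tries < restarts) {
    tries <- tries + 1
    jitter <- start_nat
    jitter[is_log] <- jitter[is_log] * stats::runif(sum(is_log), 0.5, 2)
    if ("q" %in% free) jitter[free == "q"] <- jitter[free == "q"] + stats::runif(1, -0.5, 0.5)
    starts_used <- c(starts_used, list(jitter))
    cand <- attempt(theta_from_nat(jitter))
    if (!is.null(cand) &&
        (is.null(best) || (cand$converged && !best$converged) ||
         (cand$converged == best$converged && cand$opt$value < best$opt$value))) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)

  theta_hat <- best$opt$par
  est <- theta_hat
  est[is_log] <- exp(theta_hat[is_log])
  names(est) <- free
  se <- stats::setNames(rep(NA_real_, length(free)), free)
  if (best$converged && hessian) {
    grad <- ifelse(is_log, est, 1)       # delta method d(nat)/d(theta)
    se <- stats::setNames(sqrt(diag(best$V)) * abs(grad), free)
  }
  list(estimates = est, se = se, loglik = -best$opt$value,
       converged = isTRUE(best$converged), starts_used = starts_used)
}

#' Fit a functional-response model by maximum likelihood
#'
#' Minimizes the binomial negative log-likelihood over log-transformed rate
#' and handling-time parameters (positivity without boundary pathologies);
#' the scaling exponent `q` of the flexible family is unconstrained. Starting
#' values follow the convention `a = b = 1` and `h = 1/Fmax`, where `Fmax` is
#' the mean number of prey consumed at the highest density. If the first
#' attempt fails to converge with a positive-definite Hessian, up to
#' `restarts` jittered restarts (multiplicative factor U(0.5, 2) on the
#' positive parameters, additive U(-0.5, 0.5) on `q`) are tried before
#' declaring non-convergence. Standard errors come from the inverse numerical
#' Hessian at the optimum, delta-transformed to the natural scale.
#'
#' @param trials Trial table. All trials must share one exposure time.
#' @param family Model family (see [fr_families()]). `"flexq"` with
#'   `fix_q = 0` is reported as the Rogers type II model it reduces to.
#' @param fix_q Optional fixed value for `q` (flexq family only).
#' @param start Optional named list of natural-scale starting values
#'   overriding the defaults.
#' @param restarts Maximum number of jittered restarts after a failed first
#'   attempt.
#' @return An `fr_fit` object with elements `family`, `estimates`, `se`, `z`,
#'   `p` (named numeric vectors), `loglik`, `aic`, `mfr`, `converged`,
#'   `n_trials`, `starts_used`, `t_expose` and the trial data.
#' @export
fit_fr <- function(trials, family = "rogers2", fix_q = NULL, start = NULL,
                   restarts = 10) {
  validate_trials(trials)
  family <- match.arg(family, fr_families())
  T_ <- unique_t_expose(trials)
  if (family == "flexq" && !is.null(fix_q) && fix_q == 0) {
    # q = 0 reduces exactly to Rogers type II with a = b
    if (!is.null(start) && !is.null(start$b) && is.null(start$a)) start$a <- start$b
    fit <- fit_fr(trials, "rogers2", start = start, restarts = restarts)
    fit$fixed <- list(q = 0)
    return(fit)
  }
  if (family == "flexq" && length(unique(trials$n0)) < 3 && is.null(fix_q)) {
    stop("flexible-q fits need at least three distinct densities", call. = FALSE)
  }

  free <- fr_family_pars(family)
  fixed <- list()
  if (!is.null(fix_q)) {
    if (family != "flexq") stop("`fix_q` applies to the flexq family only", call. = FALSE)
    fixed$q <- fix_q
    free <- setdiff(free, "q")
  }

  fmax <- mean(trials$ne[trials$n0 == max(trials$n0)])
  h0 <- if (fmax > 0) 1 / fmax else 0.1
  defaults <- list(a = 1, b = if (family == "hassell3") 0.01 else 1,
                   c = 0.01, d = 1, h = h0, q = 0)
  start_nat <- defaults[free]
  if (!is.null(start)) {
    keep <- names(start)[names(start) %in% free]
    start_nat[keep] <- start[keep]
  }
  start_nat <- unlist(start_nat)[free]

  mle <- fr_mle(family, trials$n0, trials$ne, T_, free, fixed,
                start_nat, restarts = restarts, hessian = TRUE)
  if (is.null(mle)) {
    stop("all optimization attempts failed outright for family ", family, call. = FALSE)
  }

  est <- mle$estimates
  if (mle$converged) {
    ws <- wald_stats(est, mle$se)
    z <- ws$z; p <- ws$p
  } else {
    z <- p <- stats::setNames(rep(NA_real_, length(est)), free)
  }
  k <- length(free)

  structure(
    list(
      family = family,
      estimates = est, se = mle$se, z = z, p = p,
      fixed = fixed,
      loglik = mle$loglik, aic = 2 * k - 2 * mle$loglik, k = k,
      mfr = if (est[["h"]] > 0) 1 / (est[["h"]] * T_) else NA_real_,
      converged = mle$converged,
      n_trials = nrow(trials),
      starts_used = mle$starts_used,
      t_expose = T_,
      trials = tibble::as_tibble(as.data.frame(trials))
    ),
    class = "fr_fit"
  )
}

unique_t_expose <- function(trials) {
  T_ <- unique(trials$t_expose)
  if (length(T_) != 1) {
    stop("all trials in one fit must share the same exposure time; found: ",
         paste(T_, collapse = ", "), call. = FALSE)
  }
  T_
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Functional-response fit:", fr_family_label(x$family),
      if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  logLik %.3f | AIC %.3f | n = %d trials | T = %g day(s)\n",
              x$loglik, x$aic, x$n_trials, x$t_expose))
  if (is.finite(x$mfr)) cat(sprintf("  maximum feeding rate: %.2f prey/day\n", x$mfr))
  print(tidy(x))
  invisible(x)
}

fr_family_label <- function(family) {
  c(rogers2 = "Rogers type II (depletion-corrected)",
    flexq = "generalized flexible-q (depletion-corrected)",
    hassell3 = "Hassell type III (depletion-corrected)",
    holling2 = "Holling type II (disc equation)")[[family]]
}

#' Tidy a functional-response fit
#'
#' @param x An `fr_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per free parameter: term, estimate, std.error,
#'   statistic (Wald z), p.value.
#' @export
tidy.fr_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p)
  )
}

#' One-row summary of a functional-response fit
#'
#' @param x An `fr_fit` object.
#' @param ... Unused.
#' @return Tibble with family, logLik, AIC, number of parameters, maximum
#'   feeding rate, convergence flag and trial count.
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$loglik,
    AIC = x$aic,
    k = x$k,
    mfr = x$mfr,
    converged = x$converged,
    n_trials = x$n_trials
  )
}
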