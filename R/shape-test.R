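#' Phenomenological shape test for the functional-response curve
#'
#' Fits a binomial logistic regression of the proportion of focal prey
#' consumed on polynomial terms in initial density and classifies the curve as
#' hyperbolic (type II candidate: proportion consumed declines with density)
#' or sigmoidal (type III / generalized candidate: proportion initially rises)
#' from the sign of the retained linear term. The response is encoded as
#' (successes, failures) = (`ne`, `n0 - ne`), giving correct binomial weights
#' for unequal densities.
#'
#' The highest-order term is backward-eliminated while non-significant
#' (cubic first, then quadratic); the linear term is always retained. For
#' numerical conditioning the polynomial is built on centered and scaled
#' density; coefficients are reported on that standardized scale (the
#' convention under which published coefficient tables of this test are
#' order 1) and additionally mapped exactly, with their covariance, to the raw
#' density scale. The test is descriptive: it cannot distinguish a true type
#' III from a generalized response, so final model choice belongs to AIC
#' comparison in [select_model()].
#'
#' @param trials Trial table (see [trial_set()]); needs at least two distinct
#'   densities.
#' @param max_degree Highest polynomial degree to start from (1, 2 or 3).
#' @param alpha Significance level for term elimination and for calling the
#'   linear-term sign significant.
#' @return An `fr_shape` object: list with `coefficients` (tibble: term,
#'   estimate, std.error, statistic, p.value on the standardized scale),
#'   `raw_coefficients` (same layout, raw density scale), `retained_degree`,
#'   `inferred_shape` (`"hyperbolic"`, `"sigmoidal"` or `"indeterminate"`),
#'   `alpha`, and a `diagnostic` message when the fit is degenerate.
#' @export
fit_shape_test <- function(trials, max_degree = 3, alpha = 0.05) {
  validate_trials(trials)
  if (!max_degree %in% 1:3) stop("`max_degree` must be 1, 2 or 3", call. = FALSE)
  n_dens <- length(unique(trials$n0))
  if (n_dens < 2) stop("shape test needs at least two distinct densities", call. = FALSE)
  max_degree <- min(max_degree, n_dens - 1)

  mu <- mean(trials$n0)
  sdev <- stats::sd(trials$n0)
  if (sdev == 0) sdev <- 1
  z <- (trials$n0 - mu) / sdev
  dat <- data.frame(ne = trials$ne, miss = trials$n0 - trials$ne,
                    z1 = z, z2 = z^2, z3 = z^3)

  fit_degree <- function(deg) {
    f <- stats::as.formula(paste(
      "cbind(ne, miss) ~", paste0("z", seq_len(deg), collapse = " + ")))
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = dat))
  }

  deg <- max_degree
  fit <- fit_degree(deg)
  # drop the top term while it is non-significant; never drop the linear term
  while (deg > 1) {
    ct <- summary(fit)$coefficients
    p_top <- ct[paste0("z", deg), "Pr(>|z|)"]
    if (is.na(p_top) || p_top > alpha) {
      deg <- deg - 1
      fit <- fit_degree(deg)
    } else break
  }

  ct <- summary(fit)$coefficients
  terms <- c("intercept", "linear", "quadratic", "cubic")[seq_len(deg + 1)]
  coefs <- tibble::tibble(
    term = terms,
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "z value"]),
    p.value = unname(ct[, "Pr(>|z|)"])
  )

  raw <- rescale_poly_coefs(stats::coef(fit), stats::vcov(fit), mu, sdev)
  raw_coefs <- tibble::tibble(
    term = terms,
    estimate = unname(raw$beta),
    std.error = unname(raw$se),
    statistic = unname(raw$beta / raw$se),
    p.value = unname(2 * stats::pnorm(-abs(raw$beta / raw$se)))
  )

  diagnostic <- NULL
  if (!fit$converged) diagnostic <- "glm did not converge"
  se_lin <- coefs$std.error[coefs$term == "linear"]
  if (!is.finite(se_lin) || se_lin > 1e3) {
    diagnostic <- paste(c(diagnostic, "linear-term standard error is degenerate (separation?)"),
                        collapse = "; ")
  }

  shape <- if (!is.null(diagnostic)) {
    "indeterminate"
  } else {
    classify_shape(coefs$estimate[coefs$term == "linear"],
                   coefs$p.value[coefs$term == "linear"], alpha)
  }

  structure(
    list(coefficients = coefs, raw_coefficients = raw_coefs,
         retained_degree = deg, inferred_shape = shape, alpha = alpha,
         diagnostic = diagnostic, n_trials = nrow(trials), glm_fit = fit,
         center = mu, scale = sdev),
    class = "fr_shape"
  )
}

#' Classify curve shape from the linear logistic coefficient
#'
#' A significantly negative linear term means the proportion consumed declines
#' from the lowest densities (hyperbolic, type II candidate); a significantly
#' positive one means it initially rises (sigmoidal, type III or generalized
#' candidate).
#'
#' @param linear_estimate Linear-term coefficient.
#' @param p_value Its two-sided p-value.
#' @param alpha Significance level.
#' @return `"hyperbolic"`, `"sigmoidal"`, or `"indeterminate"`.
#' @export
classify_shape <- function(linear_estimate, p_value, alpha = 0.05) {
  if (!is.finite(linear_estimate) || !is.finite(p_value)) return("indeterminate")
  if (p_value > alpha) return("indeterminate")
  if (linear_estimate < 0) "hyperbolic" else "sigmoidal"
}

# Exact linear map of polynomial coefficients in z = (x - mu)/s back to
# powers of raw x, with the covariance transformed accordingly.
rescale_poly_coefs <- function(beta_z, V_z, mu, s) {
  k <- length(beta_z) - 1L
  A <- matrix(0, k + 1L, k + 1L)  # raw = A %*% z-scale
  for (j in 0:k) {
    # z^j = sum_i choose(j,i) (-mu)^(j-i) x^i / s^j
    for (i in 0:j) {
      A[i + 1L, j + 1L] <- choose(j, i) * (-mu)^(j - i) / s^j
    }
  }
  beta <- drop(A %*% beta_z)
  V <- A %*% V_z %*% t(A)
  list(beta = beta, se = sqrt(pmax(diag(V), 0)))
}

#' @export
print.fr_shape <- function(x, ...) {
  cat("Functional-response shape test (polynomial logistic regression)\n")
  cat("  retained degree:", x$retained_degree,
      "| inferred shape:", x$inferred_shape, "\n")
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.fr_shape <- function(x, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") x$coefficients else x$raw_coefficients
}

#' @export
glance.fr_shape <- function(x, ...) {
  tibble::tibble(
    retained_degree = x$retained_degree,
    inferred_shape = x$inferred_shape,
    alpha = x$alpha,
    n_trials = x$n_trials
  )
}
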