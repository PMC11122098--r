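#' Nonparametric bootstrap confidence intervals for a functional-response fit
#'
#' Resamples trials with replacement and refits the model on every resample;
#' per-parameter 95% percentile intervals are computed from the converged
#' resamples. Bootstrap refits start from the point estimates. By default
#' trials are resampled freely across the whole experiment; `stratify = TRUE`
#' resamples within each density stratum instead, preserving the design
#' exactly but shrinking the bootstrap variance by the small-stratum factor
#' (n_s - 1)/n_s per stratum — a noticeable interval narrowing when strata
#' hold only a few replicates, which is why it is not the default.
#'
#' @param trials Trial table.
#' @param family Model family, or an existing [fit_fr()] result via `fit`
#'   (in which case `family` is taken from it).
#' @param n_boot Number of bootstrap resamples (> 0; 2000 by default).
#' @param seed Integer seed for the resampling RNG (local to this call).
#' @param fit Optional converged `fr_fit` to bootstrap around; fitted from
#'   `trials` if omitted.
#' @param conf Confidence level (default 0.95).
#' @param restarts Restarts per bootstrap refit (default 1; refits start at
#'   the point estimates).
#' @param stratify Resample within density strata instead of across the whole
#'   trial set (default `FALSE`; see Details).
#' @return An `fr_boot` object: `n_boot`, `replicate_estimates` (tibble, one
#'   row per converged resample), `ci` (tibble: term, estimate, conf.low,
#'   conf.high), `method = "percentile"`, `seed`, `frac_nonconverged`,
#'   `unreliable` (TRUE when more than half the resamples failed).
#' @export
bootstrap_ci <- function(trials, family = "rogers2", n_boot = 2000,
                         seed = NULL, fit = NULL, conf = 0.95, restarts = 1,
                         stratify = FALSE) {
  validate_trials(trials)
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop("`n_boot` must be a positive integer", call. = FALSE)
  }
  if (is.null(fit)) fit <- fit_fr(trials, family, restarts = 10)
  family <- fit$family
  if (!fit$converged) {
    stop("cannot bootstrap a non-converged point fit", call. = FALSE)
  }
  start_nat <- fit$estimates
  free <- names(start_nat)
  fixed <- if (identical(fit$fixed, list(q = 0))) list() else fit$fixed
  T_ <- fit$t_expose

  n_all <- nrow(trials)
  strata <- if (stratify) split(seq_len(n_all), trials$n0) else NULL
  n0_all <- trials$n0
  ne_all <- trials$ne

  run_boot <- function() {
    reps <- vector("list", n_boot)
    for (i in seq_len(n_boot)) {
      idx <- if (stratify) {
        unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
               use.names = FALSE)
      } else {
        sample.int(n_all, n_all, replace = TRUE)
      }
      # refits start at the point estimates and only need point values for
      # percentile intervals, so the Hessian is skipped
      bfit <- fr_mle(family, n0_all[idx], ne_all[idx], T_, free, fixed,
                     start_nat, restarts = restarts, hessian = FALSE, reltol = 1e-8)
      if (!is.null(bfit) && bfit$converged) reps[[i]] <- bfit$estimates
    }
    reps
  }
  reps <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())

  ok <- !vapply(reps, is.null, logical(1))
  frac_bad <- 1 - mean(ok)
  est_mat <- do.call(rbind, reps[ok])
  alpha <- (1 - conf) / 2
  ci <- if (is.null(est_mat) || nrow(est_mat) == 0) {
    tibble::tibble(term = names(fit$estimates),
                   estimate = unname(fit$estimates),
                   conf.low = NA_real_, conf.high = NA_real_)
  } else {
    tibble::tibble(
      term = colnames(est_mat),
      estimate = unname(fit$estimates[colnames(est_mat)]),
      conf.low = apply(est_mat, 2, stats::quantile, probs = alpha),
      conf.high = apply(est_mat, 2, stats::quantile, probs = 1 - alpha)
    )
  }

  structure(
    list(
      n_boot = as.integer(n_boot),
      replicate_estimates = if (is.null(est_mat)) tibble::tibble() else tibble::as_tibble(est_mat),
      ci = ci,
      conf = conf,
      method = "percentile",
      stratified = stratify,
      seed = seed,
      family = family,
      frac_nonconverged = frac_bad,
      unreliable = frac_bad > 0.5
    ),
    class = "fr_boot"
  )
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap (%s%s), %d resamples (%.1f%% non-converged%s)\n",
              x$method, if (x$stratified) ", stratified by density" else "",
              x$n_boot, 100 * x$frac_nonconverged,
              if (x$unreliable) "; UNRELIABLE" else ""))
  print(x$ci)
  invisible(x)
}

#' @export
tidy.fr_boot <- function(x, ...) x$ci
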