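#' Three-step functional-response model selection
#'
#' Implements the standard selection procedure for depletion-design predation
#' trials:
#' \enumerate{
#'   \item an advisory shape test ([fit_shape_test()]): polynomial logistic
#'     regression on the proportion consumed, classifying the curve as
#'     hyperbolic or sigmoidal;
#'   \item a flexible-exponent fit (`q` free) against the fixed `q = 0`
#'     (Rogers type II) fit, compared by AIC. If the fixed-`q` model wins, the
#'     type II model is final; if the flexible model wins, the Hassell type
#'     III model is also fitted and the generalized response is retained only
#'     if its AIC beats the type III AIC;
#'   \item the chosen family's fit is reported with maximum feeding rate, and
#'     (downstream) bootstrap confidence intervals.
#' }
#' AIC ties within `delta_aic_tie` are resolved toward the model with fewer
#' parameters. A chosen fit whose non-`q` parameters are not all significant
#' at `alpha` is flagged `evidence = FALSE` — the "no evidence of any
#' functional response type" outcome.
#'
#' @param trials Trial table (one treatment's trials).
#' @param delta_aic_tie AIC difference below which the simpler model wins.
#' @param alpha Significance level for the shape test and the evidence rule.
#' @param restarts Jittered restarts forwarded to [fit_fr()].
#' @return An `fr_selection` object: `shape` (the [fit_shape_test()] result),
#'   `fits` (named list of `fr_fit`s), `chosen` (family name or `"none"`),
#'   `chosen_fit`, `evidence` flag, and `comparison` (tibble of AIC rows).
#' @export
select_model <- function(trials, delta_aic_tie = 2, alpha = 0.05, restarts = 10) {
  validate_trials(trials)

  shape <- tryCatch(fit_shape_test(trials, alpha = alpha),
                    error = function(e) NULL)

  safe_fit <- function(...) tryCatch(fit_fr(trials, ...), error = function(e) NULL)
  fits <- list(
    flexq = safe_fit("flexq", restarts = restarts),
    rogers2 = safe_fit("rogers2", restarts = restarts)
  )

  conv <- function(f) !is.null(f) && f$converged
  aic <- function(f) if (conv(f)) f$aic else Inf

  chosen <- "none"
  if (conv(fits$flexq) && aic(fits$rogers2) - aic(fits$flexq) >= delta_aic_tie) {
    # flexible q clearly better than q = 0: sigmoidal; pit it against type III
    fits$hassell3 <- safe_fit("hassell3", restarts = restarts,
                              start = list(d = fits$flexq$estimates[["b"]],
                                           h = fits$flexq$estimates[["h"]]))
    chosen <- if (aic(fits$hassell3) - aic(fits$flexq) > -delta_aic_tie) {
      "flexq"  # generalized wins outright or within the parsimony tie band
    } else {
      "hassell3"
    }
  } else if (conv(fits$rogers2)) {
    chosen <- "rogers2"
  } else if (conv(fits$flexq)) {
    chosen <- "flexq"
  }

  chosen_fit <- if (chosen == "none") NULL else fits[[chosen]]
  evidence <- FALSE
  if (!is.null(chosen_fit)) {
    p_non_q <- chosen_fit$p[setdiff(names(chosen_fit$p), "q")]
    evidence <- all(is.finite(p_non_q)) && all(p_non_q < alpha)
  }

  comparison <- purrr::map_dfr(purrr::compact(fits), glance)

  structure(
    list(shape = shape, fits = purrr::compact(fits), chosen = chosen,
         chosen_fit = chosen_fit, evidence = evidence,
         comparison = comparison, delta_aic_tie = delta_aic_tie,
         alpha = alpha),
    class = "fr_selection"
  )
}

#' @export
print.fr_selection <- function(x, ...) {
  cat("Functional-response model selection\n")
  if (!is.null(x$shape)) {
    cat("  step 1 (advisory shape test):", x$shape$inferred_shape, "\n")
  }
  cat("  AIC comparison:\n")
  print(x$comparison)
  if (x$chosen == "none" || !x$evidence) {
    cat("  -> no evidence of any functional response type\n")
  } else {
    cat("  -> chosen:", fr_family_label(x$chosen), "\n")
  }
  invisible(x)
}

#' Tidy a model-selection result
#'
#' @param x An `fr_selection` object.
#' @param ... Unused.
#' @return The chosen fit's parameter table, with a `family` column; empty
#'   tibble when no model was chosen.
#' @export
tidy.fr_selection <- function(x, ...) {
  if (is.null(x$chosen_fit)) return(tibble::tibble())
  dplyr::mutate(tidy(x$chosen_fit), family = x$chosen, .before = 1)
}

#' One-row summary of a model-selection result
#'
#' @param x An `fr_selection` object.
#' @param ... Unused.
#' @return Tibble: inferred shape, chosen family, evidence flag, chosen AIC
#'   and maximum feeding rate.
#' @export
glance.fr_selection <- function(x, ...) {
  tibble::tibble(
    inferred_shape = if (is.null(x$shape)) NA_character_ else x$shape$inferred_shape,
    chosen = x$chosen,
    evidence = x$evidence,
    AIC = if (is.null(x$chosen_fit)) NA_real_ else x$chosen_fit$aic,
    mfr = if (is.null(x$chosen_fit)) NA_real_ else x$chosen_fit$mfr
  )
}
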