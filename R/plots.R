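#' Plot a fitted functional response over the trial data
#'
#' Draws per-trial consumption (jittered points), per-density means, and the
#' fitted depletion-corrected curve.
#'
#' @param object An `fr_fit`.
#' @param n_grid Number of densities at which to evaluate the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fr_fit <- function(object, n_grid = 200, ...) {
  trials <- object$trials
  grid <- tibble::tibble(n0 = seq(0, max(trials$n0), length.out = n_grid))
  grid$ne <- predict_fr(object$family, object$estimates, grid$n0, object$t_expose)
  means <- trials |>
    dplyr::group_by(.data$n0) |>
    dplyr::summarise(ne = mean(.data$ne), .groups = "drop")
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$n0, y = .data$ne)) +
    ggplot2::geom_jitter(width = 0.8, height = 0, alpha = 0.35) +
    ggplot2::geom_point(data = means, shape = 17, size = 2.5) +
    ggplot2::geom_line(data = grid, linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(
      x = "initial prey density (N0)",
      y = "prey consumed (Ne)",
      title = fr_family_label(object$family),
      subtitle = sprintf("AIC %.1f | MFr %.1f prey/day", object$aic, object$mfr)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the shape-test proportions and fitted polynomial logistic curve
#'
#' @param object An `fr_shape` from [fit_shape_test()].
#' @param n_grid Number of grid densities for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fr_shape <- function(object, n_grid = 200, ...) {
  fit <- object$glm_fit
  dat <- fit$data
  n0 <- dat$z1 * object$scale + object$center
  obs <- tibble::tibble(n0 = n0, prop = dat$ne / (dat$ne + dat$miss))
  zg <- seq(min(dat$z1), max(dat$z1), length.out = n_grid)
  newd <- data.frame(z1 = zg, z2 = zg^2, z3 = zg^3)
  curve <- tibble::tibble(
    n0 = zg * object$scale + object$center,
    prop = stats::predict(fit, newdata = newd, type = "response"))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$n0, y = .data$prop)) +
    ggplot2::geom_jitter(width = 0.8, height = 0, alpha = 0.4) +
    ggplot2::geom_line(data = curve, colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(x = "initial prey density (N0)",
                  y = "proportion of prey consumed",
                  title = paste("Shape test:", object$inferred_shape)) +
    ggplot2::theme_minimal()
}

#' Plot per-density consumption summaries
#'
#' Mean consumed focal and alternative prey (with one-SE bars) per density,
#' faceted by context and treatment — the graphical companion of
#' [summarize_consumption()].
#'
#' @param trials Trial table.
#' @return A ggplot object.
#' @export
plot_consumption <- function(trials) {
  s <- summarize_consumption(trials) |>
    tidyr::pivot_longer(c("mean_ne", "mean_ap"), names_to = "prey",
                        values_to = "mean") |>
    dplyr::mutate(
      se = ifelse(.data$prey == "mean_ne", .data$se_ne, .data$se_ap),
      prey = ifelse(.data$prey == "mean_ne", "focal prey", "alternative prey"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n0, y = .data$mean,
                                  colour = .data$prey)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 1.5) +
    ggplot2::facet_grid(igp ~ treatment) +
    ggplot2::labs(x = "initial focal-prey density", y = "mean consumed",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
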