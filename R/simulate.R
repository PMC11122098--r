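#' Simulate focal-prey consumption for one predation trial
#'
#' Two noise models are available. `"binomial"` draws
#' `ne ~ Binomial(n0, Ne_hat / n0)` around the family's depletion-corrected
#' prediction — exactly the sampling model the fitting likelihood assumes.
#' `"exact_depletion"` simulates the mechanistic search-and-handle renewal
#' process underlying the disc equation: waiting times to the next capture
#' are exponential with total rate `a_eff * N` over the `N` prey still alive,
#' and each capture consumes `h` days of handling from the remaining time
#' budget; the trial ends when the budget `T` is exhausted. An optional
#' beta-binomial overdispersion knob (`theta`) widens the binomial mode.
#'
#' @param family Generating family (see [fr_families()]).
#' @param pars Named list of natural-scale true parameters.
#' @param n0 Initial focal-prey density.
#' @param t_expose Exposure time in days.
#' @param noise `"binomial"` or `"exact_depletion"`.
#' @param theta Beta-binomial overdispersion (binomial mode only): `Inf`
#'   (default) is pure binomial; smaller values add between-trial variance.
#' @return Integer number of prey consumed, in `[0, n0]`.
#' @export
simulate_trial <- function(family, pars, n0, t_expose = 1,
                           noise = c("binomial", "exact_depletion"),
                           theta = Inf) {
  noise <- match.arg(noise)
  if (n0 <= 0) return(0L)
  pars <- as.list(pars)
  if (noise == "binomial") {
    p <- predict_fr(family, pars, n0, t_expose) / n0
    p <- min(max(p, 0), 1)
    if (is.finite(theta)) {
      p <- stats::rbeta(1, p * theta, (1 - p) * theta)
    }
    return(stats::rbinom(1, n0, p))
  }
  a_eff <- effective_attack_rate(family, pars, n0)
  h <- pars$h
  t <- 0; alive <- n0; eaten <- 0L
  while (alive > 0) {
    t <- t + stats::rexp(1, rate = a_eff * alive)
    if (t >= t_expose) break
    eaten <- eaten + 1L
    alive <- alive - 1L
    t <- t + h  # handling spends budget during which there is no search
  }
  eaten
}

effective_attack_rate <- function(family, pars, n0) {
  switch(family,
    holling2 = pars$a,
    rogers2  = pars$a,
    flexq    = pars$b * n0^pars$q,
    hassell3 = (pars$d + pars$b * n0) / (1 + pars$c * n0)
  )
}

#' Configuration for a synthetic predation experiment
#'
#' Defaults replicate the arena design the package targets: focal-prey
#' densities 5/10/25/50/80 with 6 replicates each, alternative-prey (AP)
#' treatments offering 0/5/25/80 aphids, 24 h (1 day) exposure. Default AP
#' consumption fractions (0.92, 0.80, 0.65 for 5/25/80 aphids offered) echo
#' the near-saturating aphid predation observed at those offers; AP
#' consumption is generated but never used in functional-response fitting —
#' it enters the analysis only as a treatment label.
#'
#' @param family Generating family.
#' @param pars Named list of true parameters.
#' @param densities Initial focal-prey densities.
#' @param reps_per_density Replicates per density (block ids 1..reps).
#' @param treatments Named numeric vector: treatment label -> aphids offered.
#' @param igp Context: `"non-parasitized"` (no intraguild predation) or
#'   `"parasitized"`.
#' @param noise Noise model for [simulate_trial()].
#' @param theta Beta-binomial overdispersion (see [simulate_trial()]).
#' @param ap_fraction Named numeric vector mapping AP offer (as character) to
#'   the mean fraction of offered aphids consumed.
#' @param t_expose Exposure time in days.
#' @param seed Integer seed recorded in the output metadata and used for
#'   generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(family = "rogers2",
                             pars = list(a = 1, h = 0.02),
                             densities = c(5, 10, 25, 50, 80),
                             reps_per_density = 6,
                             treatments = c("No AP" = 0),
                             igp = "non-parasitized",
                             noise = "binomial",
                             theta = Inf,
                             ap_fraction = c("5" = 0.92, "25" = 0.80, "80" = 0.65),
                             t_expose = 1,
                             seed = NULL) {
  stopifnot(all(densities >= 1), reps_per_density >= 1, t_expose > 0)
  structure(
    list(family = match.arg(family, fr_families()), pars = as.list(pars),
         densities = densities, reps_per_density = as.integer(reps_per_density),
         treatments = treatments, igp = igp,
         noise = match.arg(noise, c("binomial", "exact_depletion")),
         theta = theta, ap_fraction = ap_fraction,
         t_expose = t_expose, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a synthetic predation experiment
#'
#' Produces `length(densities) * reps_per_density * length(treatments)`
#' trials from a [synthetic_config()], with metadata recording the generating
#' family, true parameters and seed. Alternative-prey consumption is drawn
#' independently of focal consumption as
#' `Binomial(ap_offered, ap_fraction[treatment])`.
#'
#' @param cfg A [synthetic_config()].
#' @return An `fr_trials` tibble (see [trial_set()]).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gen <- function() {
    grid <- tidyr::expand_grid(
      treatment = names(cfg$treatments),
      n0 = cfg$densities,
      replicate = seq_len(cfg$reps_per_density)
    )
    grid$ap_offered <- unname(cfg$treatments[grid$treatment])
    grid$ne <- purrr::map_int(grid$n0, function(n0) {
      as.integer(simulate_trial(cfg$family, cfg$pars, n0, cfg$t_expose,
                                noise = cfg$noise, theta = cfg$theta))
    })
    frac <- function(offer) {
      if (offer == 0) return(0)
      f <- cfg$ap_fraction[as.character(offer)]
      if (is.na(f)) 0.8 else unname(f)
    }
    grid$ap_consumed <- purrr::map_int(grid$ap_offered, function(off) {
      if (off == 0) 0L else stats::rbinom(1, off, frac(off))
    })
    grid$igp <- cfg$igp
    grid$t_expose <- cfg$t_expose
    grid[, c("n0", "ne", "ap_offered", "ap_consumed",
             "igp", "treatment", "replicate", "t_expose")]
  }
  trials <- if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
  trial_set(trials, metadata = list(
    source = "synthetic",
    family = cfg$family,
    true_pars = cfg$pars,
    noise = cfg$noise,
    seed = cfg$seed
  ))
}
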