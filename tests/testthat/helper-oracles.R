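# Independent oracles and fixture builders shared across the test files.
# These deliberately avoid the package's solver path: the fixed-point map is
# iterated directly on the implicit equation.

# Damped fixed-point solution of Ne = N0 * (1 - exp(a * (h * Ne - T))),
# iterated as Ne <- Ne/2 + N0 * (1 - exp(a * (h * Ne - T))) / 2 from zero.
# The damped map diverges when |map slope| = a*h*N0*exp(.) > 3 at the root
# (steep sigmoidal parameter sets), so plain interval bisection — equally
# independent of the Lambert-W path — takes over in that case.
rogers_oracle <- function(a, h, n0, T_ = 1, tol = 1e-12, max_iter = 10000) {
  ne <- 0
  for (i in seq_len(max_iter)) {
    prop <- n0 * (1 - exp(a * (h * ne - T_)))
    new <- 0.5 * ne + 0.5 * prop
    if (abs(new - ne) < tol) return(new)
    ne <- new
  }
  g <- function(x) x - n0 * (1 - exp(a * (h * x - T_)))
  lo <- 0; hi <- n0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Minimal trial tibble with sensible defaults for single-column overrides.
make_trials <- function(n0, ne, ap_offered = 0, ap_consumed = 0,
                        igp = "non-parasitized", treatment = "No AP",
                        replicate = seq_along(n0), t_expose = 1) {
  tibble::tibble(n0 = n0, ne = ne, ap_offered = ap_offered,
                 ap_consumed = ap_consumed, igp = igp, treatment = treatment,
                 replicate = replicate, t_expose = t_expose)
}

# Study-design generator shorthand used by fitting/selection tests.
design_experiment <- function(family, pars, reps = 6, seed = NULL, ...) {
  generate_experiment(synthetic_config(family = family, pars = pars,
                                       reps_per_density = reps, seed = seed,
                                       ...))
}
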