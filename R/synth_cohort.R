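# Cohort-level synthetic ground truth: a latent anxiety trait couples
# open-arm occupancy and dopamine-neuron firing (both decreasing in the
# trait), while the social-interaction phenotype is drawn independently of
# the trait — the dissociation the downstream correlation stage must recover.

#' Cohort generator configuration
#'
#' Latent-trait model: each mouse draws an anxiety trait
#' `a ~ Beta(trait_alpha, trait_beta)`; chronic defeat adds
#' `stress_trait_shift` (clipped to \[0, 1\]). The trait drives the EPM
#' open-arm occupancy target (`open_base - open_slope * a`, plus noise) and
#' the true firing rate (`firing_base_hz - firing_slope_hz * a`, plus
#' noise), so firing covaries positively with open-arm time. Susceptibility
#' is an independent Bernoulli draw among stressed mice, and the true SI
#' ratio is drawn from group-specific distributions (susceptible strictly
#' below 100, resilient at or above), independent of the trait.
#'
#' @param n_ctl,n_stressed group sizes (default 28 / 60).
#' @param p_susceptible probability a stressed mouse is susceptible
#'   (default 0.59).
#' @param trait_alpha,trait_beta Beta shape parameters of the trait
#'   (default 2, 4).
#' @param stress_trait_shift additive trait increase after defeat
#'   (default 0.25).
#' @param firing_base_hz,firing_slope_hz firing model intercept and
#'   per-unit-trait depression (default 6, 4 Hz).
#' @param firing_sd_hz mouse-level firing noise (default 0.7 Hz).
#' @param transient_base_per_min,transient_openarm_gain photometry event-rate
#'   model: baseline rate and open-arm rate increase (default 6, 12
#'   events/min).
#' @param open_base,open_slope,open_sd open-arm occupancy-target model.
#' @param si_susceptible,si_resilient mean/sd of the true SI-ratio
#'   distributions; susceptible values are clipped below 100 and resilient
#'   values above.
#' @param sensor `"GCaMP6s"` or `"GCaMP6f"`.
#' @param seed master seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_ctl = 28, n_stressed = 60, p_susceptible = 0.59,
                          trait_alpha = 2, trait_beta = 4,
                          stress_trait_shift = 0.25,
                          firing_base_hz = 6, firing_slope_hz = 4,
                          firing_sd_hz = 0.7,
                          transient_base_per_min = 6,
                          transient_openarm_gain = 12,
                          open_base = 0.35, open_slope = 0.35, open_sd = 0.04,
                          si_susceptible = c(55, 15), si_resilient = c(145, 25),
                          sensor = c("GCaMP6s", "GCaMP6f"), seed = 1) {
  sensor <- match.arg(sensor)
  cfg <- list(n_ctl = n_ctl, n_stressed = n_stressed,
              p_susceptible = p_susceptible, trait_alpha = trait_alpha,
              trait_beta = trait_beta, stress_trait_shift = stress_trait_shift,
              firing_base_hz = firing_base_hz, firing_slope_hz = firing_slope_hz,
              firing_sd_hz = firing_sd_hz,
              transient_base_per_min = transient_base_per_min,
              transient_openarm_gain = transient_openarm_gain,
              open_base = open_base, open_slope = open_slope, open_sd = open_sd,
              si_susceptible = si_susceptible, si_resilient = si_resilient,
              sensor = sensor, seed = seed)
  stop_if_not_finite(cfg[setdiff(names(cfg), "sensor")], "cohort_config")
  if (n_ctl < 0 || n_stressed < 0 || n_ctl != round(n_ctl) ||
      n_stressed != round(n_stressed)) {
    stop("configuration error: counts must be non-negative integers")
  }
  if (p_susceptible < 0 || p_susceptible > 1) {
    stop("configuration error: p_susceptible must be in [0, 1]")
  }
  if (firing_base_hz <= 0 || trait_alpha <= 0 || trait_beta <= 0) {
    stop("configuration error: firing_base_hz, trait_alpha, trait_beta must be > 0")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a cohort with retained ground truth
#'
#' Draws per-mouse latent parameters from the model in [cohort_config()].
#' Deterministic given `(config, seed)`.
#'
#' @param config a `cohort_config`.
#' @return list with `mice` (stub data frame: `mouse`, `stressed`) and
#'   `ground_truth` (adds `susceptible`, `trait`, `si_true`, `firing_true_hz`,
#'   `open_frac_true`, `transient_mod_per_min`).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_ctl + config$n_stressed
  if (n == 0) {
    empty <- data.frame(mouse = character(0), stressed = logical(0))
    return(list(mice = empty,
                ground_truth = cbind(empty, data.frame(
                  susceptible = logical(0), trait = numeric(0),
                  si_true = numeric(0), firing_true_hz = numeric(0),
                  open_frac_true = numeric(0),
                  transient_mod_per_min = numeric(0)))))
  }
  with_local_seed(split_seed(config$seed, "cohort"), {
    stressed <- c(rep(FALSE, config$n_ctl), rep(TRUE, config$n_stressed))
    id <- sprintf("m%03d", seq_len(n))
    a <- stats::rbeta(n, config$trait_alpha, config$trait_beta)
    a <- clip01(a + config$stress_trait_shift * stressed)
    susceptible <- stressed & stats::runif(n) < config$p_susceptible

    si <- numeric(n)
    sus <- which(susceptible)
    res <- which(!susceptible)
    si[sus] <- pmin(90, pmax(5, stats::rnorm(length(sus), config$si_susceptible[1],
                                             config$si_susceptible[2])))
    si[res] <- pmax(110, stats::rnorm(length(res), config$si_resilient[1],
                                      config$si_resilient[2]))

    firing <- config$firing_base_hz - config$firing_slope_hz * a +
      stats::rnorm(n, 0, config$firing_sd_hz)
    firing <- pmin(9.5, pmax(1.2, firing))
    open_frac <- config$open_base - config$open_slope * a +
      stats::rnorm(n, 0, config$open_sd)
    open_frac <- pmin(0.85, pmax(0.02, open_frac))
    tmod <- config$transient_openarm_gain * exp(stats::rnorm(n, 0, 0.2))

    gt <- data.frame(mouse = id, stressed = stressed, susceptible = susceptible,
                     trait = a, si_true = si, firing_true_hz = firing,
                     open_frac_true = open_frac, transient_mod_per_min = tmod)
    list(mice = gt[, c("mouse", "stressed")], ground_truth = gt)
  })
}
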