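#' Noise model for synthetic datasets
#'
#' Describes the replicate and error structure of the synthetic data
#' generators: proportional (constant-CV, multiplicative) or additive
#' Gaussian noise with a given replicate count. Every generator is a pure
#' function of its parameters and the seed.
#'
#' @param kind `"proportional"` or `"additive"`.
#' @param cv Coefficient of variation for proportional noise (>= 0).
#' @param sd Standard deviation, response units, for additive noise (>= 0).
#' @param replicates Number of replicates per design point (>= 1).
#' @param seed RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("proportional", "additive"), cv = 0.05,
                        sd = 3, replicates = 3, seed = 20210302) {
  kind <- match.arg(kind)
  if (cv < 0 || sd < 0) {
    abort("cv and sd must be >= 0", class = "revdosim_validation_error")
  }
  if (replicates < 1) {
    abort("replicates must be >= 1", class = "revdosim_validation_error")
  }
  structure(list(kind = kind, cv = cv, sd = sd, replicates = replicates,
                 seed = seed), class = "noise_model")
}

#' Generate a synthetic incubation-rate dataset
#'
#' Emulates substrate-dependent metabolite-formation rate measurements:
#' rates follow the Michaelis-Menten curve with proportional Gaussian noise
#' (`rate = MM(S) (1 + e)`, `e ~ N(0, cv)`), truncated at zero, over the
#' 1-100 uM concentration range used in the underlying assays, with 3
#' replicates by default.
#'
#' @param Km,Vmax Generating parameters (uM; nmol/min/mg protein), > 0.
#' @param concentrations Substrate concentrations, uM.
#' @param noise A [noise_model()] (proportional kind).
#' @return A tibble (`concentration_uM`, `rate_nmol_min_mg`, `replicate`)
#'   directly consumable by [fit_michaelis_menten()].
#' @export
gen_incubation_data <- function(Km, Vmax,
                                concentrations = c(1, 2.5, 5, 10, 25, 50, 75, 100),
                                noise = noise_model("proportional")) {
  if (Km <= 0 || Vmax <= 0) {
    abort("Km and Vmax must be > 0", class = "revdosim_validation_error")
  }
  mu <- michaelis_menten_rate(rep(concentrations, each = noise$replicates),
                              Km, Vmax)
  with_local_seed(noise$seed, {
    eps <- stats::rnorm(length(mu), 0, noise$cv)
    tibble(
      concentration_uM = rep(concentrations, each = noise$replicates),
      rate_nmol_min_mg = pmax(mu * (1 + eps), 0),
      replicate = rep(seq_len(noise$replicates), times = length(concentrations))
    )
  })
}

#' Generate a synthetic AChE inhibition dataset
#'
#' Activities follow the unit-slope log-logistic curve with additive
#' Gaussian noise (default SD 3 percentage points, 3 replicates), clipped to
#' [0, 120]% of control. The default 8-point log-spaced grid spans below 10%
#' and above 90% activity when centred on the IC50.
#'
#' @param IC50 Generating IC50 (nM), > 0.
#' @param concentrations Inhibitor concentrations, nM. The default covers
#'   10-10,000 nM in 8 log-spaced points.
#' @param noise A [noise_model()] (additive kind).
#' @return A tibble (`concentration_nM`, `activity_pct`, `replicate`) for
#'   [fit_ic50()].
#' @export
gen_inhibition_data <- function(IC50,
                                concentrations = 10^seq(1, 4, length.out = 8),
                                noise = noise_model("additive")) {
  if (IC50 <= 0) abort("IC50 must be > 0", class = "revdosim_validation_error")
  conc <- rep(concentrations, each = noise$replicates)
  mu <- logistic_activity(log10(conc), log10(IC50))
  with_local_seed(noise$seed, {
    act <- mu + stats::rnorm(length(mu), 0, noise$sd)
    tibble(
      concentration_nM = conc,
      activity_pct = pmin(pmax(act, 0), 120),
      replicate = rep(seq_len(noise$replicates), times = length(concentrations))
    )
  })
}

#' Generate a synthetic cumulative urinary-excretion dataset
#'
#' Simulates the PBK-predicted cumulative urinary excretion of the
#' glucuronidated metabolite and adds proportional noise, followed by an
#' isotonic correction (running maximum) so the generated series remains
#' non-decreasing like a real cumulative measurement. Emulates the kind of
#' in vivo excretion time course used for model evaluation.
#'
#' @param model A rat [pbk_model()] with `bcp = TRUE`.
#' @param dose mg/kg bw.
#' @param timepoints Sampling times (h).
#' @param noise A [noise_model()] (proportional kind).
#' @return A tibble (`time_h`, `cumulative_pct_dose`), non-decreasing,
#'   bounded by 100% of the molar dose.
#' @export
gen_urinary_dataset <- function(model, dose,
                                timepoints = c(6, 12, 24, 48, 72, 96, 120),
                                noise = noise_model("proportional")) {
  sim <- simulate_urinary_excretion(model, dose, duration = max(timepoints))
  mu <- stats::approx(sim$time_h, sim$cumulative_pct_dose, xout = timepoints)$y
  with_local_seed(noise$seed, {
    obs <- mu * (1 + stats::rnorm(length(mu), 0, noise$cv))
    obs <- pmin(pmax(obs, 0), 100)
    obs <- cummax(obs)                       # isotonic: cumulative data
    tibble(time_h = timepoints, cumulative_pct_dose = obs)
  })
}
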