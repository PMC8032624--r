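## Chemical-specific parameter paths recognised by the perturbation
## machinery. kp_<tissue> addresses a single partition coefficient.
sensitivity_parameters <- function(model) {
  c("ka", "fup", "renal_clearance",
    "vmax_mic", "km_mic", "vmax_cyt", "km_cyt", "vmax_pla", "km_pla",
    "fumic", "fucyt", "fupla",
    paste0("kp_", setdiff(PBK_COMPARTMENTS, c("venous_blood", "arterial_blood"))))
}

## Return a copy of the model with one named parameter multiplied by `factor`.
## Partition coefficients are perturbed directly (they are parameters of the
## assembled model); fup perturbation leaves the Kp set untouched, matching
## one-at-a-time local sensitivity analysis.
perturb_parameter <- function(model, parameter, factor) {
  stopifnot(inherits(model, "pbk_model"))
  m <- model
  if (parameter == "ka") {
    m$ka <- m$ka * factor
  } else if (parameter == "fup") {
    m$chem$fup <- m$chem$fup * factor
  } else if (parameter == "renal_clearance") {
    m$physiology$renal_clearance <- m$physiology$renal_clearance * factor
  } else if (parameter %in% c("fumic", "fucyt", "fupla")) {
    ## the incubation unbound fraction acts through the in vivo Km
    term <- switch(parameter, fumic = "mic", fucyt = "cyt", fupla = "pla")
    m$metabolism[[parameter]] <- m$metabolism[[parameter]] * factor
    m$metabolism[[term]]$km <- m$metabolism[[term]]$km * factor
  } else if (grepl("^(vmax|km)_(mic|cyt|pla)$", parameter)) {
    parts <- strsplit(parameter, "_")[[1]]
    field <- if (parts[1] == "vmax") "vmax" else "km"
    m$metabolism[[parts[2]]][[field]] <- m$metabolism[[parts[2]]][[field]] * factor
  } else if (grepl("^kp_", parameter)) {
    tissue <- sub("^kp_", "", parameter)
    if (!tissue %in% names(m$kp)) {
      abort(paste0("unknown partition coefficient: ", parameter),
            class = "revdosim_validation_error")
    }
    m$kp[tissue] <- m$kp[tissue] * factor
  } else {
    abort(paste0("unknown parameter path: ", parameter),
          class = "revdosim_validation_error")
  }
  m
}

## Core forward-difference normalized coefficient for a scalar function of a
## positive scalar parameter: ((f(p') - f(p)) / (p' - p)) * (p / f(p)).
normalized_sensitivity <- function(f, p, delta = 0.05, central = FALSE) {
  if (!is.finite(p) || p <= 0) {
    abort("parameter must be positive", class = "revdosim_validation_error")
  }
  f0 <- f(p)
  if (!is.finite(f0) || f0 == 0) {
    abort("model output is zero: normalized sensitivity undefined",
          class = "revdosim_validation_error")
  }
  if (central) {
    up <- f(p * (1 + delta)); dn <- f(p * (1 - delta))
    (up - dn) / (2 * delta * p) * (p / f0)
  } else {
    up <- f(p * (1 + delta))
    (up - f0) / (delta * p) * (p / f0)
  }
}

#' Normalized sensitivity coefficient of a model output to one parameter
#'
#' `SC = (C' - C) / (P' - P) x (P / C)` where `P'` is the parameter increased
#' by the perturbation fraction (default +5%) and `C` is the model output
#' (the unbound blood Cmax by default). One-sided forward perturbation by
#' default; `central = TRUE` uses a symmetric difference.
#'
#' @param model A [pbk_model()].
#' @param dose Oral dose (mg/kg bw) at which the output is evaluated —
#'   typically a predicted effect dose such as the BMDL10.
#' @param parameter Parameter path (see [sensitivity_profile()] for the set).
#' @param delta Perturbation fraction (default 0.05).
#' @param central Use a central difference.
#' @param output Function mapping a `pbk_simulation` to a scalar output
#'   (default [unbound_cmax()]).
#' @param hours,n_out Simulation settings.
#' @return The unitless sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(model, dose, parameter, delta = 0.05,
                                    central = FALSE, output = unbound_cmax,
                                    hours = 24, n_out = 300) {
  stopifnot(inherits(model, "pbk_model"))
  run <- function(factor) {
    m <- if (factor == 1) model else perturb_parameter(model, parameter, factor)
    output(simulate_pbk(m, dose, hours = hours, n_out = n_out))
  }
  f0 <- run(1)
  if (!is.finite(f0) || f0 == 0) {
    abort("model output is zero at this dose: normalized sensitivity undefined",
          class = "revdosim_validation_error")
  }
  if (central) {
    (run(1 + delta) - run(1 - delta)) / (2 * delta) / f0
  } else {
    (run(1 + delta) - f0) / delta / f0
  }
}

#' Local sensitivity profile over the chemical-specific parameters
#'
#' Computes normalized sensitivity coefficients for a list of parameters
#' (deduplicated, order preserved) at one exposure dose. The conventional
#' reporting threshold keeps parameters with `|SC| > 0.1`; the full set is
#' always returned with an `influential` flag.
#'
#' @param model A [pbk_model()].
#' @param dose mg/kg bw.
#' @param parameters Character vector of parameter paths; defaults to every
#'   chemical-specific parameter (absorption, fup, clearances, metabolism
#'   constants, incubation unbound fractions, tissue partition coefficients).
#' @param delta Perturbation fraction (default 0.05).
#' @param threshold Influence threshold on `|SC|` (default 0.1).
#' @param ... Passed to [sensitivity_coefficient()].
#' @return A `sensitivity_result` tibble: `parameter`, `sc`, `influential`,
#'   with the dose and delta as attributes.
#' @export
sensitivity_profile <- function(model, dose, parameters = sensitivity_parameters(model),
                                delta = 0.05, threshold = 0.1, ...) {
  parameters <- unique(parameters)
  sc <- vapply(parameters, function(p) {
    sensitivity_coefficient(model, dose, p, delta = delta, ...)
  }, numeric(1))
  out <- tibble(
    parameter = parameters,
    sc = unname(sc),
    influential = abs(unname(sc)) > threshold
  )
  attr(out, "dose_mg_kg") <- dose
  attr(out, "delta") <- delta
  attr(out, "output") <- "unbound Cmax"
  class(out) <- c("sensitivity_result", class(out))
  out
}
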