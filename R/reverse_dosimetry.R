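#' Invert the PBK model: dose producing a given unbound Cmax
#'
#' Reverse dosimetry step: finds the external oral dose whose simulated
#' unbound blood Cmax equals the target concentration, by root-finding on the
#' monotone dose -> Cmax map (relative tolerance 1e-6). Concentrations above
#' the map's range raise an error prompting grid extension; `extend = TRUE`
#' (default) extends the dose grid automatically by up to three decades.
#'
#' @param map A [dose_to_cmax_map()] result (or a `pbk_model`, from which a
#'   default map is built).
#' @param conc Target unbound concentration(s), uM, >= 0.
#' @param extend Automatically extend the dose grid upwards when a target
#'   exceeds the mapped range.
#' @return Dose(s), mg/kg bw; 0 maps to 0.
#' @export
concentration_to_dose <- function(map, conc, extend = TRUE) {
  if (inherits(map, "pbk_model")) map <- dose_to_cmax_map(map)
  stopifnot(inherits(map, "cmax_map"))
  if (any(!is.finite(conc) | conc < 0)) {
    abort("target concentrations must be >= 0",
          class = "revdosim_validation_error")
  }
  hi <- max(map$cmax_unbound_uM)
  if (any(conc > hi)) {
    if (!extend) {
      abort(sprintf(
        "target concentration %.4g uM exceeds the mapped Cmax range (max %.4g uM); extend the dose grid",
        max(conc), hi), class = "revdosim_range_error")
    }
    model <- attr(map, "model")
    args <- attr(map, "sim_args")
    top <- max(map$dose_mg_kg)
    for (k in 1:3) {
      new_doses <- top * 10^seq(0.25, 1, by = 0.25) * 10^(k - 1)
      add <- vapply(new_doses, function(d) {
        do.call(simulate_pbk, c(list(model, d), args))$cmax_unbound_uM
      }, numeric(1))
      map2 <- tibble(dose_mg_kg = c(map$dose_mg_kg, new_doses),
                     cmax_unbound_uM = c(map$cmax_unbound_uM, add))
      if (any(diff(map2$cmax_unbound_uM) <= 0)) {
        abort("extended dose grid lost monotonicity; tighten solver tolerances",
              class = "revdosim_solver_error")
      }
      attr(map2, "interpolator") <- stats::splinefun(
        log(map2$dose_mg_kg), log(map2$cmax_unbound_uM), method = "monoH.FC")
      attr(map2, "model") <- model
      attr(map2, "sim_args") <- args
      class(map2) <- class(map)
      map <- map2
      if (max(map$cmax_unbound_uM) >= max(conc)) break
    }
    if (max(map$cmax_unbound_uM) < max(conc)) {
      abort("target concentration unreachable within the extended dose range",
            class = "revdosim_range_error")
    }
  }
  f <- attr(map, "interpolator")
  lo_d <- log(min(map$dose_mg_kg)); hi_d <- log(max(map$dose_mg_kg))
  vapply(conc, function(cc) {
    if (cc == 0) return(0)
    if (cc <= min(map$cmax_unbound_uM)) {
      ## below the mapped range kinetics are linear: scale the lowest point
      return(min(map$dose_mg_kg) * cc / min(map$cmax_unbound_uM))
    }
    lc <- log(cc)
    r <- stats::uniroot(function(ld) f(ld) - lc, c(lo_d, hi_d), tol = 1e-9)
    exp(r$root)
  }, numeric(1))
}

#' Predict an in vivo dose-response curve by reverse dosimetry
#'
#' Translates an in vitro AChE concentration-response curve into a predicted
#' in vivo dose-response curve: each in vitro concentration (nM, equated to
#' the in vivo unbound blood Cmax after an optional in-vitro-unbound
#' correction) is converted to the oral dose producing it, and paired with
#' the inhibition the fitted curve predicts at that concentration.
#'
#' @param model A [pbk_model()] or a prebuilt [dose_to_cmax_map()].
#' @param ic50_fit An [fit_ic50()] result.
#' @param conc_grid In vitro concentrations (nM) to translate. The default
#'   spans 1 nM - 100 uM in quarter-decade steps.
#' @param fu_invitro Fraction unbound in the in vitro assay medium applied
#'   before equating to the in vivo unbound Cmax (default 1: binding in the
#'   in vitro system taken as negligible).
#' @return A `dose_response_curve` tibble: `dose_mg_kg`, `inhibition_pct`,
#'   `source_conc_nM`, plus the species label; doses strictly increasing and
#'   inhibition non-decreasing.
#' @export
predict_dose_response <- function(model, ic50_fit,
                                  conc_grid = 10^seq(0, 5, by = 0.25),
                                  fu_invitro = 1) {
  stopifnot(inherits(ic50_fit, "ic50_fit"))
  map <- if (inherits(model, "cmax_map")) model else dose_to_cmax_map(model)
  species <- attr(map, "model")$species
  if (any(conc_grid <= 0) || is.unsorted(conc_grid, strictly = TRUE)) {
    abort("conc_grid must be > 0 and strictly increasing",
          class = "revdosim_validation_error")
  }
  conc_uM <- conc_grid * fu_invitro / 1000       # nM -> uM, unbound
  doses <- concentration_to_dose(map, conc_uM)
  inh <- inhibition_at(conc_grid, ic50_fit)
  out <- tibble(
    species = species,
    dose_mg_kg = doses,
    inhibition_pct = inh,
    source_conc_nM = conc_grid
  )
  if (is.unsorted(out$dose_mg_kg, strictly = TRUE)) {
    abort("predicted doses are not strictly increasing",
          class = "revdosim_solver_error")
  }
  if (any(diff(out$inhibition_pct) < 0)) {
    abort("predicted inhibition is not non-decreasing",
          class = "revdosim_solver_error")
  }
  class(out) <- c("dose_response_curve", class(out))
  out
}
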