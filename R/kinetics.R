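#' Michaelis-Menten rate
#'
#' The standard saturable rate law `V = Vmax * S / (Km + S)`.
#'
#' @param S Substrate concentration(s), uM; must be >= 0.
#' @param Km Michaelis constant, uM (> 0).
#' @param Vmax Maximum velocity, nmol/min/mg protein (>= 0).
#' @return Rate(s) in the units of `Vmax`.
#' @export
michaelis_menten_rate <- function(S, Km, Vmax) {
  if (any(!is.finite(S) | S < 0)) {
    abort("substrate concentrations must be >= 0",
          class = "revdosim_validation_error")
  }
  if (!is.finite(Km) || Km <= 0) {
    abort("Km must be > 0", class = "revdosim_validation_error")
  }
  Vmax * S / (Km + S)
}

#' Fit Michaelis-Menten parameters to incubation-rate data
#'
#' Unweighted nonlinear least squares on the pooled replicate points
#' (replicates are not averaged first). Starting values: `Vmax0` is the
#' largest observed rate, `Km0` the concentration whose observed rate is
#' nearest `Vmax0 / 2`; both parameters are bounded positive.
#'
#' @param data A data frame with columns `concentration_uM`,
#'   `rate_nmol_min_mg` and optionally `replicate` (an [incubation
#'   dataset][gen_incubation_data]). At least 4 distinct concentrations are
#'   required.
#' @param on_means Fit replicate means instead of pooled points.
#' @return An object of class `mm_fit`: estimates `Km` (uM) and `Vmax`
#'   (nmol/min/mg protein) with standard errors, the catalytic efficiency
#'   `Vmax/Km` (ml/min/mg protein), residuals and convergence diagnostics.
#'   Supports [tidy()] and [glance()].
#' @export
fit_michaelis_menten <- function(data, on_means = FALSE) {
  stopifnot(is.data.frame(data))
  needed <- c("concentration_uM", "rate_nmol_min_mg")
  if (!all(needed %in% names(data))) {
    abort("data must have columns concentration_uM and rate_nmol_min_mg",
          class = "revdosim_validation_error")
  }
  if (any(data$concentration_uM <= 0)) {
    abort("concentrations must be > 0", class = "revdosim_validation_error")
  }
  if (any(data$rate_nmol_min_mg < 0)) {
    abort("rates must be >= 0", class = "revdosim_validation_error")
  }
  if (length(unique(data$concentration_uM)) < 4) {
    abort("at least 4 distinct substrate concentrations are required",
          class = "revdosim_validation_error")
  }
  if (all(data$rate_nmol_min_mg == 0)) {
    abort("all rates are zero: no saturable signal to fit",
          class = "revdosim_validation_error")
  }
  if (on_means) {
    data <- data |>
      dplyr::group_by(.data$concentration_uM) |>
      dplyr::summarise(rate_nmol_min_mg = mean(.data$rate_nmol_min_mg),
                       .groups = "drop")
  }

  vmax0 <- max(data$rate_nmol_min_mg)
  km0 <- data$concentration_uM[which.min(abs(data$rate_nmol_min_mg - vmax0 / 2))]
  ## fallback starts: Hanes-Woolf linearization (S/v vs S), then coarse
  ## guesses, in case the primary start sits in a flat region of the design
  hw <- tryCatch({
    pos <- data$rate_nmol_min_mg > 0
    co <- stats::coef(stats::lm(I(concentration_uM / rate_nmol_min_mg) ~
                                  concentration_uM, data = data[pos, ]))
    list(Vmax = max(1 / co[[2]], 1e-6), Km = max(co[[1]] / co[[2]], 1e-6))
  }, error = function(e) NULL)
  starts <- Filter(Negate(is.null), list(
    list(Vmax = vmax0, Km = km0),
    hw,
    list(Vmax = vmax0, Km = stats::median(data$concentration_uM)),
    list(Vmax = vmax0, Km = min(data$concentration_uM) / 3)
  ))
  fit <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate_nmol_min_mg ~ Vmax * concentration_uM / (Km + concentration_uM),
        data = data,
        start = st,
        lower = c(Vmax = 1e-12, Km = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) { last_err <<- conditionMessage(e); NULL }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Michaelis-Menten fit failed to converge: ", last_err),
          class = "revdosim_fit_error")
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  structure(
    list(
      Km = unname(est["Km"]),
      Vmax = unname(est["Vmax"]),
      se_Km = unname(se["Km"]),
      se_Vmax = unname(se["Vmax"]),
      catalytic_efficiency = unname(est["Vmax"] / est["Km"]),
      converged = fit$convInfo$isConv %||% TRUE,
      residuals = stats::resid(fit),
      n = nrow(data),
      fit = fit
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g uM (SE %.2g), Vmax = %.4g nmol/min/mg (SE %.2g)\n",
              x$Km, x$se_Km, x$Vmax, x$se_Vmax))
  cat(sprintf("  catalytic efficiency Vmax/Km = %.3g ml/min/mg protein\n",
              x$catalytic_efficiency))
  invisible(x)
}

#' Catalytic efficiency (intrinsic clearance per mg protein)
#'
#' `Vmax / Km`, in ml/min/mg protein when `Vmax` is in nmol/min/mg and `Km`
#' in uM.
#'
#' @param fit An `mm_fit`, or a numeric `Vmax` when `Km` is also given.
#' @param Km Michaelis constant (uM), only when `fit` is numeric.
#' @return Catalytic efficiency (ml/min/mg protein).
#' @export
catalytic_efficiency <- function(fit, Km = NULL) {
  if (inherits(fit, "mm_fit")) return(fit$Vmax / fit$Km)
  if (is.null(Km) || !is.finite(Km) || Km <= 0) {
    abort("Km must be > 0", class = "revdosim_validation_error")
  }
  fit / Km
}

#' Protein scaling factors for in vitro to in vivo extrapolation
#'
#' The conversion factors used to scale per-mg-protein in vitro velocities to
#' whole-organ (liver) or whole-blood capacities: 35 mg microsomal protein/g
#' liver, 80.7 mg cytosolic protein/g liver and 550 mg plasma/g blood, plus
#' the fraction-unbound-in-incubation corrections (`fumic`, `fucyt`,
#' `fupla`), which default to 1 (binding in the incubations taken as
#' negligible).
#'
#' The plasma factor is applied literally to a Vmax expressed per mg plasma
#' protein, which treats mg plasma and mg plasma protein as equivalent; set
#' `plasma_basis_mg_per_g` to e.g. 41 (mg plasma protein per g blood at ~75
#' g protein/L plasma) for the alternative conversion basis.
#'
#' @param microsomal_mg_per_g,cytosolic_mg_per_g,plasma_basis_mg_per_g Scaling
#'   factors (mg protein or mg plasma per g tissue/blood).
#' @param fumic,fucyt,fupla Fractions unbound in the respective incubations,
#'   in (0, 1].
#' @return A `scaling_factors` list.
#' @export
scaling_factors <- function(microsomal_mg_per_g = 35,
                            cytosolic_mg_per_g = 80.7,
                            plasma_basis_mg_per_g = 550,
                            fumic = 1, fucyt = 1, fupla = 1) {
  vals <- c(microsomal_mg_per_g = microsomal_mg_per_g,
            cytosolic_mg_per_g = cytosolic_mg_per_g,
            plasma_basis_mg_per_g = plasma_basis_mg_per_g)
  if (any(!is.finite(vals) | vals <= 0)) {
    abort("scaling factors must be > 0", class = "revdosim_validation_error")
  }
  fr <- c(fumic = fumic, fucyt = fucyt, fupla = fupla)
  if (any(!is.finite(fr) | fr <= 0 | fr > 1)) {
    abort("incubation unbound fractions must lie in (0, 1]",
          class = "revdosim_validation_error")
  }
  structure(as.list(c(as.list(vals), as.list(fr))), class = "scaling_factors")
}

#' Scale an in vitro Vmax to a whole-organ in vivo capacity
#'
#' Deterministic unit conversion: `nmol/min/mg protein x (mg protein/g
#' tissue) x 60 min/h` gives nmol/h/g, which equals umol/h/kg liver (for
#' microsomal and cytosolic matrices) or umol/h/kg blood (plasma matrix).
#'
#' @param fit An `mm_fit` or a numeric Vmax (nmol/min/mg protein).
#' @param matrix One of `"liver microsomes"`, `"liver cytosol"`, `"plasma"`.
#' @param sf A [scaling_factors()] object.
#' @return Scaled Vmax, umol/h per kg liver or per kg blood.
#' @export
scale_vmax_to_in_vivo <- function(fit, matrix, sf = scaling_factors()) {
  vmax <- if (inherits(fit, "mm_fit")) fit$Vmax else fit
  if (!is.finite(vmax) || vmax < 0) {
    abort("Vmax must be >= 0", class = "revdosim_validation_error")
  }
  mgpg <- switch(matrix,
    "liver microsomes" = sf$microsomal_mg_per_g,
    "liver cytosol" = sf$cytosolic_mg_per_g,
    "plasma" = sf$plasma_basis_mg_per_g,
    abort(paste0("unknown incubation matrix: ", matrix),
          class = "revdosim_validation_error")
  )
  ## nmol/min/mg * mg/g * 60 = nmol/h/g = umol/h/kg
  vmax * mgpg * 60
}

#' Reference in vitro kinetic parameters for profenofos hydrolysis
#'
#' The reported apparent Km (uM) and Vmax (nmol/min/mg protein) for
#' conversion of profenofos to its phenol metabolite (BCP) in human and rat
#' liver microsomes, liver cytosol and plasma, as determined in the source
#' in vitro study. These are the package's default metabolism inputs and the
#' generating parameters for the synthetic incubation datasets.
#'
#' @return A tibble with columns `species`, `matrix`, `Km_uM`,
#'   `Vmax_nmol_min_mg`.
#' @export
profenofos_invitro_kinetics <- function() {
  tibble(
    species = rep(c("human", "rat"), each = 3),
    matrix = rep(c("liver microsomes", "liver cytosol", "plasma"), 2),
    Km_uM = c(6.9, 1.4, 158, 8.1, 0.34, 3.6),
    Vmax_nmol_min_mg = c(1.2, 1.1, 0.99, 8.9, 0.95, 0.68)
  )
}

#' Reference in vitro AChE inhibition potencies for profenofos
#'
#' Reported IC50 values: 302 nM for human recombinant AChE and 312 nM for rat
#' erythrocyte (RBC) AChE, with the unit-slope log-logistic activity model.
#' Used as generating parameters for synthetic inhibition datasets and as the
#' in vitro side of the reverse dosimetry.
#'
#' @return A tibble with columns `species`, `enzyme`, `ic50_nM`.
#' @export
profenofos_reference_ic50 <- function() {
  tibble(
    species = c("human", "rat"),
    enzyme = c("recombinant AChE", "RBC AChE"),
    ic50_nM = c(302, 312)
  )
}
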