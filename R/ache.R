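#' Unit-slope log-logistic AChE activity model
#'
#' `Y = 100 / (1 + 10^(X - logIC50))`: percent-of-control enzyme activity as
#' a function of log10 inhibitor concentration, with the slope fixed at 1.
#'
#' @param X log10 concentration (same concentration units as `logIC50`).
#' @param log_ic50 log10 of the IC50.
#' @return Activity, % of control, in (0, 100); strictly decreasing in `X`.
#' @export
logistic_activity <- function(X, log_ic50) {
  100 / (1 + 10^(X - log_ic50))
}

#' Fit an IC50 to concentration-response inhibition data
#'
#' Least-squares fit of the unit-slope log-logistic activity model on the
#' percent-activity scale versus log10 concentration, on the pooled replicate
#' points (replicate means via `on_means = TRUE`). A free-slope variant is
#' available behind `free_slope = TRUE` but is off by default, matching the
#' fixed-slope model.
#'
#' @param data Data frame with columns `concentration_nM`, `activity_pct`
#'   and optionally `replicate` (see [gen_inhibition_data()]). At least 4
#'   distinct concentrations spanning the transition are required; data lying
#'   entirely above 90% or below 10% activity carry no transition and raise
#'   an error.
#' @param free_slope Also estimate a Hill slope (default fixed at 1).
#' @param on_means Fit replicate means instead of pooled points.
#' @return An `ic50_fit`: `log_ic50`, `ic50_nM = 10^log_ic50`, standard
#'   error, optional slope, residual diagnostics. Supports [tidy()] /
#'   [glance()].
#' @export
fit_ic50 <- function(data, free_slope = FALSE, on_means = FALSE) {
  stopifnot(is.data.frame(data))
  if (!all(c("concentration_nM", "activity_pct") %in% names(data))) {
    abort("data must have columns concentration_nM and activity_pct",
          class = "revdosim_validation_error")
  }
  if (any(data$concentration_nM <= 0)) {
    abort("concentrations must be > 0", class = "revdosim_validation_error")
  }
  if (length(unique(data$concentration_nM)) < 4) {
    abort("at least 4 distinct concentrations are required",
          class = "revdosim_validation_error")
  }
  if (on_means) {
    data <- data |>
      dplyr::group_by(.data$concentration_nM) |>
      dplyr::summarise(activity_pct = mean(.data$activity_pct),
                       .groups = "drop")
  }
  mean_act <- tapply(data$activity_pct, data$concentration_nM, mean)
  if (all(mean_act > 90) || all(mean_act < 10)) {
    abort("no activity transition observed: data lie entirely above 90% or below 10% of control",
          class = "revdosim_fit_error")
  }

  data$X <- log10(data$concentration_nM)
  start_log <- data$X[which.min(abs(data$activity_pct - 50))]
  fit <- tryCatch(
    if (free_slope) {
      minpack.lm::nlsLM(activity_pct ~ 100 / (1 + 10^(slope * (X - logIC50))),
                        data = data,
                        start = list(logIC50 = start_log, slope = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(activity_pct ~ 100 / (1 + 10^(X - logIC50)),
                        data = data,
                        start = list(logIC50 = start_log),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) abort(paste0("IC50 fit failed: ", conditionMessage(e)),
                              class = "revdosim_fit_error")
  )
  est <- stats::coef(fit)
  se <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], rownames(co))
  }, error = function(e) rep(NA_real_, length(est)))
  structure(
    list(
      log_ic50 = unname(est["logIC50"]),
      ic50_nM = 10^unname(est["logIC50"]),
      se_log_ic50 = unname(se["logIC50"]),
      slope = if (free_slope) unname(est["slope"]) else 1,
      free_slope = free_slope,
      residuals = stats::resid(fit),
      n = nrow(data),
      fit = fit
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.4g nM (logIC50 %.4g, SE %.2g)%s\n",
              x$ic50_nM, x$log_ic50, x$se_log_ic50,
              if (x$free_slope) sprintf(", slope %.3g", x$slope) else ""))
  invisible(x)
}

#' Percent inhibition at a concentration
#'
#' `100 - activity`: the response scale used for the in vivo dose-response
#' prediction.
#'
#' @param conc Concentration(s), nM, > 0.
#' @param fit An `ic50_fit`.
#' @return Percent AChE inhibition.
#' @export
inhibition_at <- function(conc, fit) {
  stopifnot(inherits(fit, "ic50_fit"))
  if (any(conc <= 0)) {
    abort("concentration must be > 0", class = "revdosim_validation_error")
  }
  100 - 100 / (1 + 10^(fit$slope * (log10(conc) - fit$log_ic50)))
}
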