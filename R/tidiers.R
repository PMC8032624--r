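#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("Km", "Vmax"),
    estimate = c(x$Km, x$Vmax),
    std.error = c(x$se_Km, x$se_Vmax)
  )
}

#' @rdname tidy.mm_fit
#' @return `glance()`: one row with `catalytic_efficiency`, `sigma`,
#'   `converged`, `nobs`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(
    catalytic_efficiency = x$catalytic_efficiency,
    sigma = sqrt(sum(x$residuals^2) / max(x$n - 2, 1)),
    converged = isTRUE(x$converged),
    nobs = x$n
  )
}

#' Tidy an IC50 fit
#'
#' @param x An `ic50_fit`.
#' @param ... Unused.
#' @return One row per parameter (`logIC50`, plus `slope` for the free-slope
#'   variant).
#' @export
tidy.ic50_fit <- function(x, ...) {
  out <- tibble(term = "logIC50", estimate = x$log_ic50,
                std.error = x$se_log_ic50)
  if (x$free_slope) {
    out <- dplyr::bind_rows(out, tibble(term = "slope", estimate = x$slope,
                                        std.error = NA_real_))
  }
  out
}

#' @rdname tidy.ic50_fit
#' @return `glance()`: `ic50_nM`, `sigma`, `nobs`.
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(
    ic50_nM = x$ic50_nM,
    sigma = sqrt(sum(x$residuals^2) / max(x$n - 1, 1)),
    nobs = x$n
  )
}

#' Tidy a benchmark-dose result
#'
#' @param x A `bmd_result`.
#' @param ... Unused.
#' @return Per-model table: `family`, `aic`, `weight`, `bmd`.
#' @export
tidy.bmd_result <- function(x, ...) x$models

#' @rdname tidy.bmd_result
#' @return `glance()`: `bmr`, model-averaged `bmd`, `bmdl`, bootstrap
#'   bookkeeping.
#' @export
glance.bmd_result <- function(x, ...) {
  tibble(
    bmr = x$bmr,
    bmd = x$bmd,
    bmdl = x$bmdl,
    n_boot = x$n_boot,
    n_boot_converged = x$n_boot_converged,
    seed = x$seed
  )
}
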