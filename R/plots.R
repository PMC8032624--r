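#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point scale_x_log10
#'   scale_y_log10 labs theme_minimal geom_col coord_flip geom_hline
NULL

#' @export
ggplot2::autoplot

#' Plot a PBK simulation
#'
#' Concentration-time profiles for a selection of compartments.
#'
#' @param object A `pbk_simulation`.
#' @param compartments Compartments to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbk_simulation <- function(object,
                                    compartments = c("venous_blood", "liver",
                                                     "fat", "brain"),
                                    ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$compartment %in% compartments)
  ggplot(df, aes(x = .data$time_h, y = .data$concentration_uM,
                 colour = .data$compartment)) +
    geom_line() +
    labs(x = "time (h)", y = "concentration (µM)",
         title = sprintf("%s, %s, %.3g mg/kg bw", object$model$chem$name,
                         object$model$species, object$oral_dose)) +
    theme_minimal()
}

#' Plot a dose to unbound-Cmax map
#'
#' @param object A `cmax_map`.
#' @param ... Unused.
#' @return A ggplot (log-log).
#' @export
autoplot.cmax_map <- function(object, ...) {
  ggplot(object, aes(x = .data$dose_mg_kg, y = .data$cmax_unbound_uM)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "oral dose (mg/kg bw)", y = "unbound Cmax (µM)") +
    theme_minimal()
}

#' Plot a predicted in vivo dose-response curve
#'
#' @param object A `dose_response_curve` (or several row-bound together).
#' @param ... Unused.
#' @return A ggplot with log dose axis.
#' @export
autoplot.dose_response_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$dose_mg_kg, y = .data$inhibition_pct,
                     colour = .data$species)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = "oral dose (mg/kg bw)", y = "predicted AChE inhibition (%)") +
    theme_minimal()
}

#' Plot a sensitivity profile
#'
#' Bar chart of normalized sensitivity coefficients with the conventional
#' |SC| = 0.1 influence threshold marked.
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), abs(.data$sc))
  df$parameter <- factor(df$parameter, levels = df$parameter)
  ggplot(df, aes(x = .data$parameter, y = .data$sc,
                 fill = .data$influential)) +
    geom_col() +
    geom_hline(yintercept = c(-0.1, 0.1), linetype = 2, linewidth = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "normalized sensitivity coefficient") +
    theme_minimal()
}
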