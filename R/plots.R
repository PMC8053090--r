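# ggplot2 helpers for the main result types.

#' Plot a co-enrichment profile across the 16 lane fractions
#'
#' @param object An `uvrdh_coenrichment`.
#' @param log_y Use a log10 y-axis (as the study's profile figures do)?
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uvrdh_coenrichment
#' @export
autoplot.uvrdh_coenrichment <- function(object, log_y = TRUE, ...) {
  df <- object$profile
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                        y = .data$coenrichment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[object$peak_fraction, ],
                        colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Fraction (1 = well, largest fragments)",
                  y = "RDH x PD co-enrichment")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot gel lane profiles by channel and timepoint
#'
#' @param lanes Long lane tibble (`timepoint`, `channel`, `position`,
#'   `signal`; a `replicate` column facets further).
#' @return A ggplot.
#' @export
plot_lane_profiles <- function(lanes) {
  ggplot2::ggplot(lanes, ggplot2::aes(x = .data$position, y = .data$signal,
                                      colour = factor(.data$timepoint))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "Migration (0 = well)", y = "Signal",
                  colour = "min post-UV")
  }

#' Plot lesion removal kinetics
#'
#' @param kinetics Tibble from [percent_remaining()] (optionally with a
#'   `strain` column for colour).
#' @return A ggplot.
#' @export
plot_removal_kinetics <- function(kinetics) {
  aes <- if ("strain" %in% names(kinetics)) {
    ggplot2::aes(x = .data$time_min, y = .data$percent_remaining,
                 colour = .data$strain)
  } else {
    ggplot2::aes(x = .data$time_min, y = .data$percent_remaining)
  }
  ggplot2::ggplot(dplyr::filter(kinetics, .data$time_min >= 0), aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Minutes post-UV", y = "% lesions remaining")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
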