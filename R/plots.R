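#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot CEST profiles
#'
#' I/I0 against saturation offset, one panel per residue, coloured by B1
#' field.
#'
#' @param object A `cest_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cest_dataset <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset_ppm, y = .data$i_over_i0,
                               colour = factor(.data$b1_hz))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~residue) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "15N offset (ppm)", y = "I/I0",
                  colour = "B1 (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a CEST fit over the data
#'
#' @param object A `cest_fit`.
#' @param data The fitted `cest_dataset` (for the observed points).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cest_fit <- function(object, data = NULL, ...) {
  fitted <- fitted_cest_profiles(object)
  p <- ggplot2::ggplot(fitted,
                       ggplot2::aes(x = .data$offset_ppm,
                                    colour = factor(.data$b1_hz)))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(data),
      ggplot2::aes(y = .data$i_over_i0), size = 0.3, alpha = 0.5)
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::facet_wrap(~residue) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "15N offset (ppm)", y = "I/I0", colour = "B1 (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a phosphorylation progress curve
#'
#' @param object A `progress_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.progress_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fraction - .data$sd,
      ymax = .data$fraction + .data$sd), linewidth = 0.3, size = 0.3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time (min)", y = "fraction phosphorylated") +
    ggplot2::theme_minimal()
}

#' Plot a fitted DSC endotherm
#'
#' @param object A `dsc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsc_fit <- function(object, ...) {
  d <- object$corrected
  d$fitted <- model_cp(d$temp_c, object$t_m_c, object$dh_cal,
                       object$dh_vh)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temp_c)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cp), size = 0.3,
                        alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_vline(xintercept = object$t_m_c, linetype = 2) +
    ggplot2::labs(x = "temperature (deg C)",
                  y = "excess Cp (kJ mol-1 K-1)") +
    ggplot2::theme_minimal()
}

#' Chemical-shift-perturbation heat bar
#'
#' Per-residue weighted CSP bar plot; residues missing from either list
#' are shown as grey ticks at zero.
#'
#' @param csp Output of [csp_map()].
#' @return A ggplot.
#' @export
plot_csp_map <- function(csp) {
  ggplot2::ggplot(csp, ggplot2::aes(x = .data$residue_number,
                                    y = .data$weighted_csp,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(matched = "steelblue",
                                          only_a = "grey70",
                                          only_b = "grey70")) +
    ggplot2::labs(x = "residue", y = "weighted CSP (ppm)") +
    ggplot2::theme_minimal()
}

#' Line-broadening footprint plot
#'
#' Bound/free intensity ratios with the mean and the half/full
#' standard-deviation classification bands.
#'
#' @param footprint Output of [broadening_footprint()].
#' @return A ggplot.
#' @export
plot_footprint <- function(footprint) {
  m <- attr(footprint, "mean")
  s <- attr(footprint, "stdv")
  ggplot2::ggplot(footprint,
                  ggplot2::aes(x = .data$residue_number,
                               y = .data$intensity_ratio,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = m, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(m - 0.5 * s, m - s), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(none = "grey60",
                                          moderate = "orange",
                                          strong = "red")) +
    ggplot2::labs(x = "residue", y = "bound/free intensity ratio") +
    ggplot2::theme_minimal()
}
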