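#' Box plot of per-strain half-life distributions
#'
#' @param half_lives Long tibble with columns `strain` and `half_life`
#'   (e.g. from [filter_reliable_both()]).
#' @return A ggplot object.
#' @export
plot_half_life_box <- function(half_lives) {
  ggplot2::ggplot(half_lives,
                  ggplot2::aes(x = .data$strain, y = .data$half_life,
                               fill = .data$strain)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "half-life (min)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of half-life fold change versus adjusted p-value
#'
#' @param volcano Tibble from [volcano_table()].
#' @return A ggplot object; selected transcripts are highlighted.
#' @export
plot_volcano <- function(volcano) {
  ggplot2::ggplot(volcano,
                  ggplot2::aes(x = .data$log2_fc, y = -log10(.data$q_bh),
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log2 fold change in half-life",
                  y = "-log10 adjusted p", colour = "selected") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_exponential Semi-log plot of the series with the fitted
#'   exponential.
#' @param object A `decay_fit` object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  line <- tibble(
    time_min = seq(min(dat$time_min), max(dat$time_min), length.out = 100)
  )
  line$value <- exp(object$intercept + object$slope * line$time_min)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = object$label, x = "time (min)", y = "signal") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_michaelis_menten Velocities and fitted Michaelis--Menten
#'   curves per enzyme concentration (mean parameters across replicates).
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  dat <- object$data
  curves <- dat |>
    distinct(.data$e_nm) |>
    reframe(s_um = seq(0, max(dat$s_um) * 1.05, length.out = 100),
            .by = "e_nm") |>
    mutate(v_um_min = object$kcat_mean * (.data$e_nm / 1000) * .data$s_um /
             (object$km_mean + .data$s_um))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$s_um, y = .data$v_um_min,
                                    colour = factor(.data$e_nm))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "substrate (uM)", y = "velocity (uM/min)",
                  colour = "enzyme (nM)") +
    ggplot2::theme_minimal()
}
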