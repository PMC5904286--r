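#' Plot a validation report
#'
#' Measured group means against the theoretical dilution-series design on
#' log10–log10 axes, with per-chip estimates, the fitted linearity line and
#' the identity line; the LoD and LoQ are drawn as horizontal references.
#'
#' @param object A `cdpcr_validation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cdpcr_validation <- function(object, ...) {
  groups <- dplyr::filter(object$groups, !.data$is_ntc,
                          .data$theoretical_copies_per_ul > 0)
  est <- dplyr::filter(object$estimates, !.data$is_ntc,
                       .data$theoretical_copies_per_ul > 0)
  p <- ggplot2::ggplot(groups,
                       ggplot2::aes(x = .data$theoretical_copies_per_ul,
                                    y = .data$mean_copies_per_ul)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point(data = est,
                        ggplot2::aes(y = .data$copies_per_ul_template),
                        alpha = 0.4, size = 1.5) +
    ggplot2::geom_point(size = 3, shape = 21, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "theoretical concentration (copies/µl)",
      y = "measured concentration (copies/µl)",
      title = paste0("cdPCR dilution series: ", object$target_id),
      subtitle = if (!is.null(object$linearity)) {
        sprintf("slope %.3f, r² %.4f, efficiency %.0f%%",
                object$linearity$slope, object$linearity$r_squared,
                object$linearity$efficiency_pct)
      }
    )
  if (!is.null(object$linearity)) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.5,
                                  colour = "steelblue")
  }
  for (ref in c(object$lod_copies_per_ul, object$loq_copies_per_ul)) {
    if (!is.na(ref)) {
      p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                                   colour = "firebrick", alpha = 0.6)
    }
  }
  p
}

#' Plot detectable difference against replicate number
#'
#' Power curves for comparing enumeration methods: the smallest detectable
#' mean difference (percent of the mean, two-sided two-sample t test) as a
#' function of replicates per group, one curve per replicate-variability
#' level.
#'
#' @param rsd_pct Numeric vector of replicate %RSD levels, one curve each.
#' @param n_range Integer range of replicate numbers to span.
#' @param alpha,power Test size and target power.
#' @return A ggplot.
#' @examples
#' plot_power_curves(c(15, 10, 5))
#' @export
plot_power_curves <- function(rsd_pct = c(15, 10, 5), n_range = 2:25,
                              alpha = 0.05, power = 0.80) {
  curves <- tidyr::expand_grid(rsd_pct = rsd_pct, n = n_range) %>%
    rowwise() %>%
    mutate(detectable = detectable_difference(.data$n, .data$rsd_pct,
                                              alpha, power)) %>%
    ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$n, y = .data$detectable,
                               colour = factor(.data$rsd_pct))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "replicates per group",
                  y = "detectable difference (% of mean)",
                  colour = "%RSD",
                  title = sprintf(
                    "Two-sample t power curves (alpha = %.2g, power = %.2g)",
                    alpha, power))
}
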