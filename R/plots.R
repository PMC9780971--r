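# ggplot2 helpers for the package's result types.

#' Plot a cumulative work profile with its PMF estimates
#'
#' Mean work with the 95% confidence ribbon, overlaid with the Jarzynski
#' and second-cumulant PMF curves.
#'
#' @param object a `pmf_estimate`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pmf_estimate
#' @export
autoplot.pmf_estimate <- function(object, ...) {
  tb <- tidy(object)
  curves <- tb |>
    tidyr::pivot_longer(c("mean_work", "pmf_jarzynski", "pmf_cumulant2"),
                        names_to = "estimate", values_to = "energy")
  ggplot2::ggplot(curves, ggplot2::aes(.data$distance_nm, .data$energy,
                                       colour = .data$estimate)) +
    ggplot2::geom_ribbon(
      data = tb,
      ggplot2::aes(.data$distance_nm,
                   ymin = .data$mean_work - .data$ci_half,
                   ymax = .data$mean_work + .data$ci_half),
      inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "anchor distance (nm)",
                  y = "energy (kcal/mol)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-residue fluctuation profiles
#'
#' @param profiles a fluctuation tibble (`resno` plus `rmsf` or `value`),
#'   optionally with `segment` or `window` grouping columns.
#' @return a ggplot.
#' @export
plot_fluctuation_profile <- function(profiles) {
  val <- if ("rmsf" %in% names(profiles)) "rmsf" else "value"
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(.data$resno, .data[[val]]))
  if ("segment" %in% names(profiles)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$segment)))
  } else if ("window" %in% names(profiles)) {
    p <- p + ggplot2::geom_line() +
      ggplot2::facet_wrap(~window, scales = "free_x")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "residue",
                    y = if (val == "rmsf") "RMSF (Å)" else
                      "square fluctuation (Å²)",
                    colour = "segment") +
    ggplot2::theme_minimal()
}

#' Plot conservation / cMI / pMI profiles along the alignment
#'
#' @param kl tibble from [kl_conservation()].
#' @param cmi tibble from [cumulative_mi()] (optional).
#' @param pmi tibble from [proximity_mi()] (optional).
#' @return a ggplot with one facet per statistic.
#' @export
plot_coevolution_profile <- function(kl, cmi = NULL, pmi = NULL) {
  long <- dplyr::bind_rows(
    dplyr::transmute(kl, column = .data$column, statistic = "KL (bits)",
                     value = .data$kl),
    if (!is.null(cmi)) dplyr::transmute(cmi, column = .data$column,
                                        statistic = "cMI (bits)",
                                        value = .data$cmi),
    if (!is.null(pmi)) dplyr::transmute(pmi, column = .data$column,
                                        statistic = "pMI (bits)",
                                        value = .data$pmi))
  ggplot2::ggplot(long, ggplot2::aes(.data$column, .data$value)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$statistic),
                        scales = "free_y") +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pocket-volume series and distribution
#'
#' @param object a `volume_result` with a per-frame series.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot volume_result
#' @export
autoplot.volume_result <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$frame, .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = mean(tb$volume), linetype = 2) +
    ggplot2::labs(x = "frame", y = "pocket volume (Å³)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
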