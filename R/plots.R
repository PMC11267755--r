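#' Plot a peak list as a stick spectrum
#'
#' @param x A `peaklist`.
#' @param annotations Optional tibble with columns `mz` and `label` (e.g. the
#'   assignments of a [match_peaks()] result, using `peak_mz`/`label`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(x, annotations = NULL) {
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = attr(x, "label") %||% NULL,
                  subtitle = paste0(attr(x, "mode") %||% "", " spectrum")) +
    ggplot2::theme_minimal()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- annotations
    if ("peak_mz" %in% names(ann) && !"mz" %in% names(ann)) ann$mz <- ann$peak_mz
    ann$y <- x$intensity[vapply(ann$mz, function(m)
      which.min(abs(x$mz - m)), integer(1))]
    p <- p + ggplot2::geom_text(
      data = ann, ggplot2::aes(x = .data$mz, y = .data$y, label = .data$label),
      vjust = -0.4, size = 3, angle = 45, hjust = 0)
  }
  p
}

#' Plot a titration calibration fit
#'
#' Measured intensity ratios against known concentration ratios with the
#' fitted calibration line and its R-squared.
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.titration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$known, y = .data$measured)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "known concentration ratio", y = "measured intensity ratio",
      subtitle = sprintf("slope (response factor) = %.3f, R² = %.4f",
                         object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
plot.titration_fit <- function(x, ...) print(autoplot.titration_fit(x, ...))

#' Plot a conservation profile
#'
#' Dominant-residue frequencies per code position in the T and NT categories;
#' key residues (if `calls` given) are outlined.
#'
#' @param profile A `conservation_profile`.
#' @param calls Optional [call_key_residues()] output.
#' @param min_freq Hide residues below this frequency in both categories.
#' @return A ggplot object.
#' @export
plot_conservation <- function(profile, calls = NULL, min_freq = 0.05) {
  d <- profile |>
    dplyr::group_by(.data$code_index, .data$residue) |>
    dplyr::filter(max(.data$freq) >= min_freq) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$code_index),
                                       y = .data$residue,
                                       fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~category) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "frequency") +
    ggplot2::labs(x = "code position", y = "residue") +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    k <- calls[calls$is_key, , drop = FALSE]
    if (nrow(k) > 0) {
      p <- p + ggplot2::geom_tile(
        data = tidyr::crossing(k[, c("code_index", "residue")],
                               category = factor(c("T", "NT"),
                                                 levels = c("T", "NT"))),
        ggplot2::aes(x = factor(.data$code_index), y = .data$residue),
        fill = NA, color = "red", linewidth = 0.8, inherit.aes = FALSE)
    }
  }
  p
}
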