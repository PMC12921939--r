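#' Grayscale plot of one visual field
#'
#' Draws the 10-2 tessellation: one 2x2-degree tile per location, filled on
#' a grayscale (dark = low sensitivity) with the numeric decibel value
#' overlaid, plus a gray oval at the physiological blind-spot position —
#' outside the tested field, but it shows laterality at a glance (right
#' eyes: oval on the right). In `"equivalent"` mode head-mounted values are
#' harmonized before plotting (`+offset_db`, exact 0 dB stays 0).
#'
#' @param field A single-eye field tibble with `x_deg`, `y_deg` and either
#'   `sensitivity_db` or `true_db`.
#' @param mode `"raw"` (plot values as stored) or `"equivalent"` (apply the
#'   harmonization rule first).
#' @param offset_db Offset used by `"equivalent"` mode.
#' @param fill_limits Grayscale anchor range in dB.
#' @return A ggplot object.
#' @examples
#' set.seed(1)
#' plot_field(make_true_field("RP"))
#' @export
plot_field <- function(field, mode = c("raw", "equivalent"), offset_db = 14,
                       fill_limits = c(0, 35)) {
  mode <- match.arg(mode)
  value_col <- if ("sensitivity_db" %in% names(field)) {
    "sensitivity_db"
  } else if ("true_db" %in% names(field)) {
    "true_db"
  } else {
    stop("field needs a `sensitivity_db` or `true_db` column", call. = FALSE)
  }
  eyes <- unique(field[["eye"]] %||% "OD")
  if (length(eyes) != 1) {
    stop("plot_field() draws one eye at a time; got: ",
         paste(eyes, collapse = ", "), call. = FALSE)
  }
  v <- field[[value_col]]
  if (mode == "equivalent") v <- to_octopus_equivalent(pmax(v, 0), offset_db)
  shade <- pmin(pmax(v, fill_limits[1]), fill_limits[2])
  shade[is.infinite(v)] <- fill_limits[1]
  df <- tibble::tibble(
    x = field$x_deg, y = field$y_deg, value = v, shade = shade,
    label = ifelse(is.infinite(v), "<0", sprintf("%.0f", v))
  )
  bs <- blind_spot_position(eyes)
  title <- sprintf("%s %s (%s)%s",
                   field[["subject_id"]][1] %||% "", eyes,
                   field[["diagnosis"]][1] %||% field[["device"]][1] %||%
                     value_col,
                   if (mode == "equivalent") " [equivalent dB]" else "")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$shade),
                       width = 2, height = 2, color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::annotate("point", x = bs$x_deg, y = bs$y_deg, shape = 21,
                      size = 8, fill = "grey50", color = "grey30") +
    ggplot2::scale_fill_gradient(low = "grey10", high = "white",
                                 limits = fill_limits, name = "dB") +
    ggplot2::coord_fixed(xlim = c(-17, 17), ylim = c(-11, 11)) +
    ggplot2::labs(title = trimws(title), x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.deming_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("Deming regression: slope %.2f, intercept %.1f dB",
                      object$slope, object$intercept),
      x = "projection sensitivity (dB)",
      y = "head-mounted sensitivity (dB)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Bland-Altman: mean %.2f dB, LoA [%.1f, %.1f]",
                      object$mean_diff, object$loa_low, object$loa_high),
      x = "mean of paired measurements (dB)",
      y = "difference (dB)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
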