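#' Generate the 10-2 test grid
#'
#' The 10-2 pattern tests the central 10 degrees of the visual field at 68
#' locations on a 2-degree lattice offset 1 degree from the meridians: all
#' points with odd-integer coordinates in `{-9, ..., 9}` whose squared
#' eccentricity `x^2 + y^2` does not exceed 82. Ordering is deterministic:
#' superior rows first (descending y), left to right within a row.
#'
#' @return A tibble with integer columns `x_deg`, `y_deg` (one row per
#'   location, 68 rows) and attribute `pattern = "10-2"`. Positive x is to
#'   the right of the printout, positive y superior.
#' @examples
#' nrow(generate_10_2())  # 68
#' @export
generate_10_2 <- function() {
  odd <- c(-9L, -7L, -5L, -3L, -1L, 1L, 3L, 5L, 7L, 9L)
  grid <- tidyr::expand_grid(y_deg = rev(odd), x_deg = odd)
  grid <- dplyr::filter(grid, .data$x_deg^2 + .data$y_deg^2 <= 82)
  out <- tibble::as_tibble(grid[, c("x_deg", "y_deg")])
  attr(out, "pattern") <- "10-2"
  out
}

#' Physiological blind-spot position for plotting
#'
#' The blind spot lies about 15 degrees temporal to fixation, just below the
#' horizontal meridian — outside the 10-2 test field, but drawing it on field
#' plots identifies laterality at a glance: for right eyes (OD) it sits on
#' the right side of the plot, for left eyes (OS) on the left.
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A tibble with one row and columns `x_deg`, `y_deg`.
#' @examples
#' blind_spot_position("OD")  # x = 15
#' @export
blind_spot_position <- function(eye) {
  eye <- match.arg(eye, c("OD", "OS"))
  tibble::tibble(x_deg = if (eye == "OD") 15 else -15, y_deg = -2)
}
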