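# Saaty judgment scale: verbal anchors, crisp scores, reciprocals, snapping.

#' The 17 admissible Saaty judgment values
#'
#' The fundamental comparison scale admits the integers 1..9, their
#' reciprocals, and nothing else: 1/9, 1/8, ..., 1/2, 1, 2, ..., 9.
#' Even integers (2, 4, 6, 8) are intermediate values between the odd
#' verbal anchors and are accepted numerically.
#'
#' @return A sorted numeric vector of length 17.
#' @seealso [saaty_scale()] for the anchor table, [snap_saaty()] for
#'   projecting arbitrary ratios onto the grid.
#' @export
#' @examples
#' saaty_values()
saaty_values <- function() {
  sort(c(1 / (9:2), 1:9))
}

#' Verbal anchor table for the pairwise comparison scale
#'
#' The five verbal anchors of the comparison scale with their crisp
#' scores and reciprocal scores (reciprocals shown rounded to two
#' decimals, as conventionally printed).
#'
#' @return A tibble with columns `anchor`, `crisp_score`,
#'   `reciprocal`, and `reciprocal_2dp`.
#' @export
saaty_scale <- function() {
  tibble(
    anchor = c(
      "Equal importance", "Moderate", "Strong importance",
      "Very strong importance", "Extremely preferred"
    ),
    crisp_score = c(1, 3, 5, 7, 9),
    reciprocal = 1 / c(1, 3, 5, 7, 9),
    reciprocal_2dp = round(1 / c(1, 3, 5, 7, 9), 2)
  )
}

#' Test membership of the admissible judgment grid
#'
#' @param x Numeric vector of candidate judgments.
#' @param tol Absolute tolerance for grid membership (reciprocals such
#'   as 1/3 are not exactly representable in decimal input).
#' @return Logical vector.
#' @export
is_saaty_value <- function(x, tol = 1e-6) {
  grid <- saaty_values()
  vapply(x, function(v) {
    is.finite(v) && v > 0 && any(abs(v - grid) < tol)
  }, logical(1))
}

#' Snap a positive ratio onto the admissible judgment grid
#'
#' A ratio below 1 is inverted, snapped to the nearest admissible value
#' at or above 1, and re-inverted. Snapping the dominant side of the
#' judgment keeps the operation reciprocal-symmetric:
#' `snap_saaty(1/x) == 1/snap_saaty(x)` exactly, and the error on the
#' dominant side is at most half the gap between adjacent grid values.
#'
#' @param x Positive numeric vector of ratios.
#' @return Numeric vector on the 17-value grid.
#' @export
#' @examples
#' snap_saaty(c(2.7, 1 / 2.7, 0.12))
snap_saaty <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  upper <- 1:9
  vapply(x, function(v) {
    inv <- v < 1
    r <- if (inv) 1 / v else v
    s <- upper[which.min(abs(r - upper))]
    if (inv) 1 / s else s
  }, numeric(1))
}

#' Clip a positive ratio into the representable judgment range
#'
#' @param x Positive numeric vector.
#' @return `x` clipped into `[1/9, 9]`.
#' @export
clip_saaty <- function(x) {
  pmin(pmax(x, 1 / 9), 9)
}
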