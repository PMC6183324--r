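# Published-result fixtures: the group-level weights reported by the
# source questionnaire study (printed to 3 decimals). These are
# validation references — the underlying raw judgments of the 300
# respondents were never published, so the printed weights cannot be
# recomputed, only transcribed and compared against.

#' Labels of the three published study groups
#'
#' Nurses on 8-hour 3-3-3-3 rotations, support staff on 12 h on / 24 h
#' off, and security staff on 24 h on / 48 h off.
#'
#' @return Character vector of group labels.
#' @export
published_groups <- function() {
  c("nurses_8h", "support_12_24", "security_24_48")
}

#' Published group-level weights fixture
#'
#' Returns the printed criterion, local sub-criterion, and alternative
#' weights for one study group, exactly as transcribed. A sum check per
#' weight block is attached: printed values that fail to sum to 1
#' beyond 3-decimal rounding slack raise a warning flag (the security
#' group's alternative weights, as printed, sum to 1.26) but never an
#' error — the fixture stores what was printed.
#'
#' @param group One of [published_groups()].
#' @param warn Emit an R warning when a sum check fails? Default `TRUE`.
#' @return A list of class `anp_published` with tibbles `criteria`
#'   (`node`, `weight`), `subcriteria` (`criterion`, `node`, `weight` —
#'   local within the parent criterion), `alternatives` (`node`,
#'   `weight`), and `sum_checks` (`block`, `sum`, `flagged`), plus the
#'   `group` label.
#' @export
#' @examples
#' published_weights("nurses_8h")$criteria
published_weights <- function(group, warn = TRUE) {
  group <- match.arg(group, published_groups())
  all <- published_weights_table()
  g <- dplyr::filter(all, .data$group == !!group)
  criteria <- g |>
    dplyr::filter(.data$level == "criterion") |>
    dplyr::select("node", "weight")
  subcriteria <- g |>
    dplyr::filter(.data$level == "subcriterion") |>
    dplyr::select("criterion", "node", "weight")
  alternatives <- g |>
    dplyr::filter(.data$level == "alternative") |>
    dplyr::select("node", "weight")
  checks <- dplyr::bind_rows(
    tibble(block = "criteria", sum = sum(criteria$weight)),
    subcriteria |>
      dplyr::group_by(.data$criterion) |>
      dplyr::summarise(sum = sum(.data$weight), .groups = "drop") |>
      dplyr::transmute(
        block = paste0("subcriteria:", .data$criterion),
        sum = .data$sum
      ),
    tibble(block = "alternatives", sum = sum(alternatives$weight))
  )
  # 3-decimal printing can misstate a k-term sum by up to k * 0.0005;
  # allow 0.01 before flagging a genuine inconsistency.
  checks$flagged <- abs(checks$sum - 1) > 0.01
  if (warn && any(checks$flagged)) {
    warn(sprintf(
      "Printed weights for group '%s' do not sum to 1 in block(s): %s",
      group,
      paste(sprintf(
        "%s (sum %.3f)",
        checks$block[checks$flagged], checks$sum[checks$flagged]
      ), collapse = ", ")
    ))
  }
  structure(
    list(
      group = group, criteria = criteria, subcriteria = subcriteria,
      alternatives = alternatives, sum_checks = checks
    ),
    class = "anp_published"
  )
}

#' @export
print.anp_published <- function(x, ...) {
  cat(sprintf(
    "<anp_published> group %s: %d criteria, %d sub-criteria, %d alternatives\n",
    x$group, nrow(x$criteria), nrow(x$subcriteria), nrow(x$alternatives)
  ))
  if (any(x$sum_checks$flagged)) {
    cat(
      "  sum-check flag:",
      paste(x$sum_checks$block[x$sum_checks$flagged], collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' All published weights as one long tibble
#'
#' @return A tibble with columns `group`, `level` (`criterion`,
#'   `subcriterion`, `alternative`), `criterion` (parent, for
#'   sub-criteria), `node`, `weight`.
#' @export
published_weights_table <- function() {
  path <- system.file("extdata", "published_weights.csv",
    package = "shiftanp", mustWork = TRUE
  )
  readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      group = readr::col_character(),
      level = readr::col_character(),
      criterion = readr::col_character(),
      node = readr::col_character(),
      weight = readr::col_double()
    )
  )
}
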