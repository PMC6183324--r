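# Report emission: JSON (full precision), CSV, and markdown tables
# mirroring the published layout (3 decimals, round-half-even).

#' Serialize an ANP result to JSON
#'
#' Full-precision, deterministic (no timestamps): identical inputs give
#' byte-identical JSON. Every number shown by [report_markdown()]
#' appears here.
#'
#' @param result An `anp_result`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(result, path = NULL) {
  payload <- list(
    network = result$network$name,
    settings = result$settings,
    groups = purrr::map(result$groups, function(gr) {
      list(
        n_respondents = gr$n_respondents,
        n_excluded = gr$n_excluded,
        criterion_weights = gr$criterion_weights,
        subcriteria_local = gr$subcriteria_local,
        alternatives = gr$alternatives,
        desirability = gr$desirability,
        consistency = gr$consistency
      )
    })
  )
  js <- jsonlite::toJSON(payload,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(js)
}

#' Write an ANP result's weight tables to CSV
#'
#' One long CSV (the [tidy.anp_result()] table) plus one alternatives
#' CSV with limit-path weights and desirability indices.
#'
#' @param result An `anp_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  weights_path <- file.path(dir, "weights.csv")
  alts_path <- file.path(dir, "alternatives.csv")
  readr::write_csv(tidy(result), weights_path)
  alts <- purrr::map_dfr(names(result$groups), function(g) {
    dplyr::mutate(result$groups[[g]]$alternatives, group = g, .before = 1)
  })
  readr::write_csv(alts, alts_path)
  invisible(c(weights_path, alts_path))
}

#' Export a supermatrix as CSV
#'
#' Node-by-node matrix with a header row and a leading `node` id
#' column.
#'
#' @param W Supermatrix (any stage).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(W, path) {
  df <- dplyr::bind_cols(
    tibble(node = rownames(W)),
    as_tibble(as.data.frame(W))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Human-readable markdown report
#'
#' Per group: a criterion / sub-criterion weight table in the layout of
#' the published results tables, followed by the alternative ranking.
#' Weights are printed to 3 decimals (round-half-even); the JSON report
#' carries the same quantities at full precision.
#'
#' @param result An `anp_result`.
#' @return A character vector of markdown lines, invisibly printable
#'   with `cat(..., sep = "\n")`.
#' @export
report_markdown <- function(result) {
  fmt <- function(x) sprintf("%.3f", round(x, 3))
  lines <- c(sprintf("# ANP weights: %s", result$network$name), "")
  labels <- setNames(result$network$nodes$label, result$network$nodes$id)
  for (g in names(result$groups)) {
    gr <- result$groups[[g]]
    lines <- c(
      lines, sprintf("## Group: %s", g), "",
      sprintf(
        "Respondents: %d (excluded by CR: %d)",
        gr$n_respondents, gr$n_excluded
      ), "",
      "| Criterion | Criterion weight | Sub-criterion | Sub-criterion weight |",
      "|---|---|---|---|"
    )
    for (i in seq_len(nrow(gr$criterion_weights))) {
      cr <- gr$criterion_weights$node[i]
      subs <- dplyr::filter(gr$subcriteria_local, .data$criterion == cr)
      if (nrow(subs) == 0) {
        lines <- c(lines, sprintf(
          "| %s | %s | | |", labels[[cr]], fmt(gr$criterion_weights$weight[i])
        ))
        next
      }
      for (j in seq_len(nrow(subs))) {
        lines <- c(lines, sprintf(
          "| %s | %s | %s | %s |",
          if (j == 1) labels[[cr]] else "",
          if (j == 1) fmt(gr$criterion_weights$weight[i]) else "",
          labels[[subs$node[j]]], fmt(subs$weight[j])
        ))
      }
    }
    lines <- c(
      lines, "",
      "| Rank | Alternative | Weight | Desirability (normalized) |",
      "|---|---|---|---|"
    )
    for (i in seq_len(nrow(gr$alternatives))) {
      a <- gr$alternatives[i, ]
      lines <- c(lines, sprintf(
        "| %d | %s | %s | %s |",
        a$rank, labels[[a$node]], fmt(a$weight), fmt(a$d_norm)
      ))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Bar-chart overview of an ANP result
#'
#' Criterion weights per group (faceted), the standard first look at a
#' multi-group prioritization.
#'
#' @param object An `anp_result`.
#' @param level `"criteria"` (default) or `"alternatives"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anp_result <- function(object, level = c("criteria", "alternatives"),
                                ...) {
  level <- match.arg(level)
  td <- tidy(object)
  kind <- if (level == "criteria") "criteria" else "alternatives"
  dat <- dplyr::filter(td, .data$kind == !!kind)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$weight),
      y = .data$weight, fill = .data$group
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = NULL, y = "Normalized weight",
      title = sprintf(
        "%s weights by group",
        if (level == "criteria") "Criterion" else "Alternative"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of alternative weights for one group
#'
#' @param result An `anp_result`.
#' @param group Group label; default the first group.
#' @return A ggplot object.
#' @export
plot_alternatives <- function(result, group = names(result$groups)[1]) {
  gr <- result$groups[[group]]
  if (is.null(gr)) abort(sprintf("No group '%s' in result.", group))
  labels <- setNames(result$network$nodes$label, result$network$nodes$id)
  dat <- dplyr::mutate(gr$alternatives, label = labels[.data$node])
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$weight), y = .data$weight
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Normalized weight",
      title = sprintf("Shift alternative weights: %s", group)
    ) +
    ggplot2::theme_minimal()
}
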