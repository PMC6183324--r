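# Multi-respondent questionnaire handling: long-format CSV in,
# validated per-respondent comparison matrices, consistency screening,
# and group-level aggregation (geometric mean of judgments by default).

#' Read questionnaire responses from long-format CSV
#'
#' Expected columns: `respondent_id`, `group`, `context_id`,
#' `row_node`, `col_node`, `judgment`. One row per elicited judgment;
#' judgments may be decimals or fraction strings (`"1/5"`). For each
#' (respondent, context) the upper-triangle judgments are assembled
#' into a full reciprocal matrix (diagonal and reciprocal cells
#' auto-completed). Supplying both orientations of a cell is accepted
#' only when they are numerically reciprocal; contradictions and
#' duplicate cells are errors, as are off-scale judgments and unknown
#' contexts or nodes. A respondent may omit whole contexts (they are
#' simply absent and dropped from aggregation for those contexts), but
#' a partially supplied matrix is an error.
#'
#' @param csv_source Path to a CSV file, or a data frame already in the
#'   long format.
#' @param network The `anp_network` the responses refer to.
#' @return A tibble with one row per (respondent, context):
#'   `respondent_id`, `group`, `context_id`, `matrix` (list-column of
#'   reciprocal matrices with node dimnames).
#' @export
read_responses <- function(csv_source, network) {
  stopifnot(inherits(network, "anp_network"))
  raw <- if (is.character(csv_source)) {
    if (!file.exists(csv_source)) {
      abort(sprintf("Responses file not found: %s", csv_source))
    }
    readr::read_csv(csv_source,
      show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
  } else {
    dplyr::mutate(
      as_tibble(csv_source),
      dplyr::across(dplyr::everything(), as.character)
    )
  }
  needed <- c(
    "respondent_id", "group", "context_id",
    "row_node", "col_node", "judgment"
  )
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Responses are missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) abort("Responses contain no judgments.")
  ctx <- comparison_contexts(network)
  bad_ctx <- setdiff(unique(raw$context_id), ctx$context_id)
  if (length(bad_ctx) > 0) {
    abort(sprintf(
      "Unknown comparison context(s): %s",
      paste(bad_ctx, collapse = ", ")
    ))
  }
  raw$judgment_num <- parse_judgment(raw$judgment)
  off <- which(!is_saaty_value(raw$judgment_num))
  if (length(off) > 0) {
    i <- off[1]
    abort(sprintf(
      "Off-scale judgment '%s' from respondent '%s' at (%s, %s) in context '%s'.",
      raw$judgment[i], raw$respondent_id[i], raw$row_node[i],
      raw$col_node[i], raw$context_id[i]
    ))
  }
  members_of <- setNames(ctx$members, ctx$context_id)
  raw |>
    dplyr::group_by(.data$respondent_id, .data$group, .data$context_id) |>
    dplyr::group_modify(function(g, key) {
      members <- members_of[[key$context_id]]
      tibble(matrix = list(build_response_matrix(g, key, members)))
    }) |>
    dplyr::ungroup()
}

# Parse judgments given as decimals or fraction strings like "1/5".
parse_judgment <- function(x) {
  vapply(x, function(v) {
    v <- trimws(v)
    if (grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", v)) {
      parts <- as.numeric(strsplit(v, "/")[[1]])
      return(parts[1] / parts[2])
    }
    suppressWarnings(as.numeric(v))
  }, numeric(1), USE.NAMES = FALSE)
}

build_response_matrix <- function(g, key, members) {
  n <- length(members)
  bad_node <- setdiff(unique(c(g$row_node, g$col_node)), members)
  if (length(bad_node) > 0) {
    abort(sprintf(
      "Respondent '%s', context '%s': node(s) not in context: %s",
      key$respondent_id, key$context_id, paste(bad_node, collapse = ", ")
    ))
  }
  A <- diag(1, n)
  dimnames(A) <- list(members, members)
  seen <- matrix(FALSE, n, n, dimnames = dimnames(A))
  for (i in seq_len(nrow(g))) {
    r <- g$row_node[i]
    cc <- g$col_node[i]
    v <- g$judgment_num[i]
    if (r == cc) {
      if (abs(v - 1) > 1e-9) {
        abort(sprintf(
          "Respondent '%s', context '%s': diagonal cell (%s, %s) must be 1.",
          key$respondent_id, key$context_id, r, cc
        ))
      }
      next
    }
    if (seen[r, cc]) {
      abort(sprintf(
        "Respondent '%s', context '%s': duplicate cell (%s, %s).",
        key$respondent_id, key$context_id, r, cc
      ))
    }
    if (seen[cc, r] && abs(A[cc, r] * v - 1) > 1e-9) {
      abort(sprintf(
        "Respondent '%s', context '%s': contradictory judgments for (%s, %s): %s vs %s.",
        key$respondent_id, key$context_id, r, cc,
        signif(v, 4), signif(A[cc, r], 4)
      ))
    }
    A[r, cc] <- v
    A[cc, r] <- 1 / v
    seen[r, cc] <- TRUE
  }
  filled <- seen | t(seen)
  if (n >= 2) {
    missing_cells <- which(upper.tri(A) & !filled, arr.ind = TRUE)
    if (nrow(missing_cells) > 0) {
      abort(sprintf(
        "Respondent '%s', context '%s': missing judgment for (%s, %s).",
        key$respondent_id, key$context_id,
        members[missing_cells[1, 1]], members[missing_cells[1, 2]]
      ))
    }
  }
  validate_comparison_matrix(A)
  A
}

#' Write responses to the long-format questionnaire CSV
#'
#' Emits the strict upper triangle of every matrix (one row per
#' judgment); [read_responses()] on the result reproduces the input.
#'
#' @param responses Responses tibble (`respondent_id`, `group`,
#'   `context_id`, `matrix`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  long <- responses |>
    dplyr::mutate(rows = purrr::map(.data$matrix, function(A) {
      idx <- which(upper.tri(A), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      tibble(
        row_node = rownames(A)[idx[, 1]],
        col_node = colnames(A)[idx[, 2]],
        judgment = A[idx]
      )
    })) |>
    dplyr::select(-"matrix") |>
    tidyr::unnest("rows")
  readr::write_csv(long, path)
  invisible(path)
}

#' Screen respondents by consistency ratio
#'
#' Computes the consistency report of every supplied matrix and
#' excludes a respondent entirely when any of their matrices has
#' `CR >= threshold` (whole-respondent policy; set
#' `per_matrix = TRUE` to drop only the failing matrices instead).
#'
#' @param responses Responses tibble from [read_responses()] or
#'   [generate_cohort()].
#' @param threshold CR exclusion threshold, default `0.1`
#'   (`Inf` keeps everyone).
#' @param per_matrix Drop failing matrices instead of whole
#'   respondents? Default `FALSE`.
#' @return A list with `kept` and `excluded` response tibbles and
#'   `report`, a per-matrix tibble (`respondent_id`, `group`,
#'   `context_id`, `n`, `lambda_max`, `ci`, `cr`, `acceptable`).
#' @export
screen_by_cr <- function(responses, threshold = 0.1, per_matrix = FALSE) {
  report <- responses |>
    dplyr::mutate(cons = purrr::map(.data$matrix, function(A) {
      consistency(A, threshold = threshold)[, c("n", "lambda_max", "ci", "cr", "acceptable")]
    })) |>
    dplyr::select(-"matrix") |>
    tidyr::unnest("cons")
  if (per_matrix) {
    ok <- report$cr < threshold
    return(list(
      kept = responses[ok, ], excluded = responses[!ok, ], report = report
    ))
  }
  bad_resp <- unique(report$respondent_id[report$cr >= threshold])
  keep <- !(responses$respondent_id %in% bad_resp)
  list(
    kept = responses[keep, ],
    excluded = responses[!keep, ],
    report = report
  )
}

#' Aggregate respondent judgments per group and context
#'
#' Entrywise geometric mean of the upper-triangle judgments across the
#' respondents supplying each context, with reciprocals refilled — so
#' the aggregate is exactly reciprocal, though its entries may fall off
#' the 17-value grid (they stay within `[1/9, 9]`, as the geometric
#' mean of grid values).
#'
#' @param responses Responses tibble (typically `$kept` from
#'   [screen_by_cr()]).
#' @param by_group Aggregate within groups (default) or pool everyone
#'   into a single `"all"` group?
#' @return A tibble with columns `group`, `context_id`, `matrix`
#'   (aggregated), `n_respondents`.
#' @export
aggregate_judgments <- function(responses, by_group = TRUE) {
  if (nrow(responses) == 0) abort("No responses to aggregate.")
  if (!by_group) responses$group <- "all"
  responses |>
    dplyr::group_by(.data$group, .data$context_id) |>
    dplyr::summarise(
      matrix = list(geometric_mean_matrices(.data$matrix)),
      n_respondents = dplyr::n(),
      .groups = "drop"
    )
}

geometric_mean_matrices <- function(mats) {
  ref <- mats[[1]]
  members <- rownames(ref)
  logs <- lapply(mats, function(A) log(A[members, members]))
  L <- Reduce(`+`, logs) / length(logs)
  A <- diag(1, length(members))
  dimnames(A) <- list(members, members)
  up <- which(upper.tri(A), arr.ind = TRUE)
  A[up] <- exp(L[up])
  A[up[, c(2, 1), drop = FALSE]] <- 1 / A[up]
  A
}

#' Local priority vectors of aggregated (or individual) matrices
#'
#' Maps every matrix in a responses- or aggregate-shaped tibble to its
#' eigenvector priorities.
#'
#' @param aggregated Tibble with columns `context_id` and `matrix`
#'   (plus any grouping columns, which are carried through).
#' @return Long tibble: grouping columns, `context_id`, `node`,
#'   `weight`.
#' @export
context_priorities <- function(aggregated) {
  aggregated |>
    dplyr::mutate(pv = purrr::map(.data$matrix, function(A) {
      w <- priority_vector(A)
      tibble(node = names(w), weight = unname(w))
    })) |>
    dplyr::select(-"matrix", -dplyr::any_of("n_respondents")) |>
    tidyr::unnest("pv")
}
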