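# Synthetic respondents: group-specific ground-truth priorities,
# consistent ratio matrices, log-normal judgment noise snapped to the
# Saaty grid, and study-design cohort counts. Every pipeline stage is
# testable against a known truth without any external data.

#' Design a synthetic cohort
#'
#' Defaults reproduce the study design the generator emulates: three
#' hospital worker groups (8-hour rotating nurses, 12/24 support
#' staff, 24/48 security staff) of 100 respondents each. Each group
#' carries its own RNG seed, derived from `seed`, so regenerating one
#' group never disturbs the others.
#'
#' @param groups Character vector of group labels.
#' @param sizes Respondents per group (recycled), all `>= 1`.
#' @param seed Master integer seed.
#' @return A tibble with columns `group`, `size`, `group_seed`.
#' @export
cohort_design <- function(groups = published_groups(), sizes = 100,
                          seed = 1) {
  stopifnot(length(groups) >= 1, !anyDuplicated(groups), all(sizes >= 1))
  sizes <- rep_len(as.integer(sizes), length(groups))
  tibble(
    group = groups, size = sizes,
    group_seed = (as.integer(seed) + 99991L * seq_along(groups)) %%
      .Machine$integer.max
  )
}

#' Fixture-seeded ground-truth priorities for a group
#'
#' Builds a true priority vector for every comparison context of the
#' network from the published group weights, so synthetic cohorts
#' center on the reported profiles: criterion weights for the
#' goal context, local sub-criterion weights under each criterion,
#' the group's alternative weights under every sub-criterion, and — for
#' the criterion inner-dependence contexts — the criterion weights
#' restricted to the compared criteria and renormalized. Published
#' blocks are renormalized to sum exactly to 1. A context member with
#' no printed weight (the support group's evening shift) receives
#' one ninth of the block's largest weight — the smallest ratio the
#' judgment scale can represent — before renormalization.
#'
#' @param network An `anp_network` (the bundled shift-work network or a
#'   sub-network of it).
#' @param group One of [published_groups()].
#' @return A tibble with columns `context_id`, `node`, `weight`.
#' @export
ground_truth_from_published <- function(network, group) {
  pub <- published_weights(group, warn = FALSE)
  crit_w <- setNames(pub$criteria$weight, pub$criteria$node)
  sub_w <- setNames(pub$subcriteria$weight, pub$subcriteria$node)
  alt_w <- setNames(pub$alternatives$weight, pub$alternatives$node)
  ctx <- dplyr::filter(comparison_contexts(network), .data$needs_matrix)
  purrr::map_dfr(seq_len(nrow(ctx)), function(i) {
    members <- ctx$members[[i]]
    pool <- switch(ctx$source_cluster[i],
      criteria = crit_w,
      subcriteria = sub_w,
      alternatives = alt_w,
      abort(sprintf(
        "No published profile for cluster '%s'.", ctx$source_cluster[i]
      ))
    )
    w <- pool[members]
    names(w) <- members
    if (all(is.na(w))) {
      abort(sprintf(
        "No published weights cover context '%s'.", ctx$context_id[i]
      ))
    }
    w[is.na(w)] <- max(w, na.rm = TRUE) / 9
    w <- w / sum(w)
    tibble(context_id = ctx$context_id[i], node = members, weight = unname(w))
  })
}

#' Perfectly consistent matrix from a priority vector
#'
#' `a_ij = w_i / w_j`, clipped into the representable `[1/9, 9]` range.
#' Before clipping the matrix is exactly consistent
#' (`a_ij * a_jk = a_ik`), so its eigenvector recovers `w`.
#'
#' @param w Named nonnegative weight vector (need not be normalized;
#'   zero weights are not representable as ratios and are rejected).
#' @return Reciprocal matrix with dimnames `names(w)`; attribute
#'   `n_clipped` counts the off-diagonal entries clipped at the scale
#'   bounds.
#' @export
consistent_matrix_from <- function(w) {
  stopifnot(is.numeric(w), length(w) >= 1, all(is.finite(w)), all(w > 0))
  A <- outer(w, w, "/")
  clipped <- sum(A < 1 / 9 | A > 9) # symmetric count
  A <- clip_saaty(A)
  # clipping can break exact reciprocity when only one side is clipped;
  # restore it from the upper triangle
  A[lower.tri(A)] <- t(1 / A)[lower.tri(A)]
  diag(A) <- 1
  if (!is.null(names(w))) dimnames(A) <- list(names(w), names(w))
  structure(A, n_clipped = clipped)
}

#' Perturb a comparison matrix with log-normal judgment noise
#'
#' Multiplies each upper-triangle entry by `exp(eps)` with
#' `eps ~ Normal(0, sigma^2)` i.i.d., snaps the result to the nearest
#' admissible judgment value (see [snap_saaty()]), and refills the
#' reciprocals. `sigma = 0` is a pure snap of the input.
#'
#' @param A Reciprocal comparison matrix.
#' @param sigma Log-scale noise standard deviation, `>= 0`.
#' @param seed Optional integer seed for a self-contained reproducible
#'   draw; when `NULL` the current RNG stream is used.
#' @return Perturbed reciprocal matrix on the 17-value grid.
#' @export
perturb_matrix <- function(A, sigma, seed = NULL) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), sigma >= 0)
  draw <- function() {
    n <- nrow(A)
    out <- A
    up <- which(upper.tri(A), arr.ind = TRUE)
    if (nrow(up) > 0) {
      eps <- rnorm(nrow(up), mean = 0, sd = sigma)
      vals <- snap_saaty(clip_saaty(A[up] * exp(eps)))
      out[up] <- vals
      out[up[, c(2, 1), drop = FALSE]] <- 1 / vals
    }
    diag(out) <- 1
    out
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Generate a synthetic respondent cohort
#'
#' One record per planned respondent: for every comparison context the
#' respondent's judgment matrix is a noise-perturbed, grid-snapped
#' version of the perfectly consistent matrix implied by the group's
#' ground-truth priorities. Deterministic per design (each group has
#' its own seed). Demographic metadata (marital status, shift-selection
#' mode, satisfaction, age and experience bands) is drawn from the
#' study's reported margins as independent categorical draws and
#' attached as the `demographics` attribute; it plays no role in the
#' weighting mathematics.
#'
#' @param design Cohort design from [cohort_design()].
#' @param ground_truth Either a tibble (`context_id`, `node`, `weight`)
#'   used for every group, or a named list of such tibbles keyed by
#'   group label. Defaults to [ground_truth_from_published()] when the
#'   design's groups are the published ones (requires `network`).
#' @param sigma Log-scale judgment noise SD, default `0.15`.
#' @param network Network used to derive default ground truth and to
#'   order contexts.
#' @param contexts Optional character vector restricting generation to
#'   a subset of context ids (e.g. only the goal context for a
#'   criterion-level study).
#' @return A responses tibble (`respondent_id`, `group`, `context_id`,
#'   `matrix`) compatible with [screen_by_cr()] and
#'   [aggregate_judgments()], with attributes `demographics` (tibble)
#'   and `clipping` (per-context counts of truth ratios clipped at the
#'   scale bounds; a fully clipped context triggers a warning).
#' @export
generate_cohort <- function(design, ground_truth = NULL, sigma = 0.15,
                            network = shift_work_network(),
                            contexts = NULL) {
  stopifnot(is.data.frame(design), all(c("group", "size", "group_seed") %in% names(design)))
  if (is.null(ground_truth)) {
    ground_truth <- purrr::map(
      setNames(design$group, design$group),
      function(g) ground_truth_from_published(network, g)
    )
  }
  if (is.data.frame(ground_truth)) {
    ground_truth <- purrr::map(
      setNames(design$group, design$group), function(g) ground_truth
    )
  }
  out <- vector("list", nrow(design))
  demo <- vector("list", nrow(design))
  clip_notes <- list()
  for (gi in seq_len(nrow(design))) {
    g <- design$group[gi]
    truth <- ground_truth[[g]]
    if (is.null(truth)) abort(sprintf("No ground truth for group '%s'.", g))
    truth_split <- split(truth, truth$context_id)
    if (!is.null(contexts)) {
      missing_ctx <- setdiff(contexts, names(truth_split))
      if (length(missing_ctx) > 0) {
        abort(sprintf(
          "Requested context(s) not covered by ground truth: %s",
          paste(missing_ctx, collapse = ", ")
        ))
      }
      truth_split <- truth_split[intersect(names(truth_split), contexts)]
    }
    base_mats <- purrr::map(truth_split, function(tt) {
      consistent_matrix_from(setNames(tt$weight, tt$node))
    })
    fully_clipped <- names(base_mats)[vapply(base_mats, function(A) {
      n <- nrow(A)
      n > 1 && attr(A, "n_clipped") >= n * (n - 1)
    }, logical(1))]
    if (length(fully_clipped) > 0) {
      warn(sprintf(
        "Group '%s': all ratios clipped at the scale bounds in context(s): %s",
        g, paste(fully_clipped, collapse = ", ")
      ))
    }
    clip_notes[[g]] <- tibble(
      group = g, context_id = names(base_mats),
      n_clipped = vapply(base_mats, function(A) attr(A, "n_clipped"), numeric(1))
    )
    records <- withr_seed(design$group_seed[gi], {
      purrr::map_dfr(seq_len(design$size[gi]), function(r) {
        rid <- sprintf("%s_%03d", g, r)
        mats <- purrr::map(base_mats, perturb_matrix, sigma = sigma)
        tibble(
          respondent_id = rid, group = g,
          context_id = names(mats), matrix = unname(mats)
        )
      })
    })
    demo[[gi]] <- withr_seed(design$group_seed[gi] + 1L, {
      draw_demographics(unique(records$respondent_id), g)
    })
    out[[gi]] <- records
  }
  structure(
    dplyr::bind_rows(out),
    demographics = dplyr::bind_rows(demo),
    clipping = dplyr::bind_rows(clip_notes)
  )
}

# Demographic margins reported for the study sample (all male; 72%
# married; 82% obligatory shift selection; 62% satisfied; experience
# and age band shares), drawn independently per respondent.
draw_demographics <- function(respondent_ids, group) {
  n <- length(respondent_ids)
  tibble(
    respondent_id = respondent_ids,
    group = group,
    sex = "male",
    marital_status = sample(c("married", "single"), n,
      replace = TRUE, prob = c(0.72, 0.28)
    ),
    experience_band = sample(
      c("<5", "5-10", "11-20", "21-30"), n,
      replace = TRUE, prob = c(0.316, 0.344, 0.224, 0.116)
    ),
    age_band = sample(c("24-30", "31-40", "41-50"), n,
      replace = TRUE, prob = c(0.434, 0.32, 0.246)
    ),
    shift_selection = sample(c("obligatory", "voluntary"), n,
      replace = TRUE, prob = c(0.82, 0.18)
    ),
    satisfied = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.62, 0.38))
  )
}

#' Compare recovered priorities against ground truth
#'
#' Joins estimated context priorities to the generating truth and
#' reports, per context, the maximum absolute weight error, whether the
#' recovered ranking matches the true ranking exactly, and Kendall's
#' rank correlation between the two weight vectors.
#'
#' @param ground_truth Tibble (`context_id`, `node`, `weight`).
#' @param estimated Tibble (`context_id`, `node`, `weight`), e.g. from
#'   [context_priorities()] for one group.
#' @return A list with `contexts` (per-context tibble: `context_id`,
#'   `n`, `max_abs_error`, `exact_rank`, `kendall_tau`) and `summary`
#'   (one row: `n_contexts`, `max_abs_error`, `share_exact_rank`,
#'   `mean_kendall_tau`).
#' @export
recovery_report <- function(ground_truth, estimated) {
  if (!setequal(unique(ground_truth$context_id), unique(estimated$context_id))) {
    abort("Ground truth and estimate cover different contexts.")
  }
  joined <- dplyr::inner_join(
    ground_truth, estimated,
    by = c("context_id", "node"), suffix = c("_true", "_est")
  )
  if (nrow(joined) != nrow(ground_truth)) {
    abort("Ground truth and estimate cover different nodes.")
  }
  contexts <- joined |>
    dplyr::group_by(.data$context_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      max_abs_error = max(abs(.data$weight_true - .data$weight_est)),
      exact_rank = identical(
        order(-.data$weight_true, .data$node),
        order(-.data$weight_est, .data$node)
      ),
      kendall_tau = if (dplyr::n() >= 2) {
        suppressWarnings(cor(.data$weight_true, .data$weight_est,
          method = "kendall"
        ))
      } else {
        1
      },
      .groups = "drop"
    )
  summary <- tibble(
    n_contexts = nrow(contexts),
    max_abs_error = max(contexts$max_abs_error),
    share_exact_rank = mean(contexts$exact_rank),
    mean_kendall_tau = mean(contexts$kendall_tau, na.rm = TRUE)
  )
  list(contexts = contexts, summary = summary)
}
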