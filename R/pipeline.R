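# End-to-end prioritization pipeline: judgments (observed or
# synthetic) -> consistency screening -> group aggregation -> local
# priorities -> supermatrix limit -> criterion / sub-criterion /
# alternative weights, desirability indices, and ranked report.

#' Run the full ANP prioritization pipeline
#'
#' Takes either observed questionnaire responses or a synthetic cohort
#' design (exactly one of the two), screens respondents by consistency
#' ratio, aggregates judgments per group, derives local eigenvector
#' priorities, assembles and limits the supermatrix, and reports per
#' group: criterion weights, local sub-criterion weights, alternative
#' weights (limit path), desirability indices (composite-score path),
#' the alternative ranking, and the consistency log.
#'
#' Criterion weights are the goal-context priorities; when the network
#' contains criterion inner-dependence contexts, they are adjusted by
#' one application of the dependency matrix (columns = the
#' inner-dependence priority vectors) and renormalized. Alternative
#' weights are the limit-matrix mass reaching the alternatives when
#' the process is seeded at the criteria with those criterion weights.
#'
#' @param network An `anp_network`; default [shift_work_network()].
#' @param responses Observed responses tibble from [read_responses()].
#' @param design Synthetic cohort design from [cohort_design()];
#'   mutually exclusive with `responses`.
#' @param ground_truth,sigma Passed to [generate_cohort()] when
#'   `design` is given.
#' @param aggregation `"judgments"` (geometric mean of matrices, the
#'   default) or `"priorities"` (arithmetic mean of individual
#'   eigenvectors).
#' @param cr_threshold Consistency-ratio exclusion threshold, default
#'   `0.1`.
#' @param cluster_weights Optional cluster weight tibble, see
#'   [weight_supermatrix()].
#' @param sinks Sink-column policy for [limit_supermatrix()].
#' @return An `anp_result` object; see [tidy.anp_result()],
#'   [glance.anp_result()], [autoplot.anp_result()],
#'   [compare_to_published()], [report_json()].
#' @export
#' @examples
#' design <- cohort_design(sizes = 5, seed = 42)
#' res <- anp_pipeline(design = design, sigma = 0.1)
#' glance(res)
anp_pipeline <- function(network = shift_work_network(),
                         responses = NULL, design = NULL,
                         ground_truth = NULL, sigma = 0.15,
                         aggregation = c("judgments", "priorities"),
                         cr_threshold = 0.1, cluster_weights = NULL,
                         sinks = c("selfloop", "zero")) {
  aggregation <- match.arg(aggregation)
  sinks <- match.arg(sinks)
  if (is.null(responses) == is.null(design)) {
    abort("Supply exactly one input source: `responses` or `design`.")
  }
  input <- if (is.null(design)) "responses" else "synthetic"
  if (!is.null(design)) {
    responses <- generate_cohort(design, ground_truth,
      sigma = sigma, network = network
    )
  }
  if (nrow(responses) == 0) {
    abort("survey stage: no responses supplied.")
  }
  screen <- screen_by_cr(responses, threshold = cr_threshold)
  if (nrow(screen$kept) == 0) {
    abort("screening stage: every respondent was excluded by CR.")
  }
  local_priors <- if (aggregation == "judgments") {
    context_priorities(aggregate_judgments(screen$kept))
  } else {
    context_priorities(screen$kept) |>
      dplyr::group_by(.data$group, .data$context_id, .data$node) |>
      dplyr::summarise(weight = mean(.data$weight), .groups = "drop") |>
      dplyr::group_by(.data$group, .data$context_id) |>
      dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
      dplyr::ungroup()
  }
  groups <- unique(local_priors$group)
  res_groups <- purrr::map(setNames(groups, groups), function(g) {
    prior_g <- dplyr::filter(local_priors, .data$group == g) |>
      dplyr::select("context_id", "node", "weight")
    resp_g <- dplyr::filter(responses, .data$group == g)
    kept_g <- dplyr::filter(screen$kept, .data$group == g)
    group_result(
      network, prior_g, cluster_weights, sinks,
      consistency_log = dplyr::filter(screen$report, .data$group == g),
      n_respondents = length(unique(resp_g$respondent_id)),
      n_kept = length(unique(kept_g$respondent_id))
    )
  })
  structure(
    list(
      network = network,
      groups = res_groups,
      settings = list(
        input = input, aggregation = aggregation,
        cr_threshold = cr_threshold, sinks = sinks,
        sigma = if (input == "synthetic") sigma else NA_real_
      )
    ),
    class = "anp_result"
  )
}

# Single-group computation from local context priorities.
group_result <- function(network, priorities, cluster_weights, sinks,
                         consistency_log, n_respondents, n_kept) {
  ctx <- comparison_contexts(network)
  goal_ctx <- dplyr::filter(ctx, .data$target == network$goal$id)
  if (nrow(goal_ctx) != 1) {
    abort("priorities stage: expected exactly one goal-targeted context.")
  }
  crit_ids <- goal_ctx$members[[1]]
  w_goal_tbl <- dplyr::filter(
    priorities, .data$context_id == goal_ctx$context_id
  )
  if (nrow(w_goal_tbl) == 0 && goal_ctx$n == 1) {
    w_goal_tbl <- tibble(node = crit_ids, weight = 1)
  }
  if (!setequal(w_goal_tbl$node, crit_ids)) {
    abort("priorities stage: goal-context priorities incomplete.")
  }
  w_goal <- setNames(w_goal_tbl$weight, w_goal_tbl$node)[crit_ids]

  # inner dependence among criteria: one application of the dependency
  # matrix, columns = the inner-dependence priority vectors
  crit_cluster <- network$nodes$cluster_id[match(crit_ids[1], network$nodes$id)]
  fb_ctx <- dplyr::filter(
    ctx,
    .data$target %in% crit_ids, .data$source_cluster == crit_cluster
  )
  w_crit <- w_goal
  if (nrow(fb_ctx) > 0) {
    C <- matrix(0, length(crit_ids), length(crit_ids),
      dimnames = list(crit_ids, crit_ids)
    )
    for (i in seq_len(nrow(fb_ctx))) {
      p <- dplyr::filter(priorities, .data$context_id == fb_ctx$context_id[i])
      if (nrow(p) == 0 && fb_ctx$n[i] == 1) {
        p <- tibble(node = fb_ctx$members[[i]], weight = 1)
      }
      C[p$node, fb_ctx$target[i]] <- p$weight
    }
    w_crit <- as.vector(C %*% w_goal)
    names(w_crit) <- crit_ids
    if (sum(w_crit) <= 0) {
      abort("supermatrix stage: dependency-adjusted criterion weights vanish.")
    }
    w_crit <- w_crit / sum(w_crit)
  }

  W <- assemble_unweighted(network, priorities)
  Wg <- weight_supermatrix(W, network, cluster_weights)
  L <- limit_supermatrix(Wg, sinks = sinks)
  seedvec <- setNames(rep(0, nrow(L)), rownames(L))
  seedvec[names(w_crit)] <- w_crit
  mass <- as.vector(L %*% seedvec)
  names(mass) <- rownames(L)
  alt_ids <- network$nodes$id[
    network$nodes$cluster_id %in%
      network$clusters$id[network$clusters$kind == "alternatives"]
  ]
  alt_mass <- mass[alt_ids]
  if (sum(alt_mass) <= 0) {
    abort("supermatrix stage: no limit mass reaches the alternatives.")
  }
  alt_weights <- alt_mass / sum(alt_mass)

  # local sub-criterion weights straight from their contexts
  sub_nodes <- dplyr::filter(network$nodes, !is.na(.data$parent))
  sub_local <- purrr::map_dfr(unique(sub_nodes$parent), function(cr) {
    kids <- sub_nodes$id[sub_nodes$parent == cr]
    cid <- paste0(cr, "__", sub_nodes$cluster_id[sub_nodes$parent == cr][1])
    p <- dplyr::filter(priorities, .data$context_id == cid)
    if (nrow(p) == 0 && length(kids) == 1) {
      p <- tibble(node = kids, weight = 1)
    }
    tibble(criterion = cr, node = p$node, weight = p$weight)
  })

  # pseudo-limit global profile: criteria mass, global sub mass,
  # limit-path alternative mass
  pseudo <- c(
    w_crit,
    setNames(
      w_crit[sub_local$criterion] * sub_local$weight,
      sub_local$node
    ),
    alt_weights
  )
  weights_tbl <- extract_priorities(pseudo, network)

  # desirability path: with one elicited judgment set per sub-criterion
  # context the dependency and independency sub-weights coincide
  impacts <- purrr::map_dfr(sub_nodes$id, function(sc) {
    cid <- paste0(sc, "__", network$nodes$cluster_id[
      match(alt_ids[1], network$nodes$id)
    ])
    p <- dplyr::filter(priorities, .data$context_id == cid)
    if (nrow(p) == 0 && length(alt_ids) == 1) {
      p <- tibble(node = alt_ids, weight = 1)
    }
    tibble(subcriterion = sc, alternative = p$node, impact = p$weight)
  })
  # no separate dependency elicitation for sub-criteria: the dependency
  # weight is trivial (1) and the stabilized independent weight is the
  # local priority, so on a pure hierarchy the desirability index
  # reduces exactly to the hierarchical composition
  desir <- desirability_index(
    p = setNames(unname(w_crit), names(w_crit)),
    sub = tibble(
      criterion = sub_local$criterion, subcriterion = sub_local$node,
      ad = 1, a1 = sub_local$weight
    ),
    s = impacts
  )

  alternatives <- rank_alternatives(alt_weights) |>
    dplyr::left_join(
      dplyr::rename(desir, d_node = "alternative"),
      by = c(node = "d_node")
    )
  list(
    criterion_weights = tibble(
      node = names(w_crit), weight = unname(w_crit),
      weight_goal = unname(w_goal[names(w_crit)])
    ),
    weights = weights_tbl,
    subcriteria_local = sub_local,
    alternatives = alternatives,
    desirability = desir,
    limit = L,
    consistency = consistency_log,
    n_respondents = n_respondents,
    n_kept = n_kept,
    n_excluded = n_respondents - n_kept
  )
}

#' @export
print.anp_result <- function(x, ...) {
  cat(sprintf(
    "<anp_result> %s | %d group(s), input: %s, aggregation: %s\n",
    x$network$name, length(x$groups),
    x$settings$input, x$settings$aggregation
  ))
  for (g in names(x$groups)) {
    top <- x$groups[[g]]$alternatives
    cat(sprintf(
      "  %s: %d/%d respondents kept; top alternative %s (%.3f)\n",
      g, x$groups[[g]]$n_kept, x$groups[[g]]$n_respondents,
      top$node[1], top$weight[1]
    ))
  }
  invisible(x)
}

#' Tidy an ANP result into a long weight table
#'
#' @param x An `anp_result`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `node`, `label`,
#'   `cluster_id`, `kind`, `parent`, `mass`, `weight` (criterion and
#'   alternative weights normalized within cluster; sub-criterion
#'   weights local to their parent).
#' @export
tidy.anp_result <- function(x, ...) {
  purrr::map_dfr(names(x$groups), function(g) {
    dplyr::mutate(x$groups[[g]]$weights, group = g, .before = 1)
  })
}

#' One-row-per-group summary of an ANP result
#'
#' @param x An `anp_result`.
#' @param ... Unused.
#' @return A tibble: `group`, `n_respondents`, `n_excluded`,
#'   `max_cr`, `top_criterion`, `top_criterion_weight`,
#'   `top_alternative`, `top_alternative_weight`.
#' @export
glance.anp_result <- function(x, ...) {
  purrr::map_dfr(names(x$groups), function(g) {
    gr <- x$groups[[g]]
    cw <- gr$criterion_weights[order(-gr$criterion_weights$weight), ]
    tibble(
      group = g,
      n_respondents = gr$n_respondents,
      n_excluded = gr$n_excluded,
      max_cr = max(gr$consistency$cr),
      top_criterion = cw$node[1],
      top_criterion_weight = cw$weight[1],
      top_alternative = gr$alternatives$node[1],
      top_alternative_weight = gr$alternatives$weight[1]
    )
  })
}

#' Compare a computed result against the published weights
#'
#' Per weight: computed value, published value, absolute difference;
#' plus a per-group, per-level rank-agreement flag (do the computed and
#' published weights order the nodes identically?).
#'
#' @param result An `anp_result` whose group labels appear among
#'   [published_groups()].
#' @param groups Groups to compare; default every group in `result`.
#' @return A list with `deltas` (tibble: `group`, `level`, `criterion`,
#'   `node`, `computed`, `published`, `abs_diff`) and `rank_agreement`
#'   (tibble: `group`, `level`, `agrees`).
#' @export
compare_to_published <- function(result, groups = names(result$groups)) {
  unknown <- setdiff(groups, published_groups())
  if (length(unknown) > 0) {
    abort(sprintf(
      "No published fixture for group(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  deltas <- purrr::map_dfr(groups, function(g) {
    pub <- published_weights(g, warn = FALSE)
    gr <- result$groups[[g]]
    if (is.null(gr)) {
      abort(sprintf("Result contains no group '%s'.", g))
    }
    computed <- dplyr::bind_rows(
      tibble(
        level = "criterion", criterion = NA_character_,
        node = gr$criterion_weights$node,
        computed = gr$criterion_weights$weight
      ),
      tibble(
        level = "subcriterion", criterion = gr$subcriteria_local$criterion,
        node = gr$subcriteria_local$node,
        computed = gr$subcriteria_local$weight
      ),
      tibble(
        level = "alternative", criterion = NA_character_,
        node = gr$alternatives$node, computed = gr$alternatives$weight
      )
    )
    published <- dplyr::bind_rows(
      tibble(
        level = "criterion", node = pub$criteria$node,
        published = pub$criteria$weight
      ),
      tibble(
        level = "subcriterion", node = pub$subcriteria$node,
        published = pub$subcriteria$weight
      ),
      tibble(
        level = "alternative", node = pub$alternatives$node,
        published = pub$alternatives$weight
      )
    )
    computed |>
      dplyr::left_join(published, by = c("level", "node")) |>
      dplyr::mutate(
        group = g, abs_diff = abs(.data$computed - .data$published),
        .before = 1
      )
  })
  rank_agreement <- deltas |>
    dplyr::filter(!is.na(.data$published)) |>
    dplyr::group_by(.data$group, .data$level) |>
    dplyr::summarise(
      agrees = identical(
        order(-.data$computed, .data$node),
        order(-.data$published, .data$node)
      ),
      .groups = "drop"
    )
  list(deltas = deltas, rank_agreement = rank_agreement)
}
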