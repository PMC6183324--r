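# Independent oracles and toy fixtures shared across the suite.

# Principal right eigenvector via dense eigen-decomposition (oracle for
# the power-iteration implementation).
eigen_oracle <- function(A) {
  e <- eigen(A)
  i <- which.max(Re(e$values))
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  list(w = w, lambda = Re(e$values[i]))
}

# Stationary distribution of a column-stochastic matrix via a linear
# solve of (M - I) x = 0 with sum(x) = 1 (oracle for the limit matrix).
stationary_oracle <- function(M) {
  n <- nrow(M)
  A <- rbind(M - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  as.vector(qr.solve(A, b))
}

# Brute-force desirability index: naive triple loop over criteria,
# sub-criteria, alternatives.
desirability_oracle <- function(p, sub, s) {
  alts <- sort(unique(s$alternative))
  d <- setNames(rep(0, length(alts)), alts)
  for (i in alts) {
    for (r in seq_len(nrow(sub))) {
      j <- sub$criterion[r]
      k <- sub$subcriterion[r]
      s_ikj <- s$impact[s$subcriterion == k & s$alternative == i]
      d[i] <- d[i] + p[[j]] * sub$ad[r] * sub$a1[r] * s_ikj
    }
  }
  d
}

# Random reciprocal comparison matrix with on-grid judgments.
random_reciprocal <- function(n) {
  matrix_from_judgments(
    sample(saaty_values(), n * (n - 1) / 2, replace = TRUE), n
  )
}

# Minimal 1-criterion, 2-alternative hierarchy.
toy_min_network <- function() {
  anp_network(
    clusters = tibble::tibble(
      id = c("criteria", "alternatives"),
      label = c("Criteria", "Alternatives"),
      kind = c("criteria", "alternatives")
    ),
    nodes = tibble::tibble(
      id = c("c1", "a1", "a2"),
      label = c("Criterion 1", "Alt 1", "Alt 2"),
      cluster_id = c("criteria", "alternatives", "alternatives")
    ),
    edges = tibble::tibble(
      source = c("c1", "a1", "a2"),
      target = c("goal", "c1", "c1")
    ),
    name = "toy_min"
  )
}

# Feedback-free toy: 2 criteria x 2 sub-criteria each x 3 alternatives,
# every pairwise ratio of the default truth lies on the judgment grid.
toy_hierarchy_network <- function() {
  subs <- tibble::tibble(
    id = c("s11", "s12", "s21", "s22"),
    label = id, cluster_id = "subcriteria",
    parent = c("c1", "c1", "c2", "c2")
  )
  anp_network(
    clusters = tibble::tibble(
      id = c("criteria", "subcriteria", "alternatives"),
      label = id,
      kind = c("criteria", "subcriteria", "alternatives")
    ),
    nodes = dplyr::bind_rows(
      tibble::tibble(
        id = c("c1", "c2"), label = id,
        cluster_id = "criteria", parent = NA_character_
      ),
      subs,
      tibble::tibble(
        id = c("alt1", "alt2", "alt3"), label = id,
        cluster_id = "alternatives", parent = NA_character_
      )
    ),
    edges = dplyr::bind_rows(
      tibble::tibble(source = c("c1", "c2"), target = "goal"),
      tibble::tibble(source = subs$id, target = subs$parent),
      tidyr::expand_grid(
        source = c("alt1", "alt2", "alt3"),
        target = subs$id
      )
    ),
    name = "toy_hierarchy"
  )
}

# Grid-representable ground truth for toy_hierarchy_network(): every
# pairwise ratio is an admissible judgment value.
toy_hierarchy_truth <- function() {
  net <- toy_hierarchy_network()
  ctx <- comparison_contexts(net)
  w_for <- function(members) {
    w <- switch(as.character(length(members)),
      "2" = c(2, 1) / 3,
      "3" = c(4, 2, 1) / 7,
      stop("unexpected context size")
    )
    tibble::tibble(node = members, weight = w)
  }
  purrr::map_dfr(seq_len(nrow(ctx)), function(i) {
    dplyr::mutate(
      w_for(ctx$members[[i]]),
      context_id = ctx$context_id[i], .before = 1
    )
  })
}

# Random priorities for every context of a network (uniform Dirichlet
# flavoured: independent uniforms, normalized).
random_priorities <- function(network) {
  ctx <- comparison_contexts(network)
  purrr::map_dfr(seq_len(nrow(ctx)), function(i) {
    members <- ctx$members[[i]]
    w <- stats::runif(length(members), 0.05, 1)
    tibble::tibble(
      context_id = ctx$context_id[i],
      node = members, weight = w / sum(w)
    )
  })
}

# Closed-form AHP composition of alternative weights on a pure
# hierarchy: sum_j sum_k w_j * w_{k|j} * s_{i|kj}.
ahp_composition <- function(network, priorities) {
  ctx <- comparison_contexts(network)
  goal_id <- ctx$context_id[ctx$target == network$goal$id]
  w_goal <- dplyr::filter(priorities, context_id == goal_id)
  alt_ids <- network$nodes$id[
    network$nodes$cluster_id %in%
      network$clusters$id[network$clusters$kind == "alternatives"]
  ]
  out <- setNames(rep(0, length(alt_ids)), alt_ids)
  for (j in seq_len(nrow(w_goal))) {
    cr <- w_goal$node[j]
    sub_ctx <- ctx[ctx$target == cr, ]
    for (sc in seq_len(nrow(sub_ctx))) {
      subs <- dplyr::filter(priorities, context_id == sub_ctx$context_id[sc])
      if (nrow(subs) == 0) subs <- tibble::tibble(node = sub_ctx$members[[sc]], weight = 1)
      for (k in seq_len(nrow(subs))) {
        alt_ctx_id <- ctx$context_id[ctx$target == subs$node[k]]
        alts <- dplyr::filter(priorities, context_id == alt_ctx_id)
        out[alts$node] <- out[alts$node] +
          w_goal$weight[j] * subs$weight[k] * alts$weight
      }
    }
  }
  out / sum(out)
}

# Build a responses tibble directly from matrices (bypassing CSV).
responses_from_matrices <- function(respondent_id, group, mats) {
  tibble::tibble(
    respondent_id = respondent_id, group = group,
    context_id = names(mats), matrix = unname(mats)
  )
}
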