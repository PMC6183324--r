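# Supermatrix assembly and limit priorities.
#
# The supermatrix is a square matrix over all network nodes (the goal
# is a virtual comparison target, not a node). Entry (source, target)
# holds the local priority of `source` in the comparison context whose
# target is `target`; zero where no dependency exists. Cluster weights
# make each nonzero column a convex combination of its per-cluster
# priority vectors, hence column-stochastic, and the matrix-power limit
# distributes influence through the network.

node_ids <- function(network) network$nodes$id

#' Assemble the unweighted supermatrix
#'
#' Places every context's local priority vector into the column of the
#' context target. Goal-targeted contexts have no column here; their
#' priorities seed the limit instead (see [extract_priorities()]).
#' Single-member contexts receive their forced priority 1 even when
#' absent from `priorities`.
#'
#' @param network An `anp_network`.
#' @param priorities Tibble with columns `context_id`, `node`, `weight`
#'   holding the local priority vector of every comparison context (as
#'   produced by [context_priorities()]).
#' @return Square numeric matrix (nodes x nodes) with `stage`
#'   attribute `"unweighted"`; columns with no incoming dependency are
#'   all-zero and listed in the `zero_columns` attribute.
#' @export
assemble_unweighted <- function(network, priorities) {
  stopifnot(inherits(network, "anp_network"))
  ctx <- comparison_contexts(network)
  ids <- node_ids(network)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ctx_node <- dplyr::filter(ctx, .data$target != network$goal$id)
  for (i in seq_len(nrow(ctx_node))) {
    cid <- ctx_node$context_id[i]
    members <- ctx_node$members[[i]]
    if (!ctx_node$needs_matrix[i]) {
      W[members, ctx_node$target[i]] <- 1
      next
    }
    p <- dplyr::filter(priorities, .data$context_id == cid)
    if (nrow(p) == 0) {
      abort(sprintf("No priority vector supplied for context '%s'.", cid))
    }
    if (!setequal(p$node, members)) {
      abort(sprintf(
        "Priority vector for context '%s' does not cover its members.", cid
      ))
    }
    W[p$node, ctx_node$target[i]] <- p$weight
  }
  zero_cols <- ids[colSums(W) == 0]
  structure(W, stage = "unweighted", zero_columns = zero_cols)
}

#' Apply cluster weights to obtain the weighted supermatrix
#'
#' Each column of the unweighted supermatrix stacks one priority vector
#' per source cluster (each summing to 1). The blocks are scaled by the
#' cluster weights — normalized over the source clusters actually
#' present in that column — so every nonzero column sums to exactly 1.
#'
#' @param W Unweighted supermatrix from [assemble_unweighted()].
#' @param network The `anp_network` it was built from.
#' @param cluster_weights `NULL` for equal weights over the source
#'   clusters feeding each column (the reproducible default, used when
#'   no cluster-level judgments exist), or a tibble with columns
#'   `source_cluster`, `target_cluster`, `weight` (nonnegative; they
#'   are renormalized per column over the clusters present).
#' @return Column-stochastic matrix with `stage = "weighted"`.
#' @export
weight_supermatrix <- function(W, network, cluster_weights = NULL) {
  stopifnot(inherits(network, "anp_network"))
  nodes <- network$nodes
  ids <- node_ids(network)
  stopifnot(identical(rownames(W), ids), identical(colnames(W), ids))
  cluster_of <- setNames(nodes$cluster_id, nodes$id)
  out <- W
  for (j in ids) {
    col <- W[, j]
    present <- unique(cluster_of[names(col)[col > 0]])
    if (length(present) == 0) next
    cw <- vapply(present, function(sc) {
      if (is.null(cluster_weights)) {
        return(1)
      }
      hit <- dplyr::filter(
        cluster_weights,
        .data$source_cluster == sc, .data$target_cluster == cluster_of[[j]]
      )
      if (nrow(hit) == 0) 1 else hit$weight[1]
    }, numeric(1))
    if (any(cw < 0) || sum(cw) <= 0) {
      abort(sprintf("Cluster weights for column '%s' are not usable.", j))
    }
    cw <- cw / sum(cw)
    for (k in seq_along(present)) {
      rows <- ids[cluster_of[ids] == present[k] & col[ids] > 0]
      block_sum <- sum(col[rows])
      out[rows, j] <- col[rows] / block_sum * cw[k]
    }
  }
  sums <- colSums(out)
  bad <- ids[sums > 0 & abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    abort(sprintf(
      "Internal error: weighted column(s) not stochastic: %s",
      paste(bad, collapse = ", ")
    ))
  }
  structure(out,
    stage = "weighted",
    zero_columns = ids[sums == 0]
  )
}

#' Raise the weighted supermatrix to its limit
#'
#' Computes the limit of the matrix powers by repeated squaring (the
#' classical prescription of raising to large odd powers 2k+1 converges
#' to the same limit for primitive matrices). If the powers settle on a
#' matrix that is not invariant under one more multiplication, the
#' chain is cyclic and the Cesaro average over one detected period is
#' returned instead. All-zero (sink) columns are, by default, given a
#' self-loop of weight 1 first so the matrix is genuinely
#' column-stochastic; `sinks = "zero"` leaves them untouched.
#'
#' @param W Column-stochastic weighted supermatrix.
#' @param tol Entrywise convergence tolerance, default `1e-10`.
#' @param power_cap Maximum number of squarings, default `60` (powers
#'   up to about `2^60`).
#' @param sinks Sink-column policy: `"selfloop"` (default) or `"zero"`.
#' @return Limit matrix with `stage = "limit"` and attributes
#'   `squarings`, `cesaro_period` (`NA` if acyclic) and
#'   `columns_equal` (`TRUE` when all nonzero columns agree to 1e-8,
#'   i.e. the chain mixes to a single stationary column).
#' @export
limit_supermatrix <- function(W, tol = 1e-10, power_cap = 60,
                              sinks = c("selfloop", "zero")) {
  sinks <- match.arg(sinks)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  n <- nrow(W)
  zero_cols <- which(colSums(W) == 0)
  if (length(zero_cols) > 0 && sinks == "selfloop") {
    W[cbind(zero_cols, zero_cols)] <- 1
  }
  sums <- colSums(W)
  if (any(sums > 0 & abs(sums - 1) > 1e-9)) {
    abort("limit_supermatrix() needs a column-stochastic matrix.")
  }
  M <- W
  converged <- FALSE
  squarings <- 0
  for (i in seq_len(power_cap)) {
    M2 <- M %*% M
    squarings <- i
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) {
    abort(sprintf(
      "Supermatrix powers did not settle within %d squarings (residual %.3e).",
      power_cap, max(abs(M2 - M))
    ))
  }
  period <- NA_integer_
  if (max(abs(W %*% M - M)) >= 1e-8) {
    # powers of 2 settled on a cycle; find its period and average it out
    found <- FALSE
    P <- M
    for (d in seq_len(2 * n + 2)) {
      P <- W %*% P
      if (max(abs(P - M)) < 1e-8) {
        period <- d
        found <- TRUE
        break
      }
    }
    if (!found) {
      abort("Supermatrix powers neither converge nor cycle detectably.")
    }
    acc <- M
    P <- M
    for (d in seq_len(period - 1)) {
      P <- W %*% P
      acc <- acc + P
    }
    M <- acc / period
  }
  nz <- which(colSums(M) > 1e-12)
  columns_equal <- length(nz) <= 1 ||
    max(apply(M[, nz, drop = FALSE], 1, function(r) diff(range(r)))) < 1e-8
  structure(M,
    stage = "limit", squarings = squarings,
    cesaro_period = period, columns_equal = columns_equal
  )
}

#' Extract per-cluster global priorities from a limit matrix
#'
#' Reduces the limit matrix to one mass vector over nodes and
#' renormalizes it per cluster: criterion and alternative weights sum
#' to 1 within their cluster, and sub-criterion weights are reported
#' local to their parent criterion (each parent's sub-weights summing
#' to 1, the layout of the published tables) unless
#' `subcriteria = "global"`.
#'
#' With `seed` given (a named vector over nodes, e.g. the goal-context
#' criterion weights placed in the criteria slots), the mass vector is
#' `limit %*% seed` — the influence reaching each node when the process
#' starts from the goal. Without a seed, the mass vector is the mean of
#' the nonzero limit columns (the stationary column when the chain
#' mixes). `limit` may also be a plain named mass vector, e.g. a
#' published global-weight profile used as a pseudo-limit.
#'
#' @param limit Limit matrix from [limit_supermatrix()], or a named
#'   nonnegative vector over the network nodes.
#' @param network The `anp_network`.
#' @param seed Optional named nonnegative seed vector over nodes.
#' @param subcriteria `"local"` (default) or `"global"` sub-criterion
#'   normalization.
#' @return A tibble with columns `node`, `label`, `cluster_id`, `kind`,
#'   `parent`, `mass` (raw), and `weight` (normalized as above). Errors
#'   if any cluster carries zero total mass.
#' @export
extract_priorities <- function(limit, network, seed = NULL,
                               subcriteria = c("local", "global")) {
  subcriteria <- match.arg(subcriteria)
  stopifnot(inherits(network, "anp_network"))
  nodes <- network$nodes
  ids <- node_ids(network)
  if (is.matrix(limit)) {
    stopifnot(identical(rownames(limit), ids))
    if (!is.null(seed)) {
      s <- rep(0, length(ids))
      names(s) <- ids
      s[names(seed)] <- seed
      m <- as.vector(limit %*% s)
    } else {
      nz <- which(colSums(limit) > 1e-12)
      m <- rowMeans(limit[, nz, drop = FALSE])
    }
    names(m) <- ids
  } else {
    stopifnot(is.numeric(limit), !is.null(names(limit)))
    m <- rep(0, length(ids))
    names(m) <- ids
    m[names(limit)] <- limit
  }
  if (any(m < -1e-12)) abort("Limit mass must be nonnegative.")
  m <- pmax(m, 0)
  out <- nodes |>
    dplyr::left_join(network$clusters[, c("id", "kind")],
      by = c("cluster_id" = "id")
    ) |>
    dplyr::mutate(mass = unname(m[.data$id])) |>
    dplyr::rename(node = "id")
  cluster_mass <- out |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(total = sum(.data$mass), .groups = "drop")
  dead <- cluster_mass$cluster_id[cluster_mass$total <= 0]
  if (length(dead) > 0) {
    abort(sprintf(
      "Cluster(s) with zero limit mass, no priorities extractable: %s",
      paste(dead, collapse = ", ")
    ))
  }
  out <- out |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(weight = .data$mass / sum(.data$mass)) |>
    dplyr::ungroup()
  if (subcriteria == "local") {
    is_sub <- out$kind == "subcriteria" & !is.na(out$parent)
    if (any(is_sub)) {
      out <- out |>
        dplyr::group_by(.data$cluster_id, .data$parent) |>
        dplyr::mutate(
          weight = dplyr::if_else(
            .data$kind == "subcriteria" & !is.na(.data$parent),
            .data$mass / sum(.data$mass), .data$weight
          )
        ) |>
        dplyr::ungroup()
    }
  }
  out[, c("node", "label", "cluster_id", "kind", "parent", "mass", "weight")]
}

#' Desirability index of the alternatives
#'
#' Composite score `D_i = sum_j sum_k P_j * AD_kj * A1_kj * S_ikj`
#' over criteria `j` and their sub-criteria `k`: `P_j` is the relative
#' importance of criterion `j`, `AD_kj` the sub-criterion's dependency
#' weight, `A1_kj` its stabilized independent weight (summing to 1
#' within each criterion), and `S_ikj` the relative impact of
#' alternative `i` on sub-criterion `k` (summing to 1 over
#' alternatives). The number of alternatives is data-driven.
#'
#' @param p Named numeric vector of criterion weights, or a tibble with
#'   columns `criterion`, `weight`.
#' @param sub Tibble with columns `criterion`, `subcriterion`, `ad`,
#'   `a1`.
#' @param s Tibble with columns `subcriterion`, `alternative`,
#'   `impact`.
#' @return A tibble with columns `alternative`, `d` (raw index), and
#'   `d_norm` (normalized to sum to 1).
#' @export
desirability_index <- function(p, sub, s) {
  if (is.data.frame(p)) p <- setNames(p$weight, p$criterion)
  stopifnot(
    is.numeric(p), !is.null(names(p)),
    all(c("criterion", "subcriterion", "ad", "a1") %in% names(sub)),
    all(c("subcriterion", "alternative", "impact") %in% names(s))
  )
  if (any(p < 0) || any(sub$ad < 0) || any(sub$a1 < 0) || any(s$impact < 0)) {
    abort("Desirability components must be nonnegative.")
  }
  miss_crit <- setdiff(sub$criterion, names(p))
  if (length(miss_crit) > 0) {
    abort(sprintf(
      "Criterion weight(s) missing for: %s",
      paste(miss_crit, collapse = ", ")
    ))
  }
  if (!setequal(unique(s$subcriterion), sub$subcriterion)) {
    abort("Impact table and sub-criterion table cover different sub-criteria.")
  }
  a1_sums <- tapply(sub$a1, sub$criterion, sum)
  if (any(abs(a1_sums - 1) > 1e-6)) {
    abort("Independent sub-criterion weights must sum to 1 within each criterion.")
  }
  s_sums <- tapply(s$impact, s$subcriterion, sum)
  if (any(abs(s_sums - 1) > 1e-6)) {
    abort("Alternative impacts must sum to 1 within each sub-criterion.")
  }
  d <- sub |>
    dplyr::mutate(term = p[.data$criterion] * .data$ad * .data$a1) |>
    dplyr::inner_join(s, by = "subcriterion",
      relationship = "one-to-many"
    ) |>
    dplyr::group_by(.data$alternative) |>
    dplyr::summarise(d = sum(.data$term * .data$impact), .groups = "drop")
  dplyr::mutate(d, d_norm = .data$d / sum(.data$d))
}

#' Rank alternatives by weight
#'
#' Descending order; exact ties are broken lexicographically by node id
#' and flagged.
#'
#' @param weights Named numeric vector, or a tibble with columns `node`
#'   and `weight`.
#' @param tie_tol Absolute tolerance for declaring a tie, default
#'   `1e-12`.
#' @return A tibble with columns `rank`, `node`, `weight`, `tied`.
#' @export
rank_alternatives <- function(weights, tie_tol = 1e-12) {
  if (is.data.frame(weights)) weights <- setNames(weights$weight, weights$node)
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  ord <- order(-weights, names(weights))
  w <- weights[ord]
  tied <- vapply(seq_along(w), function(i) {
    any(abs(w[-i] - w[i]) <= tie_tol)
  }, logical(1))
  tibble(
    rank = seq_along(w), node = names(w),
    weight = unname(w), tied = tied
  )
}
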