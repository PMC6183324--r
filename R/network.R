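# Decision-network representation: clusters of nodes (criteria,
# sub-criteria, alternatives) plus directed dependency edges. An edge
# (source -> target) means "source influences target": the sources
# sharing a target and a cluster are pairwise compared with respect to
# that target, yielding one comparison context. The goal is a virtual
# comparison target, not a supermatrix node.

#' Construct a decision network
#'
#' Low-level constructor; most users will call [load_network()] on a
#' YAML/JSON config or [shift_work_network()] for the bundled network.
#'
#' @param clusters Tibble/data frame with columns `id`, `label`, `kind`
#'   (`kind` one of `"criteria"`, `"subcriteria"`, `"alternatives"`).
#' @param nodes Tibble with columns `id`, `label`, `cluster_id`, and
#'   optionally `parent` (the parent criterion of a sub-criterion).
#' @param edges Tibble with columns `source`, `target` (node ids;
#'   `target` may be the goal id).
#' @param name Network name.
#' @param goal Two-element list `list(id, label)`; default id `"goal"`.
#' @param validate Run [validate_network()]? Default `TRUE`.
#' @return An `anp_network` object.
#' @export
anp_network <- function(clusters, nodes, edges, name = "network",
                        goal = list(id = "goal", label = "Goal"),
                        validate = TRUE) {
  clusters <- as_tibble(clusters)
  nodes <- as_tibble(nodes)
  if (!"parent" %in% names(nodes)) nodes$parent <- NA_character_
  edges <- as_tibble(edges)
  net <- structure(
    list(
      name = name, goal = goal,
      clusters = clusters[, c("id", "label", "kind")],
      nodes = nodes[, c("id", "label", "cluster_id", "parent")],
      edges = edges[, c("source", "target")]
    ),
    class = "anp_network"
  )
  if (validate) validate_network(net)
  net
}

#' @export
print.anp_network <- function(x, ...) {
  counts <- table(factor(x$nodes$cluster_id, levels = x$clusters$id))
  cat(sprintf(
    "<anp_network> %s: %d clusters, %d nodes, %d edges\n",
    x$name, nrow(x$clusters), nrow(x$nodes), nrow(x$edges)
  ))
  for (i in seq_len(nrow(x$clusters))) {
    cat(sprintf(
      "  %s (%s): %d nodes\n",
      x$clusters$id[i], x$clusters$kind[i], counts[[x$clusters$id[i]]]
    ))
  }
  invisible(x)
}

#' Validate a decision network
#'
#' Checks id uniqueness, cluster membership, edge resolution, that the
#' comparison contexts induced by the edges cover every node (no node is
#' left without a priority), and — when `require_alternatives` — that an
#' alternatives cluster with at least two members exists.
#'
#' @param network An `anp_network`.
#' @param require_alternatives Require >= 2 alternatives (needed for a
#'   ranking run)? Default `TRUE`.
#' @return `network`, invisibly.
#' @export
validate_network <- function(network, require_alternatives = TRUE) {
  stopifnot(inherits(network, "anp_network"))
  nodes <- network$nodes
  clusters <- network$clusters
  edges <- network$edges
  if (any(!nzchar(nodes$id)) || anyDuplicated(nodes$id) > 0) {
    abort("Node ids must be non-empty and unique.")
  }
  if (anyDuplicated(clusters$id) > 0) {
    abort("Cluster ids must be unique.")
  }
  bad_kind <- setdiff(clusters$kind, c("criteria", "subcriteria", "alternatives"))
  if (length(bad_kind) > 0) {
    abort(sprintf("Unknown cluster kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  dangling_cluster <- setdiff(nodes$cluster_id, clusters$id)
  if (length(dangling_cluster) > 0) {
    abort(sprintf(
      "Node(s) reference unknown cluster(s): %s",
      paste(dangling_cluster, collapse = ", ")
    ))
  }
  empty <- setdiff(clusters$id, nodes$cluster_id)
  if (length(empty) > 0) {
    abort(sprintf("Cluster(s) with no members: %s", paste(empty, collapse = ", ")))
  }
  parents <- nodes$parent[!is.na(nodes$parent)]
  dangling_parent <- setdiff(parents, nodes$id)
  if (length(dangling_parent) > 0) {
    abort(sprintf(
      "Sub-criterion parent(s) not found among nodes: %s",
      paste(dangling_parent, collapse = ", ")
    ))
  }
  known_targets <- c(nodes$id, network$goal$id)
  bad_src <- setdiff(edges$source, nodes$id)
  bad_tgt <- setdiff(edges$target, known_targets)
  if (length(bad_src) > 0 || length(bad_tgt) > 0) {
    abort(sprintf(
      "Edge(s) reference unknown id(s): %s",
      paste(unique(c(bad_src, bad_tgt)), collapse = ", ")
    ))
  }
  if (any(edges$source == edges$target)) {
    abort("Self-edges (source == target) are not allowed.")
  }
  orphan <- setdiff(nodes$id, edges$source)
  if (length(orphan) > 0) {
    abort(sprintf(
      "Node(s) never compared in any context (no outgoing edge): %s",
      paste(orphan, collapse = ", ")
    ))
  }
  if (require_alternatives) {
    alt <- clusters$id[clusters$kind == "alternatives"]
    n_alt <- sum(nodes$cluster_id %in% alt)
    if (length(alt) == 0 || n_alt < 2) {
      abort("A ranking network needs an alternatives cluster with >= 2 members.")
    }
  }
  invisible(network)
}

#' Load a decision network from YAML, JSON, or a list
#'
#' The config has top-level keys `name`, `goal` (`id`, `label`),
#' `clusters` (each with `id`, `label`, `kind`, and `nodes`, each node
#' with `id`, `label`, and optionally `parent`), and `edges`. Edge
#' entries are either node-level (`source`, `target`) or cluster-level
#' shorthand that is expanded on load:
#'
#' * `source_cluster` + `target: <node id or goal id>` — every member of
#'   the cluster influences the target;
#' * `source_cluster` + `target: parent` — every member influences its
#'   own `parent` node;
#' * `source_cluster` + `target_cluster` — every member influences every
#'   node of the target cluster (`exclude_self: true` drops self-pairs,
#'   giving inner dependence without self-edges).
#'
#' @param config_source A file path (`.yaml`/`.yml`/`.json`) or a list
#'   with the structure above.
#' @param validate Run [validate_network()]? Default `TRUE`.
#' @return An `anp_network`.
#' @export
load_network <- function(config_source, validate = TRUE) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      abort(sprintf("Network config not found: %s", config_source))
    }
    if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config_source)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    abort("`config_source` must be a file path or a list.")
  }
  for (key in c("clusters", "edges")) {
    if (is.null(cfg[[key]])) {
      abort(sprintf("Network config is missing required key `%s`.", key))
    }
  }
  goal <- cfg$goal %||% list(id = "goal", label = "Goal")
  if (is.null(goal$id)) abort("Network config key `goal` needs an `id`.")
  clusters <- purrr::map_dfr(cfg$clusters, function(cl) {
    for (key in c("id", "kind", "nodes")) {
      if (is.null(cl[[key]])) {
        abort(sprintf("Cluster entry is missing required key `%s`.", key))
      }
    }
    tibble(id = cl$id, label = cl$label %||% cl$id, kind = cl$kind)
  })
  nodes <- purrr::map_dfr(cfg$clusters, function(cl) {
    purrr::map_dfr(cl$nodes, function(nd) {
      if (is.null(nd$id)) abort("Node entry is missing required key `id`.")
      tibble(
        id = nd$id, label = nd$label %||% nd$id,
        cluster_id = cl$id, parent = nd$parent %||% NA_character_
      )
    })
  })
  edges <- expand_edges(cfg$edges, nodes, goal)
  anp_network(clusters, nodes, edges,
    name = cfg$name %||% "network",
    goal = goal, validate = validate
  )
}

expand_edges <- function(entries, nodes, goal) {
  purrr::map_dfr(entries, function(e) {
    src <- e[["source"]]
    tgt <- e[["target"]]
    src_cl <- e[["source_cluster"]]
    tgt_cl <- e[["target_cluster"]]
    if (!is.null(src) && !is.null(tgt)) {
      return(tibble(source = src, target = tgt))
    }
    if (is.null(src_cl)) {
      abort("Edge entry needs `source`+`target` or `source_cluster`.")
    }
    members <- nodes$id[nodes$cluster_id == src_cl]
    if (length(members) == 0) {
      abort(sprintf("Edge references unknown cluster `%s`.", src_cl))
    }
    if (!is.null(tgt_cl)) {
      targets <- nodes$id[nodes$cluster_id == tgt_cl]
      if (length(targets) == 0) {
        abort(sprintf("Edge references unknown cluster `%s`.", tgt_cl))
      }
      out <- tidyr::expand_grid(source = members, target = targets)
      if (isTRUE(e[["exclude_self"]])) {
        out <- dplyr::filter(out, .data$source != .data$target)
      }
      return(out)
    }
    if (is.null(tgt)) abort("Edge entry with `source_cluster` needs a target.")
    if (identical(tgt, "parent")) {
      prt <- nodes$parent[match(members, nodes$id)]
      if (any(is.na(prt))) {
        abort(sprintf(
          "`target: parent` but node(s) without a parent: %s",
          paste(members[is.na(prt)], collapse = ", ")
        ))
      }
      return(tibble(source = members, target = prt))
    }
    tibble(source = members, target = tgt)
  })
}

#' Serialize a network back to YAML
#'
#' Writes the network with fully expanded node-level edges;
#' `load_network()` on the result reproduces an equivalent network.
#'
#' @param network An `anp_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "anp_network"))
  cl_list <- purrr::map(seq_len(nrow(network$clusters)), function(i) {
    cl <- network$clusters[i, ]
    nd <- dplyr::filter(network$nodes, .data$cluster_id == cl$id)
    list(
      id = cl$id, label = cl$label, kind = cl$kind,
      nodes = purrr::map(seq_len(nrow(nd)), function(j) {
        out <- list(id = nd$id[j], label = nd$label[j])
        if (!is.na(nd$parent[j])) out$parent <- nd$parent[j]
        out
      })
    )
  })
  cfg <- list(
    name = network$name,
    goal = network$goal,
    clusters = cl_list,
    edges = purrr::map(
      seq_len(nrow(network$edges)),
      function(i) as.list(network$edges[i, ])
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Enumerate the comparison contexts of a network
#'
#' A context is a set of nodes (sharing a cluster) compared pairwise
#' with respect to one target (a node or the goal). Contexts are
#' emitted in a deterministic order: the goal first, then targets in
#' network node order; within a target, source clusters in cluster
#' order. A context with a single member needs no matrix and carries a
#' forced priority of 1.
#'
#' @param network An `anp_network`.
#' @return A tibble with columns `context_id` (`"<target>__<cluster>"`),
#'   `target`, `source_cluster`, `members` (list-column of node ids, in
#'   network node order), `n`, and `needs_matrix` (`n >= 2`).
#' @export
comparison_contexts <- function(network) {
  stopifnot(inherits(network, "anp_network"))
  nodes <- network$nodes
  edges <- network$edges
  edges$source_cluster <- nodes$cluster_id[match(edges$source, nodes$id)]
  target_order <- c(network$goal$id, nodes$id)
  cluster_order <- network$clusters$id
  ctx <- edges |>
    dplyr::group_by(.data$target, .data$source_cluster) |>
    dplyr::summarise(
      members = list(intersect(nodes$id, .data$source)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = purrr::map_int(.data$members, length),
      needs_matrix = .data$n >= 2,
      context_id = paste0(.data$target, "__", .data$source_cluster)
    ) |>
    dplyr::arrange(
      match(.data$target, target_order),
      match(.data$source_cluster, cluster_order)
    )
  ctx[, c("context_id", "target", "source_cluster", "members", "n", "needs_matrix")]
}

#' The bundled shift-work disorder network
#'
#' The decision network for prioritizing shift-work disorders among
#' hospital personnel: 7 disorder criteria (sleep, personal life,
#' family life, mental, digestive, cardiovascular, musculoskeletal),
#' their 20 sub-criteria, and 3 shift alternatives (morning, evening,
#' night). The dependency structure is a goal -> criteria ->
#' sub-criteria -> alternatives hierarchy plus, by default, inner
#' dependence among the criteria (each criterion's importance is also
#' judged with respect to every other criterion). The exact
#' expert-elicited edge set of the source study was not published; this
#' default is a documented assumption and can be overridden by editing
#' the YAML config (see [load_network()]).
#'
#' @param criteria_feedback Include the criterion-level inner-dependence
#'   edges? Default `TRUE`; `FALSE` gives the pure hierarchy.
#' @return An `anp_network` with 30 nodes.
#' @export
shift_work_network <- function(criteria_feedback = TRUE) {
  path <- system.file("extdata", "shift_work_network.yaml",
    package = "shiftanp", mustWork = TRUE
  )
  net <- load_network(path)
  if (!criteria_feedback) {
    crit <- net$nodes$id[net$nodes$cluster_id == "criteria"]
    keep <- !(net$edges$source %in% crit & net$edges$target %in% crit)
    net$edges <- net$edges[keep, ]
    validate_network(net)
  }
  net
}
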