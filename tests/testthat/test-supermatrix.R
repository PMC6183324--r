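test_that("unweighted assembly places local priorities by context target", {
  net <- toy_min_network()
  pri <- tibble::tibble(
    context_id = "c1__alternatives", node = c("a1", "a2"), weight = c(0.7, 0.3)
  )
  W <- assemble_unweighted(net, pri)
  expect_equal(dim(W), c(3, 3))
  expect_equal(unname(W[c("a1", "a2"), "c1"]), c(0.7, 0.3))
  expect_setequal(attr(W, "zero_columns"), c("a1", "a2"))
  expect_error(
    assemble_unweighted(net, pri[0, ]),
    "c1__alternatives"
  )
})

test_that("shift-work supermatrix has order 30 and stochastic weighted columns", {
  net <- shift_work_network()
  set.seed(3)
  pri <- random_priorities(net)
  W <- assemble_unweighted(net, pri)
  expect_equal(dim(W), c(30, 30))
  Wg <- weight_supermatrix(W, net)
  sums <- colSums(Wg)
  nz <- sums > 0
  expect_true(all(abs(sums[nz] - 1) < 1e-9))
  # criterion columns mix two source clusters at equal weight
  crit <- net$nodes$id[net$nodes$cluster_id == "criteria"]
  sub_block <- Wg[net$nodes$id[net$nodes$cluster_id == "subcriteria"], crit[1]]
  expect_equal(sum(sub_block), 0.5, tolerance = 1e-12)
})

test_that("explicit cluster weights rescale blocks convexly", {
  net <- shift_work_network()
  set.seed(4)
  pri <- random_priorities(net)
  W <- assemble_unweighted(net, pri)
  cw <- tibble::tibble(
    source_cluster = c("criteria", "subcriteria"),
    target_cluster = c("criteria", "criteria"),
    weight = c(0.25, 0.75)
  )
  Wg <- weight_supermatrix(W, net, cw)
  crit <- net$nodes$id[net$nodes$cluster_id == "criteria"]
  subs <- net$nodes$id[net$nodes$cluster_id == "subcriteria"]
  expect_equal(sum(Wg[subs, crit[2]]), 0.75, tolerance = 1e-12)
  expect_equal(sum(Wg[crit, crit[2]]), 0.25, tolerance = 1e-12)
  expect_true(all(abs(colSums(Wg)[colSums(Wg) > 0] - 1) < 1e-9))
})

test_that("limit handles absorbing, cyclic, and primitive chains", {
  # absorbing: hierarchy mass concentrates on the alternatives
  net <- toy_min_network()
  pri <- tibble::tibble(
    context_id = "c1__alternatives", node = c("a1", "a2"), weight = c(0.7, 0.3)
  )
  L <- limit_supermatrix(weight_supermatrix(assemble_unweighted(net, pri), net))
  expect_equal(unname(L[c("a1", "a2"), "c1"]), c(0.7, 0.3), tolerance = 1e-9)

  # 2-cycle: raw powers oscillate, the Cesaro average is (1/2, 1/2)
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  L2 <- limit_supermatrix(M)
  expect_equal(unname(L2), matrix(0.5, 2, 2),
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(attr(L2, "cesaro_period"), 2L)

  # random primitive column-stochastic 6x6: limit column equals the
  # stationary distribution from an independent linear solve
  set.seed(21)
  P <- matrix(runif(36, 0.01, 1), 6, 6)
  P <- sweep(P, 2, colSums(P), "/")
  L3 <- limit_supermatrix(P)
  pi_hat <- stationary_oracle(P)
  for (j in 1:6) {
    expect_equal(unname(L3[, j]), pi_hat, tolerance = 1e-8)
  }
  expect_true(attr(L3, "columns_equal"))
  expect_true(all(abs(colSums(L3) - 1) < 1e-8))

  # idempotence
  L4 <- limit_supermatrix(L3)
  expect_equal(unname(L4), unname(L3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("extract_priorities renormalizes a published pseudo-limit", {
  net <- shift_work_network()
  pub <- published_weights("nurses_8h", warn = FALSE)
  crit <- setNames(pub$criteria$weight, pub$criteria$node)
  subs <- setNames(
    crit[pub$subcriteria$criterion] * pub$subcriteria$weight,
    pub$subcriteria$node
  )
  alts <- setNames(pub$alternatives$weight, pub$alternatives$node)
  out <- extract_priorities(c(crit, subs, alts), net)
  expect_equal(
    out$weight[out$node == "sleep_disorders"], 0.297,
    tolerance = 2e-3
  )
  expect_equal(out$weight[out$node == "sleeplessness"], 0.633, tolerance = 2e-3)
  expect_equal(out$weight[out$node == "hypnotics"], 0.366, tolerance = 2e-3)
  # local sub-criterion weights sum to 1 within each parent
  sub_rows <- out[out$kind == "subcriteria", ]
  sums <- tapply(sub_rows$weight, sub_rows$parent, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # uniform mass: all criteria equal-weighted
  uni <- extract_priorities(
    setNames(rep(1, 30), net$nodes$id), net
  )
  expect_true(all(abs(uni$weight[uni$kind == "criteria"] - 1 / 7) < 1e-12))
  # zero cluster mass errors
  expect_error(
    extract_priorities(c(crit, subs), net),
    "zero limit mass"
  )
})

test_that("hierarchical limit equals the closed-form AHP composition", {
  net <- toy_hierarchy_network()
  set.seed(8)
  for (rep in 1:5) {
    pri <- random_priorities(net)
    W <- weight_supermatrix(assemble_unweighted(net, pri), net)
    L <- limit_supermatrix(W)
    goal_w <- dplyr::filter(pri, context_id == "goal__criteria")
    seed_vec <- setNames(rep(0, 9), rownames(L))
    seed_vec[goal_w$node] <- goal_w$weight
    mass <- as.vector(L %*% seed_vec)
    names(mass) <- rownames(L)
    alt <- mass[c("alt1", "alt2", "alt3")]
    expect_equal(alt / sum(alt), ahp_composition(net, pri), tolerance = 1e-8)
  }
})

test_that("desirability index matches the brute-force triple loop", {
  # one-term sum
  d1 <- desirability_index(
    p = c(c1 = 1),
    sub = tibble::tibble(criterion = "c1", subcriterion = "s1", ad = 0.8, a1 = 1),
    s = tibble::tibble(
      subcriterion = "s1", alternative = c("a1", "a2", "a3"),
      impact = c(1, 0, 0)
    )
  )
  expect_equal(d1$d[d1$alternative == "a1"], 0.8)
  expect_equal(d1$d[d1$alternative != "a1"], c(0, 0))

  # uniform impacts: all alternatives equal
  sub <- tibble::tibble(
    criterion = rep(c("c1", "c2"), each = 3),
    subcriterion = paste0("s", 1:6),
    ad = runif(6, 0.2, 1), a1 = rep(1 / 3, 6)
  )
  s_uni <- tidyr::expand_grid(
    subcriterion = paste0("s", 1:6), alternative = c("a1", "a2", "a3")
  )
  s_uni$impact <- 1 / 3
  d2 <- desirability_index(c(c1 = 0.6, c2 = 0.4), sub, s_uni)
  expect_true(all(abs(d2$d - d2$d[1]) < 1e-15))

  # random instance vs naive summation oracle
  set.seed(13)
  for (rep in 1:5) {
    p <- runif(2)
    p <- setNames(p / sum(p), c("c1", "c2"))
    sub <- tibble::tibble(
      criterion = rep(c("c1", "c2"), each = 3),
      subcriterion = paste0("s", 1:6),
      ad = runif(6, 0.1, 1),
      a1 = as.vector(vapply(1:2, function(i) {
        x <- runif(3)
        x / sum(x)
      }, numeric(3)))
    )
    s_tbl <- tidyr::expand_grid(
      subcriterion = paste0("s", 1:6), alternative = c("a1", "a2", "a3")
    )
    s_tbl$impact <- as.vector(vapply(1:6, function(k) {
      x <- runif(3)
      x / sum(x)
    }, numeric(3)))
    got <- desirability_index(p, sub, s_tbl)
    want <- desirability_oracle(p, sub, s_tbl)
    expect_equal(setNames(got$d, got$alternative), want, tolerance = 1e-12)
    expect_equal(sum(got$d_norm), 1, tolerance = 1e-12)
  }

  # shape mismatch
  expect_error(
    desirability_index(c(c1 = 1),
      sub = tibble::tibble(criterion = "c1", subcriterion = "s1", ad = 1, a1 = 1),
      s = tibble::tibble(subcriterion = "s2", alternative = "a1", impact = 1)
    ),
    "different sub-criteria"
  )
})

test_that("alternatives are ranked descending with lexicographic tie flags", {
  r <- rank_alternatives(c(
    night_shift = 0.656, evening_shift = 0.183, morning_shift = 0.160
  ))
  expect_equal(r$node, c("night_shift", "evening_shift", "morning_shift"))
  expect_false(any(r$tied))
  r2 <- rank_alternatives(c(b = 0.4, a = 0.4, c = 0.2))
  expect_equal(r2$node, c("a", "b", "c"))
  expect_equal(r2$tied, c(TRUE, TRUE, FALSE))
})
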