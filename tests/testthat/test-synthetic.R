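test_that("consistent matrices are ratio quotients, clipped at the bounds", {
  expect_equal(
    unname(consistent_matrix_from(c(a = 0.5, b = 0.5))),
    matrix(1, 2, 2),
    ignore_attr = TRUE
  )
  A <- consistent_matrix_from(c(a = 0.6, b = 0.3, c = 0.1))
  expect_equal(A["a", "b"], 2)
  expect_equal(A["a", "c"], 6)
  expect_equal(A["b", "c"], 3)
  expect_equal(lambda_max(A), 3, tolerance = 1e-12)

  B <- consistent_matrix_from(c(a = 0.95, b = 0.05))
  expect_equal(B["a", "b"], 9)
  expect_equal(B["b", "a"], 1 / 9)
  expect_gt(attr(B, "n_clipped"), 0)
})

test_that("perturbation is seed-deterministic and a pure snap at sigma 0", {
  A <- consistent_matrix_from(c(a = 0.55, b = 0.3, c = 0.15))
  s1 <- perturb_matrix(A, sigma = 0)
  s2 <- perturb_matrix(A, sigma = 0)
  expect_identical(s1, s2)
  expect_true(all(is_saaty_value(s1[upper.tri(s1)])))
  expect_true(all(abs(s1 * t(s1) - 1) < 1e-12))

  p1 <- perturb_matrix(A, sigma = 0.3, seed = 123)
  p2 <- perturb_matrix(A, sigma = 0.3, seed = 123)
  expect_identical(p1, p2)
  expect_false(identical(p1, perturb_matrix(A, sigma = 0.3, seed = 124)))
})

test_that("snap bias at sigma 0 stays within half a grid gap", {
  set.seed(23)
  for (rep in 1:20) {
    w <- runif(4, 0.1, 1)
    w <- w / sum(w)
    A <- consistent_matrix_from(setNames(w, paste0("n", 1:4)))
    S <- perturb_matrix(A, sigma = 0)
    dom_a <- pmax(A[upper.tri(A)], 1 / A[upper.tri(A)])
    dom_s <- pmax(S[upper.tri(S)], 1 / S[upper.tri(S)])
    expect_true(all(abs(dom_a - dom_s) <= 0.5 + 1e-9))
  }
})

test_that("noise makes large consistent matrices measurably inconsistent", {
  w <- exp(seq(0, 1.2, length.out = 7))
  A <- consistent_matrix_from(setNames(w / sum(w), paste0("n", 1:7)))
  crs <- vapply(1:300, function(s) {
    P <- perturb_matrix(A, sigma = 0.3, seed = s)
    consistency(P)$cr
  }, numeric(1))
  expect_gte(mean(crs > 0), 0.95)
})

test_that("fixture-seeded ground truth covers every context and sums to 1", {
  net <- shift_work_network()
  gt <- ground_truth_from_published(net, "nurses_8h")
  ctx <- comparison_contexts(net)
  expect_setequal(
    unique(gt$context_id), ctx$context_id[ctx$needs_matrix]
  )
  sums <- tapply(gt$weight, gt$context_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # support group: the unprinted evening shift gets the smallest
  # representable ratio before renormalization
  gts <- ground_truth_from_published(net, "support_12_24")
  alt <- gts[gts$context_id == "sleeplessness__alternatives", ]
  expect_equal(nrow(alt), 3)
  ev <- alt$weight[alt$node == "evening_shift"]
  ni <- alt$weight[alt$node == "night_shift"]
  expect_equal(ev, ni / 9, tolerance = 1e-9)
})

test_that("cohort generation is deterministic with independent groups", {
  net <- shift_work_network()
  des <- cohort_design(sizes = 2, seed = 77)
  r1 <- generate_cohort(des, sigma = 0.2, network = net)
  r2 <- generate_cohort(des, sigma = 0.2, network = net)
  expect_identical(r1$matrix, r2$matrix)
  expect_identical(attr(r1, "demographics"), attr(r2, "demographics"))

  # changing one group's seed leaves the other groups bit-identical
  des2 <- des
  des2$group_seed[2] <- des2$group_seed[2] + 1L
  r3 <- generate_cohort(des2, sigma = 0.2, network = net)
  g1 <- r1[r1$group == "nurses_8h", ]
  g3 <- r3[r3$group == "nurses_8h", ]
  expect_identical(g1$matrix, g3$matrix)
  expect_false(identical(
    r1[r1$group == "support_12_24", ]$matrix,
    r3[r3$group == "support_12_24", ]$matrix
  ))
})

test_that("zero-noise respondents are identical and demographics attach", {
  net <- toy_hierarchy_network()
  des <- cohort_design(groups = "g1", sizes = 2, seed = 5)
  resp <- generate_cohort(des, toy_hierarchy_truth(), sigma = 0, network = net)
  mats <- split(resp$matrix, resp$respondent_id)
  expect_identical(mats[[1]], mats[[2]])
  demo <- attr(resp, "demographics")
  expect_equal(nrow(demo), 2)
  expect_true(all(demo$sex == "male"))
  expect_true(all(c("marital_status", "shift_selection", "satisfied")
  %in% names(demo)))
})

test_that("recovery report is exact on identity and on zero-noise grid truths", {
  truth <- toy_hierarchy_truth()
  rec <- recovery_report(truth, truth)
  expect_equal(rec$summary$max_abs_error, 0)
  expect_equal(rec$summary$share_exact_rank, 1)
  expect_true(all(abs(rec$contexts$kendall_tau - 1) < 1e-12))

  net <- toy_hierarchy_network()
  des <- cohort_design(groups = "g1", sizes = 3, seed = 41)
  resp <- generate_cohort(des, truth, sigma = 0, network = net)
  est <- context_priorities(aggregate_judgments(resp)) |>
    dplyr::select("context_id", "node", "weight")
  rec2 <- recovery_report(truth, est)
  expect_lte(rec2$summary$max_abs_error, 0.02)
  expect_equal(rec2$summary$share_exact_rank, 1)

  expect_error(
    recovery_report(truth, est[est$context_id != "goal__criteria", ]),
    "different contexts"
  )
})
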