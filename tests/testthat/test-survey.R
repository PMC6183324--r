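toy_csv <- function() {
  # two respondents covering both contexts of the minimal network
  tibble::tribble(
    ~respondent_id, ~group, ~context_id, ~row_node, ~col_node, ~judgment,
    "r1", "g1", "c1__alternatives", "a1", "a2", "3",
    "r2", "g1", "c1__alternatives", "a1", "a2", "1/3"
  )
}

test_that("long-format responses parse into reciprocal matrices", {
  net <- toy_min_network()
  rec <- read_responses(toy_csv(), net)
  expect_equal(nrow(rec), 2)
  A <- rec$matrix[[which(rec$respondent_id == "r1")]]
  expect_equal(A["a1", "a2"], 3)
  expect_equal(A["a2", "a1"], 1 / 3)
  # fraction strings parse
  B <- rec$matrix[[which(rec$respondent_id == "r2")]]
  expect_equal(B["a1", "a2"], 1 / 3)
})

test_that("responses survive a CSV write/read round trip", {
  net <- shift_work_network()
  des <- cohort_design(groups = "nurses_8h", sizes = 2, seed = 9)
  resp <- generate_cohort(des, sigma = 0.2, network = net)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, path)
  back <- read_responses(path, net)
  expect_equal(nrow(back), nrow(resp))
  key <- order(back$respondent_id, back$context_id)
  key0 <- order(resp$respondent_id, resp$context_id)
  for (i in seq_along(key)) {
    A0 <- resp$matrix[[key0[i]]]
    A1 <- back$matrix[[key[i]]]
    expect_equal(A1[rownames(A0), colnames(A0)], A0, tolerance = 1e-9,
      ignore_attr = TRUE
    )
  }
})

test_that("invalid judgments are rejected with the offending cell named", {
  net <- toy_min_network()
  bad <- toy_csv()
  bad$judgment[1] <- "11"
  expect_error(read_responses(bad, net), "r1.*a1.*a2|Off-scale")

  contra <- tibble::tribble(
    ~respondent_id, ~group, ~context_id, ~row_node, ~col_node, ~judgment,
    "r1", "g1", "c1__alternatives", "a1", "a2", "3",
    "r1", "g1", "c1__alternatives", "a2", "a1", "1/2"
  )
  expect_error(read_responses(contra, net), "contradictory", ignore.case = TRUE)

  dup <- contra
  dup$row_node[2] <- "a1"
  dup$col_node[2] <- "a2"
  expect_error(read_responses(dup, net), "duplicate", ignore.case = TRUE)

  unknown <- toy_csv()
  unknown$context_id[1] <- "c9__alternatives"
  expect_error(read_responses(unknown, net), "Unknown comparison context")

  badnode <- toy_csv()
  badnode$row_node[1] <- "a9"
  expect_error(read_responses(badnode, net), "a9")

  partial <- tibble::tribble(
    ~respondent_id, ~group, ~context_id, ~row_node, ~col_node, ~judgment,
    "r1", "g1", "goal__criteria", "c1", "c1", "1"
  )
  net3 <- toy_hierarchy_network()
  expect_error(read_responses(partial, net3), "missing judgment")
})

test_that("CR screening excludes whole respondents on any failing matrix", {
  consistent <- matrix_from_judgments(c(2, 4, 2), n = 3,
    nodes = c("x", "y", "z")
  )
  inconsistent <- matrix_from_judgments(c(9, 1 / 9, 9), n = 3,
    nodes = c("x", "y", "z")
  )
  resp <- dplyr::bind_rows(
    responses_from_matrices("good", "g", list(ctx_a = consistent, ctx_b = consistent)),
    responses_from_matrices("bad", "g", list(ctx_a = consistent, ctx_b = inconsistent))
  )
  sc <- screen_by_cr(resp)
  expect_setequal(unique(sc$kept$respondent_id), "good")
  expect_setequal(unique(sc$excluded$respondent_id), "bad")
  flagged <- sc$report[sc$report$cr >= 0.1, ]
  expect_equal(flagged$respondent_id, "bad")
  expect_equal(flagged$context_id, "ctx_b")
  expect_gt(flagged$cr, 0.25)
  # infinite threshold keeps everyone
  expect_equal(nrow(screen_by_cr(resp, threshold = Inf)$excluded), 0)
  # per-matrix mode drops only the failing matrix
  pm <- screen_by_cr(resp, per_matrix = TRUE)
  expect_equal(nrow(pm$excluded), 1)
  expect_true("bad" %in% pm$kept$respondent_id)
})

test_that("screening is monotone in the threshold", {
  net <- shift_work_network()
  des <- cohort_design(groups = "nurses_8h", sizes = 12, seed = 31)
  resp <- generate_cohort(des, sigma = 0.5, network = net,
    contexts = "goal__criteria"
  )
  kept <- lapply(c(0.02, 0.05, 0.1, 0.3), function(t) {
    unique(screen_by_cr(resp, threshold = t)$kept$respondent_id)
  })
  for (i in 1:3) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("geometric-mean aggregation cancels, averages, and stays reciprocal", {
  m <- function(j) matrix_from_judgments(j, 2, nodes = c("u", "v"))
  single <- responses_from_matrices("r1", "g", list(ctx = m(3)))
  agg1 <- aggregate_judgments(single)
  expect_equal(agg1$matrix[[1]], m(3))
  expect_equal(agg1$n_respondents, 1L)

  pair <- dplyr::bind_rows(
    responses_from_matrices("r1", "g", list(ctx = m(3))),
    responses_from_matrices("r2", "g", list(ctx = m(1 / 3)))
  )
  expect_equal(aggregate_judgments(pair)$matrix[[1]]["u", "v"], 1)

  trio <- dplyr::bind_rows(
    responses_from_matrices("r1", "g", list(ctx = m(2))),
    responses_from_matrices("r2", "g", list(ctx = m(4))),
    responses_from_matrices("r3", "g", list(ctx = m(8)))
  )
  expect_equal(aggregate_judgments(trio)$matrix[[1]]["u", "v"], 4)

  # reciprocity preserved exactly on random 4x4 judgment sets, and the
  # aggregate is permutation-invariant over respondents
  set.seed(19)
  mats <- lapply(1:6, function(i) {
    A <- random_reciprocal(4)
    dimnames(A) <- list(letters[1:4], letters[1:4])
    A
  })
  resp <- purrr::map_dfr(seq_along(mats), function(i) {
    responses_from_matrices(paste0("r", i), "g", list(ctx = mats[[i]]))
  })
  agg <- aggregate_judgments(resp)$matrix[[1]]
  expect_true(all(abs(agg * t(agg) - 1) < 1e-12))
  shuffled <- resp[sample(nrow(resp)), ]
  expect_equal(aggregate_judgments(shuffled)$matrix[[1]], agg)
})

test_that("missing contexts drop a respondent from that context only", {
  m <- function(j, nodes) matrix_from_judgments(j, 2, nodes = nodes)
  full <- responses_from_matrices("r1", "g", list(
    ctx_a = m(3, c("u", "v")), ctx_b = m(5, c("p", "q"))
  ))
  partial <- responses_from_matrices("r2", "g", list(ctx_a = m(3, c("u", "v"))))
  agg <- aggregate_judgments(dplyr::bind_rows(full, partial))
  expect_equal(agg$n_respondents[agg$context_id == "ctx_a"], 2L)
  expect_equal(agg$n_respondents[agg$context_id == "ctx_b"], 1L)
})
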