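# Pairwise comparison matrices and eigenvector priorities.
#
# A comparison matrix A is positive and reciprocal: a_ii = 1,
# a_ji = 1/a_ij, entries in [1/9, 9]. Local weights are the normalized
# principal right eigenvector w of A w = lambda_max w, computed by power
# iteration; lambda_max is recovered from the Rayleigh-style ratio
# mean((A w)_i / w_i).

#' Build a reciprocal comparison matrix from upper-triangle judgments
#'
#' Takes the n(n-1)/2 judgments of the strict upper triangle in row-major
#' order (a_12, a_13, ..., a_1n, a_23, ...), places unit diagonal entries,
#' and fills the lower triangle with reciprocals.
#'
#' @param judgments Numeric vector of length `n*(n-1)/2`; each value must
#'   lie on the 17-value admissible grid (see [saaty_values()]) unless
#'   `strict = FALSE`, in which case any value in `[1/9, 9]` is accepted
#'   (used for aggregated judgments, which may fall off the grid).
#' @param n Matrix order (number of compared elements), `n >= 1`.
#' @param nodes Optional character vector of element ids used as dimnames.
#' @param strict Require grid membership? Default `TRUE`.
#' @return An `n` by `n` reciprocal matrix.
#' @export
#' @examples
#' matrix_from_judgments(c(3, 5, 3), n = 3)
matrix_from_judgments <- function(judgments, n, nodes = NULL, strict = TRUE) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  m <- n * (n - 1) / 2
  if (length(judgments) != m) {
    abort(sprintf(
      "Expected %d upper-triangle judgments for n = %d, got %d.",
      m, n, length(judgments)
    ))
  }
  if (m > 0) {
    if (strict) {
      bad <- which(!is_saaty_value(judgments))
    } else {
      bad <- which(!is.finite(judgments) | judgments < 1 / 9 - 1e-9 |
        judgments > 9 + 1e-9)
    }
    if (length(bad) > 0) {
      abort(sprintf(
        "Judgment(s) at position(s) %s not admissible (must lie %s): %s",
        paste(bad, collapse = ", "),
        if (strict) "on the 17-value Saaty grid" else "in [1/9, 9]",
        paste(signif(judgments[bad], 4), collapse = ", ")
      ))
    }
  }
  A <- diag(1, n)
  if (m > 0) {
    idx <- which(upper.tri(A), arr.ind = TRUE)
    # row-major upper triangle: order by row then column
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    A[idx] <- judgments
    A[idx[, c(2, 1), drop = FALSE]] <- 1 / judgments
  }
  if (!is.null(nodes)) {
    stopifnot(length(nodes) == n)
    dimnames(A) <- list(nodes, nodes)
  }
  A
}

#' Validate a comparison matrix
#'
#' Checks squareness, positivity, unit diagonal, reciprocity to `tol`,
#' and the `[1/9, 9]` entry range.
#'
#' @param A Matrix to validate.
#' @param tol Reciprocity tolerance, default `1e-12` (relative).
#' @return `A`, invisibly; errors describe the first violation found.
#' @export
validate_comparison_matrix <- function(A, tol = 1e-12) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort("A comparison matrix must be square.")
  }
  if (any(!is.finite(A)) || any(A <= 0)) {
    abort("Comparison matrix entries must be finite and positive.")
  }
  if (any(abs(diag(A) - 1) > tol)) {
    abort("Comparison matrix diagonal must be 1.")
  }
  if (any(abs(A * t(A) - 1) > 1e-8)) {
    abort("Comparison matrix is not reciprocal: a_ji must equal 1/a_ij.")
  }
  if (any(A < 1 / 9 - 1e-9) || any(A > 9 + 1e-9)) {
    abort("Comparison matrix entries must lie in [1/9, 9].")
  }
  invisible(A)
}

#' Principal eigenvector priorities of a comparison matrix
#'
#' Power iteration with renormalization at every step; convergence is
#' declared when the maximum absolute change between successive iterates
#' falls below `tol`.
#'
#' @param A A valid reciprocal comparison matrix.
#' @param tol Convergence tolerance on successive iterates, default `1e-12`.
#' @param max_iter Iteration cap, default `10000`.
#' @param validate Run [validate_comparison_matrix()] first? Default `TRUE`.
#' @return A normalized weight vector summing to 1, named after the
#'   matrix dimnames when present.
#' @export
#' @examples
#' A <- matrix_from_judgments(c(3, 5, 3), n = 3)
#' priority_vector(A)
priority_vector <- function(A, tol = 1e-12, max_iter = 10000, validate = TRUE) {
  if (validate) validate_comparison_matrix(A)
  n <- nrow(A)
  if (n == 1) {
    w <- 1
    names(w) <- rownames(A)
    return(w)
  }
  w <- rep(1 / n, n)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w_new <- as.vector(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    abort(sprintf(
      "Power iteration did not converge in %d iterations (residual %.3e).",
      max_iter, max(abs(as.vector(A %*% w) / sum(A %*% w) - w))
    ))
  }
  names(w) <- rownames(A)
  w
}

#' Principal eigenvalue estimate of a comparison matrix
#'
#' Given the priority vector `w`, the principal eigenvalue is estimated
#' as the mean of the component-wise ratios `(A w)_i / w_i`; for an
#' exact eigenpair every ratio equals lambda_max. Equals `n` exactly for
#' consistent matrices.
#'
#' @param A Comparison matrix.
#' @param w Its priority vector; computed if missing.
#' @return Scalar eigenvalue estimate.
#' @export
lambda_max <- function(A, w = NULL) {
  if (is.null(w)) w <- priority_vector(A)
  mean(as.vector(A %*% w) / w)
}

#' Consistency index
#'
#' `CI = (lambda_max - n) / (n - 1)`. A 1x1 or 2x2 reciprocal matrix is
#' always consistent, so CI is defined as 0 for `n <= 2`.
#'
#' @param lambda Principal eigenvalue estimate.
#' @param n Matrix order, `n >= 1`.
#' @return Scalar CI; tiny negative values from floating-point round-off
#'   are clamped to 0.
#' @export
consistency_index <- function(lambda, n) {
  stopifnot(n >= 1)
  if (n <= 2) {
    return(0)
  }
  max((lambda - n) / (n - 1), 0)
}

#' Tabulated average random consistency index (RCI)
#'
#' Average consistency index of random reciprocal matrices by order
#' (1 to 10), from a 500-sample simulation with upper-triangle entries
#' drawn uniformly from the 17 admissible values. Reproducible with
#' [estimate_rci()].
#'
#' @return A tibble with columns `n` and `rci`.
#' @export
rci_table <- function() {
  tibble(
    n = 1:10,
    rci = c(0, 0, 0.52, 0.89, 1.11, 1.25, 1.35, 1.40, 1.45, 1.49)
  )
}

#' Consistency ratio and acceptability report
#'
#' `CR = CI / RCI(n)`; for `n <= 2` both CI and RCI are 0 and CR is
#' defined as 0. A judgment matrix is acceptable when `CR < 0.1`
#' (strict: a matrix with CR exactly 0.1 is not acceptable).
#'
#' @param ci Consistency index.
#' @param n Matrix order.
#' @param rci Random consistency index for order `n`; taken from
#'   [rci_table()] when `NULL`. Orders above 10 require an explicit
#'   value (see [estimate_rci()]).
#' @param threshold Acceptability threshold, default `0.1`.
#' @return A one-row tibble: `n`, `ci`, `rci`, `cr`, `acceptable`.
#' @export
consistency_ratio <- function(ci, n, rci = NULL, threshold = 0.1) {
  stopifnot(n >= 1, ci >= 0)
  if (is.null(rci)) {
    if (n > 10) {
      abort(paste(
        "No tabulated RCI for n > 10;",
        "supply `rci` (e.g. from estimate_rci(n, ...))."
      ))
    }
    rci <- rci_table()$rci[n]
  }
  cr <- if (n <= 2 || rci == 0) 0 else ci / rci
  # strict comparison with a guard against floating-point round-off:
  # a ratio at the threshold (e.g. CI/RCI = 0.052/0.52) is not acceptable
  tibble(
    n = as.integer(n), ci = ci, rci = rci, cr = cr,
    acceptable = (threshold - cr) > 1e-12
  )
}

#' Full consistency report for a comparison matrix
#'
#' Convenience wrapper computing the priority vector, lambda_max, CI,
#' CR, and the acceptability flag in one call.
#'
#' @inheritParams priority_vector
#' @inheritParams consistency_ratio
#' @return A one-row tibble: `n`, `lambda_max`, `ci`, `rci`, `cr`,
#'   `acceptable`, plus a `weights` list-column with the priority vector.
#' @export
consistency <- function(A, rci = NULL, threshold = 0.1, validate = TRUE) {
  w <- priority_vector(A, validate = validate)
  n <- nrow(A)
  lam <- lambda_max(A, w)
  ci <- consistency_index(lam, n)
  rep <- consistency_ratio(ci, n, rci = rci, threshold = threshold)
  dplyr::mutate(rep,
    lambda_max = lam, weights = list(w),
    .after = "n"
  )
}

#' Monte Carlo estimate of the random consistency index
#'
#' Draws `samples` random reciprocal matrices of order `n` whose
#' upper-triangle entries are i.i.d. uniform over the 17 admissible
#' judgment values, computes each matrix's consistency index by the
#' eigenvector method, and returns the mean. With the conventional
#' 500-sample size this reproduces the tabulated RCI values in
#' [rci_table()] to within Monte Carlo error.
#'
#' @param n Matrix order, `n >= 1`. Orders 1 and 2 return 0 exactly.
#' @param samples Number of random matrices, default `500`.
#' @param seed Integer seed; the estimate is reproducible per seed.
#' @return Scalar mean consistency index.
#' @export
#' @examples
#' estimate_rci(3, samples = 200, seed = 1)
estimate_rci <- function(n, samples = 500, seed = 1) {
  stopifnot(n >= 1, samples >= 1)
  if (n <= 2) {
    return(0)
  }
  grid <- saaty_values()
  m <- n * (n - 1) / 2
  withr_seed(seed, {
    cis <- vapply(seq_len(samples), function(s) {
      A <- matrix_from_judgments(sample(grid, m, replace = TRUE), n)
      w <- priority_vector(A, validate = FALSE)
      consistency_index(lambda_max(A, w), n)
    }, numeric(1))
    mean(cis)
  })
}

# Evaluate `code` under a local RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  code
}
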