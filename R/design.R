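#' Effect-coded age-period-cohort design matrix
#'
#' Builds the m x q design matrix of the Poisson log-linear APC model
#' log r = mu + alpha_i + beta_j + gamma_k with m = A * P rows (one per
#' grid cell, age-major order) and q = 1 + (A-1) + (P-1) + (C-1)
#' columns. Each categorical block uses sum-to-zero (effect) coding with
#' the last category as reference: a cell in category c < L contributes
#' an indicator 1 in column c of the block; a cell in the reference
#' category contributes -1 across all the block's columns. The cohort
#' block is indexed along the diagonals k = (A - i) + j.
#'
#' Because of the structural dependency cohort = period - age, the
#' matrix has rank q - 1: a one-dimensional null space that is the
#' source of the APC identification problem.
#'
#' @param A number of age groups (>= 2).
#' @param P number of periods (>= 2).
#' @return Object of class `apc_design`: the matrix `X`, dimensions
#'   `A`, `P`, `C`, `q`, column labels, and a `row_map` of (i, j, k).
#' @export
apc_design <- function(A, P) {
  A <- as.integer(A); P <- as.integer(P)
  if (is.na(A) || is.na(P) || A < 2L || P < 2L)
    abort_validation("APC design needs at least 2 age groups and 2 periods")
  C <- A + P - 1L
  q <- 1L + (A - 1L) + (P - 1L) + (C - 1L)
  m <- A * P

  code <- function(cat, L) {
    v <- numeric(L - 1L)
    if (cat < L) v[cat] <- 1 else v[] <- -1
    v
  }

  X <- matrix(0, m, q)
  row_map <- data.frame(i = integer(m), j = integer(m), k = integer(m))
  for (i in seq_len(A)) {
    for (j in seq_len(P)) {
      r <- (i - 1L) * P + j
      k <- (A - i) + j
      X[r, 1L] <- 1
      X[r, 1L + seq_len(A - 1L)] <- code(i, A)
      X[r, A + seq_len(P - 1L)] <- code(j, P)
      X[r, A + P - 1L + seq_len(C - 1L)] <- code(k, C)
      row_map[r, ] <- c(i, j, k)
    }
  }
  labels <- c("(Intercept)",
              paste0("age", seq_len(A - 1L)),
              paste0("period", seq_len(P - 1L)),
              paste0("cohort", seq_len(C - 1L)))
  colnames(X) <- labels
  structure(list(X = X, A = A, P = P, C = C, q = q, m = m,
                 col_labels = labels, row_map = row_map),
            class = "apc_design")
}

#' @export
print.apc_design <- function(x, ...) {
  cat(sprintf("apc_design: A=%d, P=%d, C=%d; %d rows x %d columns (rank %d)\n",
              x$A, x$P, x$C, x$m, x$q, x$q - 1L))
  invisible(x)
}

#' Null vector of the APC design
#'
#' Computes, by full singular-value decomposition, the unique (up to
#' sign) unit vector b0 spanning the design's null space: X b0 = 0.
#' Adding any multiple of b0 to a coefficient vector leaves every fitted
#' rate unchanged, so constraining the solution orthogonal to b0 (the
#' intrinsic estimator) selects the minimum-norm representative.
#'
#' Normalisation: unit Euclidean norm, intercept coordinate exactly 0,
#' first nonzero coordinate positive — the returned vector is
#' deterministic for a given design.
#'
#' @param design an [apc_design()].
#' @return Named numeric vector of length q.
#' @export
null_vector <- function(design) {
  stopifnot(inherits(design, "apc_design"))
  X <- design$X
  q <- ncol(X)
  sv <- svd(X, nu = 0L, nv = q)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
  rank <- sum(sv$d > tol)
  ndim <- q - rank
  if (ndim != 1L)
    abort_identification(sprintf(
      "null space has dimension %d (expected 1); effects are not identified by a single constraint",
      ndim), null_dimension = ndim)
  b0 <- sv$v[, rank + 1L]
  if (abs(b0[1]) > 1e-8)
    abort_identification("null vector has a nonzero intercept coordinate; design is malformed")
  b0[1] <- 0
  b0 <- b0 / sqrt(sum(b0^2))
  first <- which(abs(b0) > 1e-8)[1]
  if (b0[first] < 0) b0 <- -b0
  names(b0) <- design$col_labels
  b0
}

# Closed-form null direction: the linear-trend trade-off
# alpha_i <- alpha_i + s(i - mean), beta_j <- beta_j - s(j - mean),
# gamma_k <- gamma_k + s(k - mean), re-expressed in effect coding.
# Used as an independent cross-check of the SVD route.
analytic_null <- function(A, P) {
  C <- A + P - 1L
  tA <- seq_len(A - 1L) - (A + 1) / 2
  tP <- seq_len(P - 1L) - (P + 1) / 2
  tC <- seq_len(C - 1L) - (C + 1) / 2
  v <- c(0, tA, -tP, tC)
  v / sqrt(sum(v^2))
}

#' Project a parameter vector orthogonal to the null direction
#'
#' Returns `theta - (theta . b0) b0`, the component of `theta` in the
#' orthogonal complement of the null space — the estimand of the
#' intrinsic estimator.
#'
#' @param theta numeric parameter vector of length q.
#' @param b0 null vector from [null_vector()] (same length).
#' @return Vector of the same length, orthogonal to `b0`.
#' @export
project_out_null <- function(theta, b0) {
  if (length(theta) != length(b0))
    abort_validation(sprintf(
      "length mismatch: theta has %d elements, b0 has %d",
      length(theta), length(b0)),
      subclass = "apcie_dimension_error")
  as.vector(theta) - sum(theta * b0) * as.vector(b0)
}
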