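# Shared fixtures and independent oracles.

# Minimum-norm least-squares solve via SVD pseudoinverse (independent of
# the package's basis-projection route).
pinv_solve <- function(M, y) {
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
}

# Small deterministic 3x3 Lexis table (ages 50-64, years 1990-2000).
small_table <- function() {
  rate_table(
    deaths = rbind(c(5, 7, 6), c(4, 8, 9), c(10, 3, 6)),
    population = matrix(1e4, 3, 3),
    age_start = c(50, 55, 60), age_end = c(54, 59, 64),
    years = c(1990, 1995, 2000))
}

# Well-formed long CSV for a given table, written to a temp file.
write_temp_csv <- function(table) {
  f <- tempfile(fileext = ".csv")
  write_rate_table(table, f)
  f
}

# Concatenate a fit's expanded effects in table order.
all_effects <- function(fit) {
  c(fit$age_effects, fit$period_effects, fit$cohort_effects)
}

# Expand a reduced (effect-coded) parameter vector into full sum-to-zero
# blocks: list(mu, alpha, beta, gamma).
expand_theta <- function(theta, A, P) {
  C <- A + P - 1L
  ex <- function(x) c(x, -sum(x))
  list(mu = theta[1],
       alpha = ex(theta[1L + seq_len(A - 1L)]),
       beta = ex(theta[A + seq_len(P - 1L)]),
       gamma = ex(theta[A + P - 1L + seq_len(C - 1L)]))
}
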