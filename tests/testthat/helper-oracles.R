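# Shared fixtures and independent oracles used across the test files.

# Small genotype_data built directly from a count matrix.
make_geno <- function(Z, ids = sprintf("s%d", seq_len(ncol(Z)))) {
  new_genotype_data(Z, snp_ids = ids, chrom = rep(1L, ncol(Z)),
                    pos = seq_len(ncol(Z)),
                    alleles = cbind(A1 = rep("A", ncol(Z)),
                                    A2 = rep("B", ncol(Z))),
                    sample_ids = sprintf("i%d", seq_len(nrow(Z))))
}

# Elastic-net objective of the selection stage.
enet_objective <- function(W, y, u, alpha, lambda) {
  m <- nrow(W)
  sum((y - W %*% u)^2) / (2 * m) + alpha * lambda * sum(abs(u)) +
    (1 - alpha) / 2 * lambda * sum(u^2)
}

# Independent KKT/subgradient residual of the elastic-net objective: the
# gradient of the smooth part must lie in the subdifferential of the l1 term.
enet_kkt_residual <- function(W, y, u, alpha, lambda) {
  m <- nrow(W)
  grad <- -crossprod(W, y - W %*% u) / m + (1 - alpha) * lambda * u
  res <- numeric(length(u))
  act <- u != 0
  res[act] <- abs(grad[act] + alpha * lambda * sign(u[act]))
  res[!act] <- pmax(abs(grad[!act]) - alpha * lambda, 0)
  max(res)
}

# Plain cyclic coordinate descent for the same objective; deliberately
# independent of glmnet. Only for tiny instances.
enet_cd_oracle <- function(W, y, alpha, lambda, n_iter = 5000, tol = 1e-12) {
  m <- nrow(W); p <- ncol(W)
  u <- numeric(p)
  d <- colSums(W^2) / m
  r <- y
  for (it in seq_len(n_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      a <- sum(W[, j] * r) / m + d[j] * u[j]
      new <- sign(a) * max(abs(a) - alpha * lambda, 0) /
        (d[j] + (1 - alpha) * lambda)
      if (new != u[j]) {
        r <- r - W[, j] * (new - u[j])
        delta <- max(delta, abs(new - u[j]))
        u[j] <- new
      }
    }
    if (delta < tol) break
  }
  u
}

# Dense evaluation of the restricted log-likelihood of y ~ N(1 b, sg2 K +
# se2 I), intercept projected out, written without the eigen-rotation used
# by the implementation.
reml_loglik_dense <- function(y, K, sg2, se2) {
  m <- length(y)
  C <- matrix(1, m, 1)
  Q2 <- qr.Q(qr(C), complete = TRUE)[, -1, drop = FALSE]
  V <- sg2 * K + se2 * diag(m)
  Vs <- crossprod(Q2, V %*% Q2)
  ys <- as.numeric(crossprod(Q2, y))
  ch <- chol(Vs)
  -0.5 * (2 * sum(log(diag(ch))) +
            sum(backsolve(ch, ys, transpose = TRUE)^2) +
            (m - 1) * log(2 * pi))
}

# Random standardized-genotype-like matrix (iid standard normal columns).
rand_design <- function(m, n, seed) {
  with_seed_test(seed, matrix(rnorm(m * n), m, n))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
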