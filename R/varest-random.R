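#' Build the genetic relationship matrix from standardized genotypes
#'
#' `K = (1/n_hat) W2 W2'` over the selected standardized SNPs: the average
#' over SNPs of the products of standardized genotypes, whose diagonal
#' averages to ~1 in an unrelated sample.
#'
#' @param W2 `m2 x n_hat` standardized genotype matrix.
#' @param sample_ids optional individual identifiers.
#' @return object of class `"grm"` with elements `K`, `n_hat`, `sample_ids`.
#' @export
build_grm <- function(W2, sample_ids = NULL) {
  n_hat <- ncol(W2)
  if (is.null(n_hat) || n_hat == 0L) stop("empty model: no SNPs to build a GRM")
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%06d", seq_len(nrow(W2)))
  structure(list(K = tcrossprod(W2) / n_hat, n_hat = as.integer(n_hat),
                 sample_ids = as.character(sample_ids)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals, %d SNPs, mean diagonal %.3f\n",
              nrow(x$K), x$n_hat, mean(diag(x$K))))
  invisible(x)
}

#' Write a GRM in the GCTA binary dialect
#'
#' Produces `<prefix>.grm.bin` (lower triangle, row-wise, float32),
#' `<prefix>.grm.N.bin` (per-pair SNP counts, float32) and
#' `<prefix>.grm.id` (FID/IID text).
#'
#' @param grm a `"grm"` object.
#' @param prefix output path prefix.
#' @export
write_grm_gcta <- function(grm, prefix) {
  K <- grm$K
  m <- nrow(K)
  lower <- K[lower.tri(K, diag = TRUE)]
  # GCTA stores row-wise lower triangle: (1,1), (2,1), (2,2), (3,1) ...
  idx <- which(lower.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower[ord]), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_hat), length(lower)), con, size = 4)
  close(con)
  write.table(data.frame(grm$sample_ids, grm$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM in the GCTA binary dialect
#' @param prefix path prefix of the .grm.bin/.grm.N.bin/.grm.id triplet.
#' @return a `"grm"` object (with `n_hat` the rounded median pair count).
#' @export
read_grm_gcta <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  m <- nrow(ids)
  n_pair <- m * (m + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_pair, size = 4)
  nsnp <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_pair, size = 4)
  K <- matrix(0, m, m)
  pos <- 1L
  for (i in seq_len(m)) {
    K[i, 1:i] <- vals[pos:(pos + i - 1L)]
    pos <- pos + i
  }
  K <- K + t(K) - diag(diag(K))
  structure(list(K = K, n_hat = as.integer(round(median(nsnp))),
                 sample_ids = as.character(ids[[2]])),
            class = "grm")
}

#' Restricted maximum likelihood fit of one variance component
#'
#' Fits `y2 ~ N(C b, sigma_g2 K + sigma_e2 I)` by REML. The intercept is
#' always projected out (plus any further covariate columns), the projected
#' kernel is eigendecomposed once, and the restricted likelihood is profiled
#' over the heritability ratio `h = sigma_g2 / (sigma_g2 + sigma_e2)` on a
#' dense grid followed by golden-section refinement, which is exact for a
#' single GRM plus residual and needs no iterative convergence tuning.
#' The average-information matrix at the optimum supplies the delta-method
#' standard error of `h`.
#'
#' @param y2 stage-2 phenotype vector.
#' @param grm a `"grm"` object (or plain symmetric matrix).
#' @param covar optional covariate matrix (an intercept is always added).
#' @param h_bounds interior search bounds for the ratio.
#' @param grid_step grid spacing of the initial profile search.
#' @param info `"average"` (default) or `"observed"` information matrix for
#'   the standard error.
#' @return object of class `"random_varest"` with `sigma_g2`, `sigma_e2`,
#'   `h2_raw`, `h2`, `clipped`, `se`, `loglik`, `converged`, `n_iter`,
#'   `info_inv`.
#' @export
reml_fit <- function(y2, grm, covar = NULL,
                     h_bounds = c(1e-6, 1 - 1e-6), grid_step = 0.01,
                     info = c("average", "observed")) {
  info <- match.arg(info)
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  m <- length(y2)
  stopifnot(nrow(K) == m, ncol(K) == m)
  C <- cbind(rep(1, m), covar)
  qr_C <- qr(C)
  if (qr_C$rank < ncol(C)) stop("covariate matrix is rank deficient")
  q <- ncol(C)
  Qfull <- qr.Q(qr_C, complete = TRUE)
  Q2 <- Qfull[, (q + 1L):m, drop = FALSE]     # basis of the error contrast space
  y_rot <- as.numeric(crossprod(Q2, y2))
  Ks <- crossprod(Q2, K %*% Q2)
  eig <- eigen((Ks + t(Ks)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  if (max(lam) - min(lam) < 1e-8 * max(1, mean(lam)))
    stop("non-identifiable model: GRM is numerically proportional to the identity")
  z <- as.numeric(crossprod(eig$vectors, y_rot))
  df <- m - q
  # profiled restricted log-likelihood of h (total variance profiled out)
  prof <- function(h) {
    v <- h * lam + (1 - h)
    s2 <- sum(z^2 / v) / df
    -0.5 * (sum(log(v)) + df * log(s2) + df * (1 + log(2 * pi)))
  }
  grid <- seq(h_bounds[1], h_bounds[2], by = grid_step)
  ll <- vapply(grid, prof, numeric(1))
  i0 <- which.max(ll)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- optimize(prof, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  h_hat <- if (opt$objective >= ll[i0]) opt$maximum else grid[i0]
  v <- h_hat * lam + (1 - h_hat)
  s2_tot <- sum(z^2 / v) / df
  sigma_g2 <- h_hat * s2_tot
  sigma_e2 <- (1 - h_hat) * s2_tot
  vv <- sigma_g2 * lam + sigma_e2
  loglik <- -0.5 * (sum(log(vv)) + sum(z^2 / vv) + df * log(2 * pi))
  I2 <- .reml_information(lam, z, sigma_g2, sigma_e2, info)
  info_inv <- tryCatch(solve(I2), error = function(e) NULL)
  se <- if (is.null(info_inv)) NA_real_ else
    tryCatch(delta_se(sigma_g2, sigma_e2, info_inv), error = function(e) NA_real_)
  h <- h2_point(sigma_g2, sigma_e2)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2_raw = h$h2_raw, h2 = h$h2, clipped = h$clipped,
                 se = se, loglik = loglik, converged = TRUE,
                 n_iter = length(grid) + 1L, info_inv = info_inv,
                 eigenvalues = lam, df = df),
            class = "random_varest")
}

# 2x2 information matrix for (sigma_g2, sigma_e2) in the eigenrotated basis
.reml_information <- function(lam, z, sg2, se2, type) {
  v <- sg2 * lam + se2
  if (type == "average") {
    matrix(0.5 * c(sum(lam^2 * z^2 / v^3), sum(lam * z^2 / v^3),
                   sum(lam * z^2 / v^3), sum(z^2 / v^3)), 2, 2)
  } else {
    matrix(c(sum(lam^2 * z^2 / v^3) - 0.5 * sum(lam^2 / v^2),
             sum(lam * z^2 / v^3) - 0.5 * sum(lam / v^2),
             sum(lam * z^2 / v^3) - 0.5 * sum(lam / v^2),
             sum(z^2 / v^3) - 0.5 * sum(1 / v^2)), 2, 2)
  }
}

#' @export
print.random_varest <- function(x, ...) {
  cat("Random-effect (REML) estimate\n")
  cat(sprintf("  sigma_g2 = %.4f  sigma_e2 = %.4f  h2 = %.4f%s%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (is.na(x$se)) "" else sprintf("  (SE %.4f)", x$se),
              if (x$clipped) "  [clipped]" else ""))
  cat(sprintf("  restricted loglik = %.3f\n", x$loglik))
  invisible(x)
}

#' Delta-method standard error of the heritability ratio
#'
#' First-order propagation of the variance-component covariance through
#' `h(sigma_g2, sigma_e2) = sigma_g2 / (sigma_g2 + sigma_e2)`: the gradient
#' is `g = (sigma_e2, -sigma_g2) / (sigma_g2 + sigma_e2)^2` and
#' `SE = sqrt(g' V g)` with `V` the inverse information of the components.
#'
#' @param sigma_g2,sigma_e2 variance components at the optimum.
#' @param info_inv 2x2 symmetric PSD covariance of the components.
#' @return standard error (scalar).
#' @export
delta_se <- function(sigma_g2, sigma_e2, info_inv) {
  info_inv <- as.matrix(info_inv)
  stopifnot(all(dim(info_inv) == c(2, 2)))
  if (max(abs(info_inv - t(info_inv))) > 1e-8 * max(1, max(abs(info_inv))))
    stop("info_inv must be symmetric")
  ev <- eigen((info_inv + t(info_inv)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("info_inv must be positive semi-definite")
  g <- c(sigma_e2, -sigma_g2) / (sigma_g2 + sigma_e2)^2
  sqrt(max(0, as.numeric(g %*% info_inv %*% g)))
}

#' Heritability point estimate from REML components
#'
#' Same ratio-and-clip rule as [h2_point()], applied to the REML variance
#' components.
#'
#' @param sigma_g2,sigma_e2 variance components.
#' @return list with `h2_raw`, `h2`, `clipped`.
#' @export
h2_point_random <- function(sigma_g2, sigma_e2) h2_point(sigma_g2, sigma_e2)
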