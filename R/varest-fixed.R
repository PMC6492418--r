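#' Trace summaries of the selected-SNP sample covariance
#'
#' With `S = (1/m2) W2' W2` the sample covariance of the selected SNPs on
#' half 2, returns `d1 = tr(S) / n_hat` (mean eigenvalue) and
#' `d2 = tr(S^2)/n_hat - tr(S)^2/(n_hat m2)` (a noise-corrected second-moment
#' summary, consistent for the mean squared eigenvalue of the population
#' covariance). When `n_hat > m2` the traces are computed on the `m2 x m2`
#' Gram form, never materializing `S`.
#'
#' @param W2 `m2 x n_hat` stage-2 design matrix.
#' @return list with `d1`, `d2`, `m2`, `n_hat`.
#' @export
compute_d1_d2 <- function(W2) {
  m2 <- nrow(W2); n_hat <- ncol(W2)
  stopifnot(n_hat >= 1, m2 >= 2)
  if (n_hat <= m2) {
    S <- crossprod(W2) / m2
    tr_s <- sum(diag(S))
    tr_s2 <- sum(S * S)
  } else {
    G <- tcrossprod(W2) / m2       # tr identities: tr(W'W) = tr(WW') etc.
    tr_s <- sum(diag(G))
    tr_s2 <- sum(G * G)
  }
  d1 <- tr_s / n_hat
  d2 <- tr_s2 / n_hat - tr_s^2 / (n_hat * m2)
  if (!is.finite(d2) || d2 <= 1e-12 * max(d1^2, 1))
    stop("degenerate design: second spectral moment d2 is numerically zero")
  list(d1 = d1, d2 = d2, m2 = m2, n_hat = n_hat)
}

.mom_from_summaries <- function(y_norm2, wy_norm2, d, formula) {
  m2 <- d$m2; n_hat <- d$n_hat; d1 <- d$d1; d2 <- d$d2
  cross <- d1 / (m2 * (m2 + 1) * d2)
  if (formula == "reference") {
    tau2 <- -n_hat * d1^2 / (m2 * (m2 + 1) * d2) * y_norm2 + cross * wy_norm2
    sig2 <- (1 + n_hat * d1^2 / ((m2 + 1) * d2)) * y_norm2 / m2 -
      cross * wy_norm2
  } else {  # the literal printed variant (d2 squared in tau2; 1/n_hat in sig2)
    tau2 <- -n_hat * d1^2 / (m2 * (m2 + 1) * d2^2) * y_norm2 + cross * wy_norm2
    sig2 <- (1 + n_hat * d1^2 / ((m2 + 1) * d2)) * y_norm2 / n_hat -
      cross * wy_norm2
  }
  list(tau2 = tau2, sig2 = sig2)
}

#' Method-of-moments variance estimation (fixed-effect branch)
#'
#' Estimates the total genetic variance `tau^2 = u' Sigma u` of the selected
#' SNPs and the residual variance from the two norms `|y2|^2` and
#' `|W2' y2|^2` together with the spectral summaries of [compute_d1_d2()].
#' The estimator is moment-based and remains valid when the selected set is
#' larger than the half-sample (`n_hat > m2`) and when SNPs are correlated.
#'
#' Two published spellings of the estimator pair circulate that differ in a
#' `d2` power and a `1/m2` vs `1/n_hat` factor; `formula = "reference"`
#' (default) is the dimensionally consistent form that is unbiased in Monte
#' Carlo checks, `"literal"` the other spelling, kept for comparison.
#'
#' @param y2 stage-2 phenotype vector (centered when `center = TRUE`).
#' @param W2 stage-2 design on the selected SNPs.
#' @param formula `"reference"` or `"literal"` (see Details).
#' @param center mean-center `y2` before forming the norms (the estimator
#'   assumes a mean-zero response).
#' @return object of class `"fixed_varest"` with `tau2_hat`, `sigma_e2_hat`,
#'   `h2_raw`, `h2`, `clipped`, the summaries `d1`, `d2`, `m2`, `n_hat`, and
#'   `se` (`NA` until [fixed_se()] fills it).
#' @export
mom_estimate <- function(y2, W2, formula = c("reference", "literal"),
                         center = TRUE) {
  formula <- match.arg(formula)
  stopifnot(length(y2) == nrow(W2))
  if (center) y2 <- y2 - mean(y2)
  d <- compute_d1_d2(W2)
  est <- .mom_from_summaries(sum(y2^2), sum(crossprod(W2, y2)^2), d, formula)
  # both estimators are homogeneous in the two norms, so y2 = 0 gives the
  # degenerate pair (0, 0) with no defined ratio
  h <- if (est$tau2 + est$sig2 == 0)
    list(h2_raw = NA_real_, h2 = NA_real_, clipped = NA) else
    h2_point(est$tau2, est$sig2)
  structure(list(tau2_hat = est$tau2, sigma_e2_hat = est$sig2,
                 h2_raw = h$h2_raw, h2 = h$h2, clipped = h$clipped,
                 d1 = d$d1, d2 = d$d2, m2 = d$m2, n_hat = d$n_hat,
                 formula = formula, se = NA_real_),
            class = "fixed_varest")
}

#' @export
print.fixed_varest <- function(x, ...) {
  cat(sprintf("Fixed-effect (method-of-moments) estimate [%s formula]\n",
              x$formula))
  cat(sprintf("  tau2 = %.4f  sigma_e2 = %.4f  h2 = %.4f%s%s\n",
              x$tau2_hat, x$sigma_e2_hat, x$h2,
              if (is.na(x$se)) "" else sprintf("  (SE %.4f)", x$se),
              if (x$clipped) "  [clipped]" else ""))
  invisible(x)
}

#' Heritability point estimate with boundary clipping
#'
#' `h2_raw = tau2 / (tau2 + sigma_e2)`. Because the true heritability lies
#' strictly inside (0, 1), estimates at or outside the boundaries are pinned
#' to 0.0001 or 0.9999 and flagged.
#'
#' @param tau2_hat genetic-variance estimate.
#' @param sigma_e2_hat residual-variance estimate.
#' @return list with `h2_raw`, `h2` and logical `clipped`.
#' @export
h2_point <- function(tau2_hat, sigma_e2_hat) {
  tot <- tau2_hat + sigma_e2_hat
  if (tot == 0) stop("undefined heritability ratio: tau2 + sigma_e2 = 0")
  clip_h2(tau2_hat / tot)
}

#' Bootstrap standard error of the fixed-effect heritability estimate
#'
#' Nonparametric bootstrap over the individuals of half 2: each resample
#' recomputes [mom_estimate()] and the clipped point estimate; the SE is the
#' standard deviation of the bootstrap estimates. Degenerate resamples are
#' dropped; if more than half fail the SE is reported missing.
#'
#' @param y2,W2 stage-2 data.
#' @param n_boot number of bootstrap resamples (>= 50 recommended; smaller
#'   values are accepted for diagnostics).
#' @param seed RNG seed.
#' @param formula,center passed to [mom_estimate()].
#' @return bootstrap standard error (scalar, possibly `NA`).
#' @export
fixed_se <- function(y2, W2, n_boot = 200L, seed = 1L,
                     formula = c("reference", "literal"), center = TRUE) {
  formula <- match.arg(formula)
  m2 <- length(y2)
  with_seed(seed, {
    h_boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m2, replace = TRUE)
      tryCatch(mom_estimate(y2[idx], W2[idx, , drop = FALSE],
                            formula = formula, center = center)$h2,
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- !is.na(h_boot)
    if (sum(ok) < n_boot / 2) {
      warning("more than half of the bootstrap resamples were degenerate")
      return(NA_real_)
    }
    if (sum(ok) < 2) return(0)
    sd(h_boot[ok])
  })
}
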