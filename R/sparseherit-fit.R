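#' Full configuration of a two-stage fit
#'
#' @param enet an [enet_config()] for the selection stage.
#' @param mom_formula method-of-moments spelling, see [mom_estimate()].
#' @param n_boot bootstrap resamples for the fixed-branch SE (0 disables).
#' @param qc a [qc_thresholds()] applied when raw counts are supplied, or
#'   `NULL` to skip QC.
#' @return object of class `"sh_config"`.
#' @export
sh_config <- function(enet = enet_config(), mom_formula = "reference",
                      n_boot = 200L, qc = qc_thresholds()) {
  structure(list(enet = enet, mom_formula = mom_formula,
                 n_boot = as.integer(n_boot), qc = qc),
            class = "sh_config")
}

#' Two-stage SNP-heritability estimation
#'
#' Estimates the SNP heritability of a quantitative trait in two stages on a
#' randomly split cohort. Stage 1 fits a cross-validated elastic net on one
#' half and keeps the SNPs with nonzero coefficients. Stage 2, on the
#' independent other half restricted to the selected SNPs, estimates variance
#' components under both a fixed-effect model (high-dimensional
#' method-of-moments, [mom_estimate()]) and a random-effect model
#' (single-component GREML, [reml_fit()]). Splitting guards against the
#' overestimation that occurs when variance is estimated on the same samples
#' that selected the model; the random-effect estimate is the headline
#' number for real data.
#'
#' @param geno a `"genotype_data"` object ([read_plink()],
#'   [simulate_genotypes()]) or a numeric matrix of genotype counts /
#'   standardized genotypes.
#' @param y phenotype vector aligned with the rows of `geno`.
#' @param covar optional covariate matrix (no intercept column needed; the
#'   nuisance space is projected out of both `y` and the genotypes before
#'   the split).
#' @param config an [sh_config()].
#' @param seed seed controlling the split, CV folds and bootstrap.
#' @return an object of class `"sparseherit"`; see [print.sparseherit()],
#'   [summary.sparseherit()], [coef.sparseherit()].
#' @examples
#' sc <- sim_scenario(m = 120, n = 60, s = 4, ld_rho = 0, seed = 7)
#' cohort <- simulate_cohort(sc)
#' fit <- sparseherit(cohort$data, cohort$y, seed = 7,
#'                    config = sh_config(enet = enet_config(
#'                      alpha_grid = c(0.5, 1), n_lambda = 30, n_folds = 5),
#'                      n_boot = 0))
#' fit
#' @export
sparseherit <- function(geno, y, covar = NULL, config = sh_config(),
                        seed = 1L) {
  cl <- match.call()
  data <- .as_standardized(geno, config$qc)
  W <- data$W
  m <- nrow(W); n <- ncol(W)
  stopifnot(length(y) == m)
  seeds <- derive_seeds(seed, 3L)
  proj <- project_covariates(y, W, covar)
  y_use <- proj$y_res
  W_use <- if (is.null(proj$W_res)) W else proj$W_res

  split <- split_sample(m, seed = seeds[1])
  cfg1 <- config$enet
  cfg1$cv_seed <- seeds[2]
  sel <- select_model(W_use[split$half1, , drop = FALSE], y_use[split$half1],
                      cfg1)
  est <- .stage2_estimates(y_use, W_use, split$half2, sel$M_hat, config,
                           boot_seed = seeds[3])
  structure(list(call = cl, m = m, n = n, split = split, selection = sel,
                 fixed = est$fixed, random = est$random,
                 empty_selection = sel$empty,
                 snp_ids = data$snp_ids, config = config, seed = seed,
                 covar_q = proj$q),
            class = "sparseherit")
}

.as_standardized <- function(geno, qc) {
  if (inherits(geno, "genotype_data")) {
    if (is.null(geno$W)) {
      if (!is.null(qc)) geno <- qc_filter(geno, qc)
      geno <- standardize(geno)
    }
    return(geno)
  }
  G <- as.matrix(geno)
  ok <- G[!is.na(G)]
  if (length(ok) && all(ok %in% 0:2)) {
    gd <- new_genotype_data(
      matrix(as.integer(G), nrow(G), ncol(G)),
      snp_ids = colnames(G) %||% sprintf("snp%06d", seq_len(ncol(G))),
      chrom = rep(1L, ncol(G)), pos = seq_len(ncol(G)),
      alleles = cbind(A1 = rep("A", ncol(G)), A2 = rep("B", ncol(G))),
      sample_ids = rownames(G) %||% sprintf("ind%06d", seq_len(nrow(G))))
    if (!is.null(qc)) gd <- qc_filter(gd, qc)
    return(standardize(gd))
  }
  # already-standardized numeric matrix: wrap without QC
  list(W = G,
       snp_ids = colnames(G) %||% sprintf("snp%06d", seq_len(ncol(G))),
       sample_ids = rownames(G) %||% sprintf("ind%06d", seq_len(nrow(G))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage-2 estimation on half-2 rows and a given SNP index set.
.stage2_estimates <- function(y, W, half2, M_hat, config, boot_seed = 1L) {
  if (length(M_hat) == 0L) {
    clip <- clip_h2(0)
    empty_fixed <- structure(list(tau2_hat = NA_real_, sigma_e2_hat = NA_real_,
                                  h2_raw = NA_real_, h2 = clip$h2,
                                  clipped = TRUE, d1 = NA, d2 = NA,
                                  m2 = length(half2), n_hat = 0L,
                                  formula = config$mom_formula, se = NA_real_),
                             class = "fixed_varest")
    empty_rand <- structure(list(sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                                 h2_raw = NA_real_, h2 = clip$h2,
                                 clipped = TRUE, se = NA_real_,
                                 loglik = NA_real_, converged = NA,
                                 n_iter = 0L, info_inv = NULL),
                            class = "random_varest")
    return(list(fixed = empty_fixed, random = empty_rand))
  }
  y2 <- y[half2]
  W2 <- W[half2, M_hat, drop = FALSE]
  fixed <- mom_estimate(y2, W2, formula = config$mom_formula)
  if (config$n_boot > 0)
    fixed$se <- fixed_se(y2, W2, n_boot = config$n_boot, seed = boot_seed,
                         formula = config$mom_formula)
  random <- reml_fit(y2, build_grm(W2))
  list(fixed = fixed, random = random)
}

#' @export
print.sparseherit <- function(x, ...) {
  cat("Two-stage SNP-heritability fit\n")
  cat(sprintf("  cohort: %d individuals x %d SNPs; halves of %d / %d\n",
              x$m, x$n, length(x$split$half1), length(x$split$half2)))
  cat(sprintf("  stage 1: %d SNPs selected (alpha = %g, lambda = %.4g)%s\n",
              x$selection$n_hat, x$selection$cv_path$chosen_alpha,
              x$selection$cv_path$chosen_lambda,
              if (x$empty_selection) " [empty]" else ""))
  cat(sprintf("  h2 (random-effect, REML):        %.4f%s%s\n", x$random$h2,
              if (is.na(x$random$se)) "" else sprintf(" (SE %.4f)", x$random$se),
              if (isTRUE(x$random$clipped)) " [clipped]" else ""))
  cat(sprintf("  h2 (fixed-effect, moments):      %.4f%s%s\n", x$fixed$h2,
              if (is.na(x$fixed$se)) "" else sprintf(" (SE %.4f)", x$fixed$se),
              if (isTRUE(x$fixed$clipped)) " [clipped]" else ""))
  invisible(x)
}

#' Summarize a two-stage heritability fit
#' @param object a `"sparseherit"` fit.
#' @param ... unused.
#' @return the fit, invisibly, after printing selection and both variance
#'   estimates.
#' @export
summary.sparseherit <- function(object, ...) {
  print(object)
  cat("\nSelection stage\n")
  print(object$selection)
  if (!object$empty_selection) {
    cat("\n"); print(object$fixed)
    cat("\n"); print(object$random)
  }
  invisible(object)
}

#' Coefficients of the selection stage
#' @param object a `"sparseherit"` fit.
#' @param ... unused.
#' @return the full-length elastic-net coefficient vector (named by SNP id
#'   when available).
#' @export
coef.sparseherit <- function(object, ...) {
  u <- object$selection$u_hat
  if (!is.null(object$snp_ids) && length(object$snp_ids) == length(u))
    names(u) <- object$snp_ids
  u
}

#' Predicted genetic values
#' @param object a `"sparseherit"` fit.
#' @param newdata standardized genotype matrix (or `"genotype_data"` with
#'   `W`) whose columns match the fit.
#' @param ... unused.
#' @return numeric vector of genetic values `W u_hat`.
#' @export
predict.sparseherit <- function(object, newdata, ...) {
  W <- if (inherits(newdata, "genotype_data")) newdata$W else as.matrix(newdata)
  stopifnot(ncol(W) == length(object$selection$u_hat))
  as.numeric(W %*% object$selection$u_hat)
}

#' Plot the cross-validation paths of a fit
#'
#' Mean held-out MSE with one-standard-error bars against `log10(lambda)`,
#' one curve per mixing weight alpha; the chosen `(alpha, lambda)` is marked.
#'
#' @param x a `"sparseherit"` fit or a `"cv_path"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sparseherit <- function(x, ...) plot(x$selection$cv_path, ...)

#' @rdname plot.sparseherit
#' @export
plot.cv_path <- function(x, ...) {
  path <- x$path
  alphas <- unique(path$alpha)
  cols <- seq_along(alphas)
  graphics::plot(NA, xlim = range(log10(path$lambda)),
                 ylim = range(c(path$mse - path$se, path$mse + path$se)),
                 xlab = expression(log[10](lambda)), ylab = "CV MSE", ...)
  for (i in seq_along(alphas)) {
    sub <- path[path$alpha == alphas[i], ]
    graphics::lines(log10(sub$lambda), sub$mse, col = cols[i])
    graphics::segments(log10(sub$lambda), sub$mse - sub$se,
                       log10(sub$lambda), sub$mse + sub$se,
                       col = grDevices::adjustcolor(cols[i], 0.3))
  }
  graphics::abline(v = log10(x$chosen_lambda), lty = 2)
  graphics::legend("topleft", legend = sprintf("alpha = %g", alphas),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Residuals of the selection-stage model
#' @param object a `"sparseherit"` fit.
#' @param geno,y the genotype data and phenotype the model was fit to.
#' @param ... unused.
#' @return residual vector `y - W u_hat`.
#' @export
residuals.sparseherit <- function(object, geno, y, ...) {
  y - predict(object, geno)
}
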