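#' Define a simulation scenario
#'
#' Bundles the parameters of one simulated cohort: `m` individuals genotyped
#' at `n` biallelic SNPs, of which `s` carry nonzero effects (the sparsity
#' level is `s/n`), with residual variance `sigma_e2`. Genotypes follow
#' Hardy-Weinberg proportions at allele frequencies drawn uniformly from
#' `maf_range`, and consecutive SNPs within blocks of `ld_block_size` are in
#' linkage disequilibrium governed by the latent correlation `ld_rho`.
#'
#' @param m number of individuals.
#' @param n number of SNPs.
#' @param s number of causal SNPs (`1 <= s <= n`).
#' @param sigma_e2 residual variance of the phenotype (> 0).
#' @param maf_range length-2 vector of allele-frequency bounds in (0, 0.5].
#' @param ld_block_size number of consecutive SNPs per LD block.
#' @param ld_rho within-block latent AR(1) correlation in [0, 1).
#' @param seed RNG seed making the cohort reproducible.
#' @return an object of class `"sim_scenario"`.
#' @examples
#' sc <- sim_scenario(m = 200, n = 100, s = 5, seed = 1)
#' @export
sim_scenario <- function(m, n, s, sigma_e2 = 1,
                         maf_range = c(0.05, 0.5),
                         ld_block_size = 100, ld_rho = 0.5,
                         seed = 1L) {
  stopifnot(m >= 1, n >= 1)
  if (s < 1 || s > n) stop("'s' must satisfy 1 <= s <= n")
  if (sigma_e2 <= 0) stop("'sigma_e2' must be positive")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("'maf_range' must be ordered bounds within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  if (ld_block_size < 1) stop("'ld_block_size' must be >= 1")
  structure(list(m = as.integer(m), n = as.integer(n), s = as.integer(s),
                 sigma_e2 = sigma_e2, maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: m=%d individuals, n=%d SNPs, s=%d causal (gamma=%.3g)\n",
    x$m, x$n, x$s, x$s / x$n))
  cat(sprintf("  sigma_e2=%g, MAF ~ U(%g, %g), LD blocks of %d at rho=%g, seed=%d\n",
              x$sigma_e2, x$maf_range[1], x$maf_range[2],
              x$ld_block_size, x$ld_rho, x$seed))
  invisible(x)
}

#' Simulate genotype counts under HWE with block LD
#'
#' Draws an `m x n` matrix of minor-allele counts in \{0, 1, 2\}. Each SNP's
#' allele frequency is uniform on `maf_range`. Within each block of
#' `ld_block_size` consecutive SNPs, two latent Gaussian haplotype processes
#' per individual follow an AR(1) correlation `ld_rho` across SNPs; each is
#' thresholded at the quantile matching the SNP's allele frequency and the
#' two carrier indicators are summed. Marginal genotype frequencies therefore
#' follow Hardy-Weinberg proportions while adjacent SNPs are correlated.
#'
#' @param scenario a [sim_scenario()] object.
#' @return a `"genotype_data"` object (see [read_plink()]) with the count
#'   matrix `Z`, per-SNP metadata and the true allele frequencies in
#'   `p_true`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  m <- scenario$m; n <- scenario$n
  with_seed(scenario$seed, {
    p <- runif(n, scenario$maf_range[1], scenario$maf_range[2])
    thr <- qnorm(1 - p)               # latent > thr  <=>  carries the allele
    Z <- matrix(0L, m, n)
    rho <- scenario$ld_rho
    starts <- seq(1L, n, by = scenario$ld_block_size)
    for (b in starts) {
      cols <- b:min(b + scenario$ld_block_size - 1L, n)
      nb <- length(cols)
      for (hap in 1:2) {
        L <- matrix(rnorm(m * nb), m, nb)
        if (rho > 0 && nb > 1) {
          w <- sqrt(1 - rho^2)
          for (j in 2:nb) L[, j] <- rho * L[, j - 1] + w * L[, j]
        }
        Z[, cols] <- Z[, cols] +
          (L > matrix(thr[cols], m, nb, byrow = TRUE))
      }
    }
    new_genotype_data(
      Z = Z,
      snp_ids = sprintf("snp%06d", seq_len(n)),
      chrom = rep(1L, n),
      pos = seq_len(n),
      alleles = cbind(A1 = rep("A", n), A2 = rep("B", n)),
      sample_ids = sprintf("ind%06d", seq_len(m)),
      p_true = p)
  })
}

#' Simulate a sparse SNP-effect vector
#'
#' Picks `s` of `n` SNP indices uniformly at random (without replacement) and
#' assigns them independent Gaussian effects with mean 0 and variance `1/s`,
#' so the total genetic variance of standardized independent SNPs is 1 in
#' expectation regardless of the sparsity level.
#'
#' @param n total number of SNPs.
#' @param s number of causal SNPs.
#' @param seed RNG seed.
#' @param sigma_e2 residual variance recorded in the returned truth object.
#' @return an object of class `"true_model"` with elements `u_star` (length
#'   `n`), `M0` (sorted causal indices), `s`, `sigma_u2 = 1/s`, `sigma_e2`,
#'   and `h_tilde` (`NA` until filled by [approx_true_h2()]).
#' @export
simulate_effects <- function(n, s, seed = 1L, sigma_e2 = 1) {
  if (s < 1 || s > n) stop("'s' must satisfy 1 <= s <= n")
  with_seed(seed, {
    idx <- sort(sample.int(n, s))
    u <- numeric(n)
    u[idx] <- rnorm(s, 0, sqrt(1 / s))
    structure(list(u_star = u, M0 = idx, s = as.integer(s),
                   sigma_u2 = 1 / s, sigma_e2 = sigma_e2, h_tilde = NA_real_),
              class = "true_model")
  })
}

#' Simulate a phenotype from standardized genotypes
#'
#' Forms `y = W u* + e` with `e ~ N(0, sigma_e2 I)`.
#'
#' @param W standardized genotype matrix (`m x n`).
#' @param true_model a `"true_model"` object (or any list with `u_star` and
#'   `sigma_e2`).
#' @param seed RNG seed for the noise draw.
#' @param sigma_e2 residual variance; defaults to the truth object's value.
#' @return numeric phenotype vector of length `m`.
#' @export
simulate_phenotype <- function(W, true_model, seed = 1L,
                               sigma_e2 = true_model$sigma_e2) {
  if (ncol(W) != length(true_model$u_star))
    stop("column count of W must equal length of u_star")
  g <- as.numeric(W %*% true_model$u_star)
  with_seed(seed, g + rnorm(nrow(W), 0, sqrt(sigma_e2)))
}

#' Approximate the true heritability of a simulated cohort
#'
#' The realized genetic values `g = W u*` give the sample genetic variance
#' `|g|^2 / m`; the approximated true heritability is its share of the total
#' `|g|^2/m + sigma_e2`. Its replicate-to-replicate spread is negligible at
#' the cohort sizes used here, so it serves as the per-replicate truth.
#'
#' @param W standardized genotype matrix.
#' @param u_star effect vector.
#' @param sigma_e2 residual variance (> 0).
#' @return heritability value in [0, 1).
#' @export
approx_true_h2 <- function(W, u_star, sigma_e2) {
  stopifnot(sigma_e2 > 0, ncol(W) == length(u_star))
  vg <- sum(as.numeric(W %*% u_star)^2) / nrow(W)
  vg / (vg + sigma_e2)
}

#' Simulate a complete cohort (genotypes, effects, phenotype, truth)
#'
#' Convenience wrapper chaining [simulate_genotypes()], [standardize()],
#' [simulate_effects()], [simulate_phenotype()] and [approx_true_h2()].
#' Sub-seeds for the three random draws are derived from `scenario$seed`.
#'
#' @param scenario a [sim_scenario()] object.
#' @return list with `data` (standardized `"genotype_data"`), `truth`
#'   (a `"true_model"` with `h_tilde` filled in) and `y` (phenotype vector).
#' @export
simulate_cohort <- function(scenario) {
  seeds <- derive_seeds(scenario$seed, 3L)
  geno_scenario <- scenario
  geno_scenario$seed <- seeds[1]
  data <- simulate_genotypes(geno_scenario)
  data <- standardize(data)
  truth <- simulate_effects(scenario$n, scenario$s, seed = seeds[2],
                            sigma_e2 = scenario$sigma_e2)
  y <- simulate_phenotype(data$W, truth, seed = seeds[3])
  truth$h_tilde <- approx_true_h2(data$W, truth$u_star, scenario$sigma_e2)
  list(data = data, truth = truth, y = y, scenario = scenario)
}
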