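#' Run the two-stage pipeline on prepared data
#'
#' Thin functional wrapper around [sparseherit()] for use in scripted
#' pipelines; identical computation and return value.
#'
#' @param data a `"genotype_data"` object (standardized or raw counts).
#' @param y phenotype vector.
#' @param config an [sh_config()].
#' @param seed RNG seed for split, folds and bootstrap.
#' @param covar optional covariates.
#' @return a `"sparseherit"` fit.
#' @export
run_two_stage <- function(data, y, config = sh_config(), seed = 1L,
                          covar = NULL) {
  sparseherit(data, y, covar = covar, config = config, seed = seed)
}

# Test hook: the anti-pattern of estimating variance on the same half that
# selected the model, used to demonstrate overestimation. Not exported.
.two_stage_train_eval <- function(data, y, config = sh_config(n_boot = 0L),
                                  seed = 1L) {
  W <- data$W
  seeds <- derive_seeds(seed, 3L)
  split <- split_sample(nrow(W), seed = seeds[1])
  cfg1 <- config$enet
  cfg1$cv_seed <- seeds[2]
  sel <- select_model(W[split$half1, , drop = FALSE], y[split$half1], cfg1)
  val <- .stage2_estimates(y, W, split$half2, sel$M_hat, config, seeds[3])
  train <- .stage2_estimates(y, W, split$half1, sel$M_hat, config, seeds[3])
  list(selection = sel, validation = val, training = train)
}

#' Estimate heritability under one analysis variant
#'
#' The figure-style baselines: `"full"` skips selection and estimates on all
#' SNPs, `"oracle"` uses the true causal set, `"two_stage"` runs the complete
#' selection-then-estimation strategy. All variants use the same sample
#' split and estimate only on half 2, so variance comparisons are fair.
#'
#' @param data standardized `"genotype_data"`.
#' @param y phenotype vector.
#' @param variant one of `"two_stage"`, `"full"`, `"oracle"`.
#' @param truth a `"true_model"` (required for `"oracle"`).
#' @param config an [sh_config()]; the bootstrap is typically disabled in
#'   replicate studies.
#' @param seed RNG seed.
#' @return list with `fixed`, `random`, `n_hat`, `variant`.
#' @export
run_variant <- function(data, y, variant = c("two_stage", "full", "oracle"),
                        truth = NULL, config = sh_config(n_boot = 0L),
                        seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "two_stage") {
    fit <- sparseherit(data, y, config = config, seed = seed)
    return(list(fixed = fit$fixed, random = fit$random,
                n_hat = fit$selection$n_hat, variant = variant))
  }
  if (variant == "oracle" && is.null(truth))
    stop("the oracle variant needs the true model")
  W <- data$W
  seeds <- derive_seeds(seed, 3L)
  split <- split_sample(nrow(W), seed = seeds[1])
  M <- if (variant == "full") seq_len(ncol(W)) else truth$M0
  est <- .stage2_estimates(y, W, split$half2, M, config, seeds[3])
  list(fixed = est$fixed, random = est$random, n_hat = length(M),
       variant = variant)
}

#' Replicate experiment over one simulation scenario
#'
#' Simulates `n_replicates` independent cohorts from `scenario` (each with
#' its own substream seed derived from `master_seed`) and estimates
#' heritability under each requested variant. Per-replicate failures are
#' recorded rather than fatal, up to a 20\% cap.
#'
#' @param scenario a [sim_scenario()].
#' @param variants subset of `c("two_stage", "full", "oracle")`.
#' @param n_replicates number of replicates (>= 2).
#' @param master_seed master seed spawning per-replicate substreams.
#' @param config an [sh_config()] (bootstrap disabled by default here).
#' @return object of class `"herit_experiment"`: `replicates` data.frame
#'   with one row per replicate x variant (columns replicate, variant,
#'   h_tilde, h2_fixed, h2_rand, n_hat, clipped_fixed, clipped_rand), and
#'   `summary` with mean, SD and first/third quartiles per variant and
#'   estimator.
#' @export
run_experiment <- function(scenario, variants = c("two_stage", "full", "oracle"),
                           n_replicates = 30L, master_seed = 1L,
                           config = sh_config(n_boot = 0L)) {
  stopifnot(n_replicates >= 2)
  variants <- match.arg(variants, several.ok = TRUE)
  seeds <- derive_seeds(master_seed, n_replicates)
  rows <- vector("list", n_replicates * length(variants))
  k <- 0L; n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    sc <- scenario
    sc$seed <- seeds[r]
    cohort <- tryCatch(simulate_cohort(sc), error = function(e) e)
    for (v in variants) {
      k <- k + 1L
      res <- if (inherits(cohort, "error")) cohort else
        tryCatch(run_variant(cohort$data, cohort$y, v, truth = cohort$truth,
                             config = config, seed = seeds[r]),
                 error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        if (n_fail > 0.2 * n_replicates * length(variants))
          stop("more than 20% of replicate runs failed; last error: ",
               conditionMessage(res))
        rows[[k]] <- data.frame(replicate = r, variant = v, h_tilde = NA,
                                h2_fixed = NA, h2_rand = NA, n_hat = NA,
                                clipped_fixed = NA, clipped_rand = NA,
                                error = conditionMessage(res))
        next
      }
      rows[[k]] <- data.frame(replicate = r, variant = v,
                              h_tilde = cohort$truth$h_tilde,
                              h2_fixed = res$fixed$h2, h2_rand = res$random$h2,
                              n_hat = res$n_hat,
                              clipped_fixed = res$fixed$clipped,
                              clipped_rand = res$random$clipped,
                              error = NA_character_)
    }
  }
  reps <- do.call(rbind, rows)
  structure(list(scenario = scenario, n_replicates = as.integer(n_replicates),
                 variants = variants, replicates = reps,
                 summary = .summarize_experiment(reps),
                 master_seed = as.integer(master_seed), schema = "sparseherit-exp/1"),
            class = "herit_experiment")
}

.summarize_experiment <- function(reps) {
  out <- list()
  for (v in unique(reps$variant)) {
    sub <- reps[reps$variant == v & is.na(reps$error), ]
    for (est in c("h2_fixed", "h2_rand", "h_tilde")) {
      x <- sub[[est]]
      out[[length(out) + 1L]] <- data.frame(
        variant = v, estimator = est, n = length(x),
        mean = mean(x), sd = sd(x),
        q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
    }
  }
  do.call(rbind, out)
}

#' @export
print.herit_experiment <- function(x, ...) {
  cat(sprintf("Replicate experiment: %d replicates of (m=%d, n=%d, s=%d, sigma_e2=%g)\n",
              x$n_replicates, x$scenario$m, x$scenario$n, x$scenario$s,
              x$scenario$sigma_e2))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Simulation-scenario presets for the figure-style experiments
#'
#' Named grids of scenarios mirroring the package's simulation study: `fig2a`
#' varies the noise level with all SNPs causal, `fig2b` the sample size,
#' `fig2c` the SNP count, `fig2d` the number of causal SNPs, and `fig3a`-`fig3d`
#' exercise the two-stage strategy at sparsity s = 10, 100, 1000, 10000.
#' Desk-scale presets cap n at 10000 and the fig2b sample sizes at 1000;
#' `full_scale = TRUE` restores n = 100000 and m up to 3000.
#'
#' @param name preset name.
#' @param full_scale use the full-size grids.
#' @return list of [sim_scenario()] objects.
#' @export
scenario_preset <- function(name = c("fig2a", "fig2b", "fig2c", "fig2d",
                                     "fig3a", "fig3b", "fig3c", "fig3d"),
                            full_scale = FALSE) {
  name <- match.arg(name)
  n_big <- if (full_scale) 100000L else 10000L
  sc <- function(m, n, s, sigma_e2 = 1) sim_scenario(m, n, s, sigma_e2)
  switch(name,
    fig2a = lapply(c(4, 1, 0.25), function(v) sc(1000, 10000, 10000, v)),
    fig2b = lapply(if (full_scale) c(300, 1000, 3000) else c(300, 1000),
                   function(m) sc(m, 10000, 10000)),
    fig2c = lapply(c(1000, 3000, 10000), function(n) sc(1000, n, n)),
    fig2d = lapply(c(100, 1000, 10000), function(s) sc(1000, 10000, s)),
    fig3a = list(sc(1000, n_big, 10)),
    fig3b = list(sc(1000, n_big, 100)),
    fig3c = list(sc(1000, n_big, 1000)),
    fig3d = list(sc(1000, n_big, min(10000L, n_big))))
}

#' Write a fit or experiment to disk
#'
#' Experiments produce `<prefix>.replicates.tsv` and `<prefix>.summary.json`;
#' fits produce `<prefix>.report.json` and a `<prefix>.selected.tsv` table of
#' selected SNPs. Files round-trip through [read_report()].
#'
#' @param x a `"sparseherit"` fit or `"herit_experiment"`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_report <- function(x, prefix) {
  if (inherits(x, "herit_experiment")) {
    write.table(x$replicates, paste0(prefix, ".replicates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(schema = x$schema,
           scenario = unclass(x$scenario), n_replicates = x$n_replicates,
           variants = x$variants, master_seed = x$master_seed,
           summary = x$summary),
      paste0(prefix, ".summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "sparseherit")) {
    sel <- x$selection
    ids <- if (is.null(x$snp_ids)) sprintf("snp%06d", seq_along(sel$u_hat))
           else x$snp_ids
    tab <- data.frame(snp_id = ids[sel$M_hat], u_hat = sel$u_hat[sel$M_hat])
    write.table(tab, paste0(prefix, ".selected.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(schema = "sparseherit-fit/1", m = x$m, n = x$n, seed = x$seed,
           n_hat = sel$n_hat, chosen_alpha = sel$cv_path$chosen_alpha,
           chosen_lambda = sel$cv_path$chosen_lambda,
           empty_selection = x$empty_selection,
           fixed = x$fixed[c("tau2_hat", "sigma_e2_hat", "h2_raw", "h2",
                             "clipped", "se", "d1", "d2", "m2", "n_hat")],
           random = x$random[c("sigma_g2", "sigma_e2", "h2_raw", "h2",
                               "clipped", "se", "loglik")]),
      paste0(prefix, ".report.json"), auto_unbox = TRUE, digits = NA)
  } else stop("write_report handles 'sparseherit' and 'herit_experiment' objects")
  invisible(prefix)
}

#' Read back a written report
#' @param prefix the prefix given to [write_report()].
#' @return a list with the parsed JSON (`summary` or `report`) and, for
#'   experiments, the `replicates` data.frame.
#' @export
read_report <- function(prefix) {
  if (file.exists(paste0(prefix, ".summary.json"))) {
    list(summary = jsonlite::read_json(paste0(prefix, ".summary.json"),
                                       simplifyVector = TRUE),
         replicates = read.table(paste0(prefix, ".replicates.tsv"),
                                 header = TRUE, sep = "\t"))
  } else if (file.exists(paste0(prefix, ".report.json"))) {
    list(report = jsonlite::read_json(paste0(prefix, ".report.json"),
                                      simplifyVector = TRUE),
         selected = read.table(paste0(prefix, ".selected.tsv"),
                               header = TRUE, sep = "\t"))
  } else stop("no report found at prefix ", prefix)
}
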