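test_that("sample splitting gives disjoint, exhaustive, near-equal halves", {
  sp <- split_sample(1000, seed = 3)
  expect_length(sp$half1, 500)
  expect_length(sp$half2, 500)
  expect_length(intersect(sp$half1, sp$half2), 0)
  expect_setequal(c(sp$half1, sp$half2), 1:1000)

  sp7 <- split_sample(7, seed = 1)
  expect_equal(sort(c(length(sp7$half1), length(sp7$half2))), c(3, 4))

  expect_identical(split_sample(100, seed = 9), split_sample(100, seed = 9))
  expect_error(split_sample(3), "at least 4")
})

test_that("lambda grid is geometric, descending, and scales as 1/alpha", {
  # single column with max absolute score 2 at alpha = 1
  m <- 4
  W <- matrix(1, m, 1)
  y <- rep(2, m)                      # (1/m) |w'y| = 2
  g <- lambda_grid(W, y, alpha = 1, n_lambda = 3, lambda_min_ratio = 0.01)
  expect_equal(g, c(2, 0.2, 0.02))
  g2 <- lambda_grid(W, y, alpha = 0.5, n_lambda = 3, lambda_min_ratio = 0.01)
  expect_equal(g2[1], 4)              # lambda_max doubles at alpha = 0.5
  expect_true(all(diff(g2) < 0))
  expect_error(lambda_grid(W, rep(0, m), 1), "degenerate")
})

test_that("elastic-net fits reproduce single-predictor closed forms exactly", {
  # standardized predictor with (1/m) w'y = 2, (1/m) w'w = 1
  m <- 8
  w <- rep(c(1, -1), m / 2)
  y <- 2 * w
  # alpha = 1, lambda = 0.5: soft threshold S(2, 0.5) = 1.5
  expect_equal(fit_elastic_net(cbind(w), y, alpha = 1, lambda = 0.5), 1.5)
  # alpha = 0.5, lambda = 1: S(2, 0.5) / (1 + 0.5) = 1.0
  expect_equal(fit_elastic_net(cbind(w), y, alpha = 0.5, lambda = 1), 1.0)
})

test_that("penalties at or above lambda_max give the all-zero solution", {
  W <- rand_design(50, 20, seed = 13)
  y <- with_seed_test(14, rnorm(50))
  lmax <- max(abs(crossprod(W, y))) / (50 * 0.7)
  expect_identical(fit_elastic_net(W, y, 0.7, lmax), numeric(20))
  expect_identical(fit_elastic_net(W, y, 0.7, lmax * 2), numeric(20))
})

test_that("returned fits satisfy the KKT conditions and beat the zero vector", {
  set.seed(17)
  for (case in 1:4) {
    m <- sample(30:60, 1); p <- sample(10:80, 1)
    alpha <- sample(c(0.2, 0.5, 1), 1)
    W <- matrix(rnorm(m * p), m, p)
    b <- numeric(p); b[sample(p, 3)] <- rnorm(3)
    y <- as.numeric(W %*% b) + rnorm(m)
    lam <- 0.3 * max(abs(crossprod(W, y))) / (m * alpha)
    u <- fit_elastic_net(W, y, alpha, lam)
    expect_lt(enet_kkt_residual(W, y, u, alpha, lam), 1e-6)
    expect_lte(enet_objective(W, y, u, alpha, lam),
               enet_objective(W, y, numeric(p), alpha, lam))
  }
})

test_that("path fits agree with an independent coordinate-descent oracle", {
  set.seed(19)
  m <- 40; p <- 12
  W <- matrix(rnorm(m * p), m, p)
  y <- as.numeric(W[, 1] - W[, 5]) + rnorm(m, 0, 0.5)
  for (alpha in c(0.4, 1)) {
    lam <- 0.2 * max(abs(crossprod(W, y))) / (m * alpha)
    u_pkg <- fit_elastic_net(W, y, alpha, lam)
    u_ora <- enet_cd_oracle(W, y, alpha, lam)
    expect_equal(enet_objective(W, y, u_pkg, alpha, lam),
                 enet_objective(W, y, u_ora, alpha, lam), tolerance = 1e-8)
    expect_equal(u_pkg, u_ora, tolerance = 1e-4)
  }
})

test_that("the one-standard-error rule picks the documented lambda", {
  one_se <- sparseherit:::.one_se_choose
  # mean MSEs (1.0, 0.8, 0.79) at lambdas (1, 0.5, 0.1), all SEs 0.05:
  # threshold 0.84 -> largest lambda within it is 0.5
  expect_equal(one_se(c(1, 0.5, 0.1), c(1.0, 0.8, 0.79), rep(0.05, 3),
                      "sparse"), 2)
  # all equal -> sparsest (largest) lambda
  expect_equal(one_se(c(1, 0.5, 0.1), rep(1, 3), rep(0.01, 3), "sparse"), 1)
  # minimum at the largest lambda -> that lambda
  expect_equal(one_se(c(1, 0.5, 0.1), c(0.5, 0.8, 0.9), rep(0.01, 3),
                      "sparse"), 1)
  # literal 'dense' reading: smallest lambda within one SE
  expect_equal(one_se(c(1, 0.5, 0.1), c(1.0, 0.8, 0.79), rep(0.05, 3),
                      "dense"), 3)
})

test_that("cross-validation is reproducible and its folds balanced", {
  W <- rand_design(60, 40, seed = 23)
  y <- as.numeric(W[, 1] * 0.8) + with_seed_test(24, rnorm(60))
  cfg <- enet_config(alpha_grid = c(0.5, 1), n_lambda = 20, n_folds = 5,
                     cv_seed = 7)
  cv1 <- cross_validate(W, y, cfg)
  cv2 <- cross_validate(W, y, cfg)
  expect_identical(cv1, cv2)
  expect_true(cv1$chosen_alpha %in% c(0.5, 1))
  expect_true(cv1$chosen_lambda %in% cv1$path$lambda)
  expect_true(all(cv1$path$se >= 0))
  folds <- sparseherit:::.cv_folds(60, 7, seed = 1)
  expect_lte(diff(range(lengths(folds))), 1)
  expect_setequal(unlist(folds), 1:60)
})

test_that("strong sparse signals are recovered and support shrinks along the path", {
  # noiseless response from 5 strong causal SNPs: selection must cover them
  hits <- vapply(1:10, function(r) {
    W <- rand_design(80, 40, seed = 300 + r)
    idx <- 1:5
    y <- as.numeric(W[, idx] %*% rep(2, 5)) + with_seed_test(400 + r, rnorm(80, 0, 0.01))
    sel <- select_model(W, y, enet_config(alpha_grid = c(0.9, 1),
                                          n_lambda = 40, n_folds = 5,
                                          cv_seed = r))
    all(idx %in% sel$M_hat)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # support size is weakly decreasing in lambda at fixed alpha
  W <- rand_design(50, 30, seed = 29)
  y <- as.numeric(W[, 1:3] %*% c(1, -1, 0.5)) + with_seed_test(30, rnorm(50, 0, 0.3))
  lams <- lambda_grid(W, y, 1, n_lambda = 12, lambda_min_ratio = 0.01)
  sizes <- vapply(lams, function(l) sum(fit_elastic_net(W, y, 1, l) != 0),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))   # lams descend, so sizes ascend
})

test_that("pure-noise responses under heavy penalties yield a flagged empty selection", {
  W <- rand_design(40, 25, seed = 33)
  y <- with_seed_test(34, rnorm(40))
  # a grid compressed near lambda_max keeps every model empty
  sel <- select_model(W, y, enet_config(alpha_grid = 1, n_lambda = 5,
                                        lambda_min_ratio = 0.999,
                                        n_folds = 5, cv_seed = 2,
                                        one_se_direction = "sparse"))
  expect_true(sel$empty)
  expect_identical(sel$n_hat, 0L)
})
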