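test_that("PLINK bed/bim/fam writing and reading are mutually inverse", {
  set.seed(31)
  Z <- matrix(sample(c(0:2, NA), 23 * 7, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 23, 7)
  g <- make_geno(Z)
  prefix <- file.path(tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_identical(g2$Z, g$Z)
  expect_identical(g2$snp_ids, g$snp_ids)
  expect_identical(g2$sample_ids, g$sample_ids)
  # a second write reproduces the .bed byte-for-byte
  write_plink(g2, paste0(prefix, "_b"))
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 10000),
                   readBin(paste0(prefix, "_b.bed"), "raw", 10000))
})

test_that("bed decoding matches a hand-encoded 2-bit fixture", {
  # 3 samples, 2 SNPs. SNP-major; 2 bits per sample, LSB first.
  # SNP1: sample codes (00, 10, 11) = hom A1, het, hom A2 -> Z = (2, 1, 0)
  #   byte = 00 | 10<<2 | 11<<4 = 0x38
  # SNP2: (01, 00, 10) = missing, hom A1, het -> Z = (NA, 2, 1)
  #   byte = 01 | 00<<2 | 10<<4 = 0x21
  prefix <- file.path(tempdir(), "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x21)), paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("f%d\ti%d\t0\t0\t0\t-9", 1:3, 1:3), paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_identical(g$Z[, 1], c(2L, 1L, 0L))
  expect_identical(g$Z[, 2], c(NA_integer_, 2L, 1L))
  expect_identical(g$snp_ids, c("rs1", "rs2"))
})

test_that("malformed bed files are rejected with a located error", {
  prefix <- file.path(tempdir(), "bad")
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines("f1\ti1\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic.*offset 0")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "mode byte")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "truncated")
})

test_that("phenotype and covariate readers tolerate optional headers", {
  f <- tempfile()
  writeLines(c("FID IID pheno", "f1 i1 1.5", "f2 i2 -0.25"), f)
  ph <- read_pheno(f)
  expect_equal(ph$VALUE, c(1.5, -0.25))
  writeLines(c("f1 i1 1.5 2", "f2 i2 -0.25 3"), f)
  cv <- read_covar(f)
  expect_equal(cv$C1, c(1.5, -0.25))
  expect_equal(cv$C2, c(2, 3))
})

test_that("Hardy-Weinberg exact test matches a direct enumeration oracle", {
  # independent oracle: conditional probability of each heterozygote count
  # given allele counts, computed with choose() products
  hwe_oracle <- function(het, hom_r, hom_c) {
    n <- het + hom_r + hom_c
    nr <- 2 * min(hom_r, hom_c) + het
    hvals <- seq(nr %% 2, nr, by = 2)
    pr <- sapply(hvals, function(h) {
      a <- (nr - h) / 2
      exp(h * log(2) + lchoose(n, h) + lchoose(n - h, a))
    })
    # normalize (the constant 2n-choose-nr factor cancels)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[hvals == het] * (1 + 1e-12)])
  }
  cases <- list(c(50, 25, 25), c(10, 1, 89), c(3, 0, 97), c(40, 40, 20),
                c(0, 5, 5), c(7, 2, 11))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  # equilibrium counts are comfortably retained at the 1e-6 threshold
  expect_gt(hwe_exact_test(50, 25, 25), 0.1)
})

test_that("QC filter applies call-rate, MAF and HWE thresholds exactly", {
  set.seed(41)
  m <- 300
  Z <- cbind(
    good = rbinom(m, 2, 0.3),
    rare = c(rep(0L, m - 2), 1L, 1L),        # MAF 1/300 -> fails MAF >= 1%
    sparse = rbinom(m, 2, 0.3),              # will get missing calls
    hwe_bad = c(rep(0L, 150), rep(2L, 150))  # no hets: extreme HWE violation
  )
  Z[sample(m, 9), "sparse"] <- NA            # call rate 0.97 < 0.99
  g <- make_geno(Z, ids = colnames(Z))
  filtered <- qc_filter(g)
  expect_identical(filtered$snp_ids, "good")
  log <- attr(filtered, "qc_log")
  expect_equal(log$fail_call_rate, 1)
  expect_gte(log$fail_maf, 1)
  expect_gte(log$fail_hwe, 1)

  # idempotence
  again <- qc_filter(filtered)
  expect_identical(again$Z, filtered$Z)
  expect_error(qc_filter(g, qc_thresholds(min_maf = 0.49)), "every SNP")
})

test_that("standardization matches the binomial formula and centers exactly", {
  # counts (0,1,2): p-hat = 0.5 -> column (-sqrt2, 0, sqrt2)
  g <- make_geno(cbind(c(0L, 1L, 2L)))
  s <- standardize(g)
  expect_equal(s$W[, 1], c(-sqrt(2), 0, sqrt(2)))
  expect_equal(s$p, 0.5, ignore_attr = TRUE)

  # a single 2 at p = 0.5 standardizes to 1/sqrt(0.5)
  expect_equal((2 - 2 * 0.5) / sqrt(2 * 0.5 * 0.5), sqrt(2))

  expect_error(standardize(make_geno(cbind(c(0L, 0L, 0L)))), "monomorphic")

  # missing -> 0 after standardization, column means exactly 0
  set.seed(5)
  Z <- matrix(rbinom(200 * 10, 2, 0.4), 200, 10)
  Z[sample(length(Z), 50)] <- NA
  s2 <- standardize(make_geno(Z))
  expect_true(all(s2$W[is.na(Z)] == 0))
  expect_lt(max(abs(colMeans(s2$W))), 1e-12 * 200)
})

test_that("covariate projection produces orthogonal residuals and is idempotent", {
  set.seed(6)
  m <- 50
  y <- rnorm(m)
  W <- matrix(rnorm(m * 4), m, 4)
  C <- cbind(1, rnorm(m), rnorm(m))
  pr <- project_covariates(y, W, C)
  expect_lt(max(abs(crossprod(C, pr$y_res))), 1e-10)
  expect_lt(max(abs(crossprod(C, pr$W_res))), 1e-10)
  expect_equal(pr$m_eff, m - 3)
  expect_lte(sqrt(sum(pr$y_res^2)), sqrt(sum(y^2)))
  # idempotent
  pr2 <- project_covariates(pr$y_res, pr$W_res, C)
  expect_equal(pr2$y_res, pr$y_res, tolerance = 1e-12)

  # intercept only = centering; no covariates = identity
  prc <- project_covariates(y, W, cbind(rep(1, m)))
  expect_equal(prc$y_res, y - mean(y))
  pr0 <- project_covariates(y, W, NULL)
  expect_identical(pr0$y_res, y)
  expect_equal(pr0$m_eff, m)

  expect_error(project_covariates(y, W, cbind(1, 1:m, 2 * (1:m))),
               "rank deficient")
})
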