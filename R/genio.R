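#' Construct a genotype_data object
#'
#' Container for raw minor-allele counts plus per-SNP/per-sample metadata.
#' `Z` holds counts of the A1 allele in \{0, 1, 2\} with `NA` for missing
#' calls. After [standardize()] the object additionally carries the sample
#' allele frequencies `p` and the standardized matrix `W`.
#'
#' @param Z integer m x n matrix of A1-allele counts (NA = missing).
#' @param snp_ids,chrom,pos per-SNP identifier, chromosome and position.
#' @param alleles n x 2 character matrix with columns A1, A2.
#' @param sample_ids per-individual identifiers.
#' @param p_true optional true allele frequencies (simulation only).
#' @return object of class `"genotype_data"`.
#' @export
new_genotype_data <- function(Z, snp_ids, chrom, pos, alleles, sample_ids,
                              p_true = NULL) {
  n <- ncol(Z)
  stopifnot(length(snp_ids) == n, length(chrom) == n, length(pos) == n,
            nrow(alleles) == n, length(sample_ids) == nrow(Z))
  ok <- Z[!is.na(Z)]
  if (length(ok) && !all(ok %in% 0:2))
    stop("non-missing genotype counts must lie in {0, 1, 2}")
  structure(list(Z = Z, snp_ids = as.character(snp_ids),
                 chrom = as.integer(chrom), pos = as.integer(pos),
                 alleles = alleles, sample_ids = as.character(sample_ids),
                 p_true = p_true, p = NULL, W = NULL),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("Genotype data: %d individuals x %d SNPs (%s standardized)\n",
              nrow(x$Z), ncol(x$Z), if (is.null(x$W)) "not" else ""))
  miss <- sum(is.na(x$Z))
  if (miss) cat(sprintf("  %d missing calls (%.3g%%)\n",
                        miss, 100 * miss / length(x$Z)))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$Z)

# PLINK 1 .bed 2-bit codes (SNP-major): 00 = hom A1 (count 2), 01 = missing,
# 10 = het, 11 = hom A2 (count 0). Counts are of the .bim A1 allele.
.bed_code_to_count <- c(2L, NA_integer_, 1L, 0L)     # index = code + 1
.bed_count_to_code <- function(z) {                  # inverse map, NA -> 01
  code <- integer(length(z))
  code[is.na(z)] <- 1L
  code[!is.na(z) & z == 2L] <- 0L
  code[!is.na(z) & z == 1L] <- 2L
  code[!is.na(z) & z == 0L] <- 3L
  code
}

# 256 x 4 lookup: byte value -> the four 2-bit codes, sample order = LSB first
.bed_byte_lut <- local({
  b <- 0:255
  cbind(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
        bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L))
})

#' Read a PLINK binary genotype triplet
#'
#' Decodes `<prefix>.bed` (v1.00 magic `0x6c 0x1b`, SNP-major mode byte
#' `0x01`), `<prefix>.bim` and `<prefix>.fam`. Counts are oriented so that
#' `Z` counts copies of the .bim A1 allele; the 2-bit code 01 becomes `NA`.
#'
#' @param prefix path prefix of the .bed/.bim/.fam triplet.
#' @return a `"genotype_data"` object.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "id", "cm", "pos", "A1", "A2"),
                       colClasses = c("integer", "character", "numeric",
                                      "integer", "character", "character"))
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("FID", "IID", "PID", "MID", "sex", "phen"))
  m <- nrow(fam_df); n <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic bytes at offset 0")
  if (raw[3] != as.raw(0x01))
    stop("unsupported .bed mode byte at offset 2 (need SNP-major 0x01)")
  bps <- ceiling(m / 4)                      # bytes per SNP
  if (length(raw) - 3L != bps * n)
    stop(sprintf(".bed truncated: expected %d data bytes, found %d (offset %d)",
                 bps * n, length(raw) - 3L, length(raw)))
  body <- as.integer(raw[-(1:3)]) + 1L
  Z <- matrix(NA_integer_, m, n)
  for (j in seq_len(n)) {
    bytes <- body[((j - 1L) * bps + 1L):(j * bps)]
    codes <- as.vector(t(.bed_byte_lut[bytes, , drop = FALSE]))[seq_len(m)]
    Z[, j] <- .bed_code_to_count[codes + 1L]
  }
  new_genotype_data(Z, snp_ids = bim_df$id, chrom = bim_df$chrom,
                    pos = bim_df$pos,
                    alleles = cbind(A1 = bim_df$A1, A2 = bim_df$A2),
                    sample_ids = fam_df$IID)
}

#' Write a PLINK binary genotype triplet
#'
#' Inverse of [read_plink()]; round-trips \{0, 1, 2, NA\} matrices bit-exactly.
#'
#' @param data a `"genotype_data"` object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_data"))
  Z <- data$Z
  m <- nrow(Z); n <- ncol(Z)
  bim_df <- data.frame(chrom = data$chrom, id = data$snp_ids, cm = 0,
                       pos = data$pos, A1 = data$alleles[, 1],
                       A2 = data$alleles[, 2])
  write.table(bim_df, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam_df <- data.frame(FID = data$sample_ids, IID = data$sample_ids,
                       PID = 0, MID = 0, sex = 0, phen = -9)
  write.table(fam_df, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bps <- ceiling(m / 4)
  pow <- c(1L, 4L, 16L, 64L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bps * 4L - m
  out <- matrix(0L, 4L, bps * n)
  codes <- .bed_count_to_code(as.vector(Z))
  dim(codes) <- c(m, n)
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, n))
  dim(codes) <- c(4L, bps * n)
  bytes <- as.integer(pow %*% codes)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a PLINK-style phenotype file
#'
#' Whitespace-delimited `FID IID VALUE`; a header line is tolerated and
#' detected by a non-numeric third field.
#'
#' @param path phenotype file path.
#' @return data.frame with columns FID, IID, VALUE.
#' @export
read_pheno <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("phenotype file needs at least 3 columns (FID IID VALUE)")
  if (is.na(suppressWarnings(as.numeric(df[1, 3])))) df <- df[-1, , drop = FALSE]
  data.frame(FID = as.character(df[[1]]), IID = as.character(df[[2]]),
             VALUE = as.numeric(df[[3]]), stringsAsFactors = FALSE)
}

#' Write a two-column-id phenotype file
#' @param data a `"genotype_data"` object supplying sample ids.
#' @param y phenotype vector aligned with `data$sample_ids`.
#' @param path output path.
#' @export
write_pheno <- function(data, y, path) {
  stopifnot(length(y) == length(data$sample_ids))
  write.table(data.frame(data$sample_ids, data$sample_ids, y), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a covariate file (FID IID C1..Cq)
#' @param path covariate file path.
#' @return data.frame with FID, IID and numeric covariate columns.
#' @export
read_covar <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("covariate file needs at least 3 columns")
  if (is.na(suppressWarnings(as.numeric(df[1, 3])))) df <- df[-1, , drop = FALSE]
  out <- data.frame(FID = as.character(df[[1]]), IID = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  for (k in 3:ncol(df)) out[[paste0("C", k - 2L)]] <- as.numeric(df[[k]])
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Standard (non-mid) exact test on autosomal genotype counts: the p-value is
#' the total probability, under the conditional distribution of heterozygote
#' counts given allele counts, of all outcomes no more probable than the one
#' observed (the PLINK default).
#'
#' @param n_het heterozygote count.
#' @param n_hom1,n_hom2 the two homozygote counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  n <- n_hom1 + n_hom2 + n_het
  if (n == 0L) return(1)
  # probabilities over all heterozygote counts with n_het's parity
  het_vals <- seq(n_rare %% 2L, n_rare, by = 2L)
  lp <- vapply(het_vals, function(h) {
    r_hom <- (n_rare - h) / 2
    c_hom <- n - h - r_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(r_hom + 1) - lgamma(c_hom + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- which(het_vals == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Quality-control thresholds
#'
#' Defaults follow common GWAS practice: call rate >= 99\%, minor allele
#' frequency >= 1\%, Hardy-Weinberg exact p >= 1e-6.
#'
#' @param min_call_rate minimum fraction of non-missing calls per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum HWE exact-test p-value.
#' @return object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_call_rate = 0.99, min_maf = 0.01,
                          min_hwe_p = 1e-6) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1, min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Filter SNPs on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Retains exactly the SNPs whose call rate, minor allele frequency (computed
#' over non-missing calls) and HWE exact-test p-value all meet the
#' thresholds. Exclusion counts per criterion are attached as the `"qc_log"`
#' attribute.
#'
#' @param data a `"genotype_data"` object.
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `"genotype_data"` (standardization is dropped and
#'   must be redone).
#' @export
qc_filter <- function(data, thresholds = qc_thresholds()) {
  stopifnot(inherits(data, "genotype_data"), inherits(thresholds, "qc_thresholds"))
  Z <- data$Z
  m <- nrow(Z)
  nmiss <- colSums(is.na(Z))
  call_rate <- 1 - nmiss / m
  p_hat <- colMeans(Z, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  hwe_p <- vapply(seq_len(ncol(Z)), function(j) {
    z <- Z[, j][!is.na(Z[, j])]
    hwe_exact_test(sum(z == 1L), sum(z == 0L), sum(z == 2L))
  }, numeric(1))
  pass_cr <- call_rate >= thresholds$min_call_rate
  pass_maf <- !is.nan(maf) & maf >= thresholds$min_maf
  pass_hwe <- hwe_p >= thresholds$min_hwe_p
  keep <- pass_cr & pass_maf & pass_hwe
  if (!any(keep)) stop("QC removed every SNP: no polymorphic panel remains")
  out <- new_genotype_data(Z[, keep, drop = FALSE], data$snp_ids[keep],
                           data$chrom[keep], data$pos[keep],
                           data$alleles[keep, , drop = FALSE],
                           data$sample_ids,
                           p_true = data$p_true[keep])
  attr(out, "qc_log") <- list(n_in = ncol(Z), n_out = sum(keep),
                              fail_call_rate = sum(!pass_cr),
                              fail_maf = sum(!pass_maf),
                              fail_hwe = sum(!pass_hwe))
  out
}

#' Standardize genotype counts to zero mean and unit variance
#'
#' Each column is transformed as `W_ij = (Z_ij - 2 p_j) / sqrt(2 p_j (1 -
#' p_j))` with `p_j` the sample allele frequency over non-missing calls,
#' the binomial standardization of a biallelic SNP under Hardy-Weinberg
#' proportions. Missing cells become 0 on the standardized scale (mean
#' imputation), so every column has mean exactly 0.
#'
#' @param data a `"genotype_data"` object with at least one sample.
#' @return the same object with `p` and `W` filled in.
#' @export
standardize <- function(data) {
  stopifnot(inherits(data, "genotype_data"))
  Z <- data$Z
  p <- colMeans(Z, na.rm = TRUE) / 2
  mono <- which(is.nan(p) | p <= 0 | p >= 1)
  if (length(mono))
    stop("monomorphic SNP(s) cannot be standardized: ",
         paste(data$snp_ids[mono[seq_len(min(5, length(mono)))]], collapse = ", "))
  W <- sweep(Z, 2L, 2 * p, `-`)
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), `/`)
  W[is.na(W)] <- 0
  data$p <- p
  data$W <- W
  data
}

#' Project nuisance covariates out of phenotype and genotypes
#'
#' Replaces `y` and every column of `W` by their residuals after least-squares
#' projection onto the column space of `C`, so downstream estimators see data
#' orthogonal to the covariates. The effective sample size `m - q` is
#' returned for degrees-of-freedom accounting.
#'
#' @param y phenotype vector.
#' @param W standardized genotype matrix (may be `NULL` to project only `y`).
#' @param C `m x q` covariate matrix of full column rank (include an
#'   intercept column explicitly if wanted); `NULL` or zero columns is a
#'   no-op.
#' @return list with `y_res`, `W_res`, `m_eff` and `q`.
#' @export
project_covariates <- function(y, W = NULL, C = NULL) {
  m <- length(y)
  if (is.null(C) || NCOL(C) == 0L)
    return(list(y_res = y, W_res = W, m_eff = m, q = 0L))
  C <- as.matrix(C)
  stopifnot(nrow(C) == m)
  qr_C <- qr(C)
  if (qr_C$rank < ncol(C)) stop("covariate matrix is rank deficient")
  if (ncol(C) >= m) stop("need more samples than covariates")
  list(y_res = as.numeric(qr.resid(qr_C, y)),
       W_res = if (is.null(W)) NULL else qr.resid(qr_C, W),
       m_eff = m - ncol(C), q = ncol(C))
}
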