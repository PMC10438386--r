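make_gm <- function(dos, pos = NULL, chrom = NULL, loc = NULL) {
  L <- ncol(dos)
  genotype_matrix(dos,
                  data.frame(id = sprintf("s%03d", seq_len(L)),
                             chrom = chrom %||% rep("chr1", L),
                             pos = pos %||% (seq_len(L) * 1000L),
                             ref = "A", alt = "T"),
                  data.frame(id = sprintf("i%03d", seq_len(nrow(dos))),
                             locality = loc %||% rep("L1", nrow(dos)),
                             longitude = 0, latitude = 0))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("VCF reading keeps biallelic SNPs, skips others, and reads ./. as missing", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\tsnp2\tG\tC\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t300\tindel1\tGA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t400\tmulti1\tG\tC,T\t.\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t500\tsnp3\tC\tG\t.\tPASS\t.\tGT\t0/1\t1/1"), vcf)
  expect_message(gm <- read_vcf(vcf), "skipped 2")
  expect_equal(dim(gm$dosages), c(2, 3))
  expect_equal(unname(gm$dosages["sampA", ]), c(0, 2, 1))
  expect_true(is.na(gm$dosages["sampB", "snp2"]))
  expect_equal(gm$snp_meta$pos, c(100L, 200L, 500L))
})

test_that("VCF round-trip preserves dosages and site metadata", {
  set.seed(4)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  gm <- make_gm(dos, chrom = rep(c("chr1", "chr2"), each = 6))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path, sample_meta = gm$sample_meta)
  expect_equal(gm2$dosages, gm$dosages, ignore_attr = TRUE)
  expect_equal(gm2$snp_meta$pos, gm$snp_meta$pos)
  expect_equal(gm2$snp_meta$chrom, gm$snp_meta$chrom)
})

test_that("missingness and MAF filtering follow the threshold rules", {
  dos <- rbind(c(NA, 0, 0), c(NA, 0, 1), c(NA, 0, 2),
               c(0, 0, 2), c(1, 0, 1), c(2, 0, 0))
  gm <- make_gm(dos)
  f <- filter_genotypes(gm, max_missing = 0.2, min_maf = 0.01)
  # SNP1: 3/6 missing -> removed; SNP2 monomorphic -> removed; SNP3 kept
  expect_equal(f$report$n_removed_missing, 1L)
  expect_equal(f$report$n_removed_maf, 1L)
  expect_equal(colnames(f$genotypes$dosages), "s003")
  expect_equal(f$report$n_output,
               f$report$n_input - f$report$n_removed_missing -
                 f$report$n_removed_maf - f$report$n_removed_ld)
  expect_error(filter_genotypes(make_gm(matrix(0L, 4, 3))), "review")
})

test_that("filtering matches a brute-force oracle and is idempotent", {
  set.seed(17)
  dos <- matrix(rbinom(50 * 200, 2, rep(runif(200, 0, 0.6), each = 50)), 50, 200)
  dos[matrix(runif(length(dos)) < 0.15, nrow(dos))] <- NA
  gm <- make_gm(dos)
  f <- filter_genotypes(gm, 0.2, 0.05)
  keep <- brute_filter(dos, 0.2, 0.05)
  expect_identical(colnames(f$genotypes$dosages), gm$snp_meta$id[keep])
  f2 <- filter_genotypes(f$genotypes, 0.2, 0.05)
  expect_identical(f2$genotypes$dosages, f$genotypes$dosages)
  expect_equal(f2$report$n_removed_missing + f2$report$n_removed_maf, 0L)
})

test_that("imputation fills from locality frequencies deterministically", {
  dos <- rbind(c(2, 1, NA), c(2, NA, 0), c(2, 1, 1), c(NA, 1, 2))
  gm <- make_gm(dos, loc = c("A", "A", "B", "B"))
  out <- impute_missing(gm, seed = 5)
  expect_false(anyNA(out$dosages))
  expect_equal(out$dosages[4, 1], 2)      # fixed alt -> p-hat = 1
  expect_identical(impute_missing(gm, seed = 5)$dosages, out$dosages)
  gm_full <- make_gm(matrix(1L, 3, 3))
  expect_identical(impute_missing(gm_full, seed = 1), gm_full)
  gm_empty <- make_gm(rbind(c(NA, 1), c(NA, 1)))
  expect_error(impute_missing(gm_empty), "entirely missing")
})

test_that("imputed dosage means track the estimated allele frequency", {
  set.seed(8)
  n <- 40; L <- 30
  p0 <- runif(L, 0.2, 0.8)
  dos <- matrix(rbinom(n * L, 2, rep(p0, each = n)), n, L)
  miss <- matrix(runif(n * L) < 0.5, n, L)
  dosm <- dos; dosm[miss] <- NA
  gm <- make_gm(dosm)
  phat <- colMeans(dosm, na.rm = TRUE) / 2
  # Monte-Carlo over seeds: imputed values are binomial(2, phat) draws
  imp_mean <- rowMeans(sapply(1:30, function(s) {
    out <- impute_missing(gm, mode = "global_frequency", seed = s)$dosages
    vapply(seq_len(L), function(j) mean(out[miss[, j], j]), numeric(1))
  }))
  n_imp <- colSums(miss)
  se <- sqrt(2 * phat * (1 - phat) / (n_imp * 30))
  expect_true(all(abs(imp_mean - 2 * phat) < 3.5 * se + 1e-9))
})

test_that("LD pruning drops later in-window correlated SNPs only", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0)
  dos <- cbind(x, x, x)
  gm <- make_gm(dos, pos = c(1000L, 2000L, 12000L))
  out <- ld_prune(gm, r2_max = 0.5, window_bp = 5000)
  # second removed (1 kb from first); third kept (outside 5 kb window)
  expect_equal(colnames(out$genotypes$dosages), c("s001", "s003"))
  expect_equal(out$report$n_removed_ld, 1L)
  # zero-variance SNP never produces NaN r2 and is kept
  dos2 <- cbind(x, rep(1, 8), x)
  out2 <- ld_prune(make_gm(dos2, pos = c(1000L, 1500L, 2000L)))
  expect_equal(out2$report$n_removed_ld, 1L)
  expect_true("s002" %in% colnames(out2$genotypes$dosages))
  expect_error(ld_prune(gm, window_bp = 0), "positive")
})

test_that("LD pruning matches a brute-force scan and ignores other chromosomes", {
  set.seed(23)
  base <- matrix(rbinom(40 * 60, 2, 0.4), 40, 60)
  dos <- base[, rep(seq_len(60), each = 2)]               # correlated pairs
  dos <- dos + matrix(rbinom(length(dos), 1, 0.1), nrow(dos))
  dos[dos > 2] <- 2
  pos <- sort(sample(1:200000, 120))
  gm <- make_gm(dos, pos = as.integer(pos))
  out <- ld_prune(gm, 0.5, 5000)
  keep <- brute_ld_prune(dos, rep("chr1", 120), pos, 0.5, 5000)
  expect_identical(colnames(out$genotypes$dosages), gm$snp_meta$id[keep])
  # post-check: no surviving within-window pair above the threshold
  kd <- out$genotypes$dosages; kp <- out$genotypes$snp_meta$pos
  for (a in seq_len(ncol(kd))) for (b in seq_len(ncol(kd))) {
    if (b <= a || kp[b] - kp[a] > 5000) next
    expect_lte(suppressWarnings(cor(kd[, a], kd[, b]))^2, 0.5)
  }
  # prepending SNPs on a different chromosome leaves the result unchanged
  dos_pre <- cbind(matrix(rbinom(40 * 5, 2, 0.5), 40), dos)
  gm_pre <- make_gm(dos_pre, pos = as.integer(c(1:5 * 100, pos)),
                    chrom = c(rep("chr0", 5), rep("chr1", 120)))
  out_pre <- ld_prune(gm_pre, 0.5, 5000)
  kept_chr1 <- out_pre$genotypes$snp_meta$pos[out_pre$genotypes$snp_meta$chrom == "chr1"]
  expect_identical(kept_chr1, out$genotypes$snp_meta$pos)
})
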