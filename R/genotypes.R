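#' Genotype dosage matrix with site and sample metadata
#'
#' The central genotype container: an individuals x SNPs matrix of alternate
#' allele counts (0/1/2, `NA` = missing) plus per-SNP metadata (chromosome,
#' 1-based position, ref/alt alleles) and per-sample metadata (id, locality,
#' longitude, latitude).
#'
#' @param dosages integer matrix, individuals x SNPs, values in
#'   `{0, 1, 2, NA}`.
#' @param snp_meta data frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per SNP column).
#' @param sample_meta data frame with columns `id`, `locality`, `longitude`,
#'   `latitude` (one row per individual).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_meta) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 1) stopf("need at least one individual")
  if (nrow(snp_meta) != ncol(dosages)) stopf("snp_meta rows must match SNP columns")
  if (nrow(sample_meta) != nrow(dosages)) stopf("sample_meta rows must match individuals")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snp_meta))) stopf("snp_meta needs columns: %s", paste(need, collapse = ", "))
  if (!all(c("id", "locality") %in% names(sample_meta)))
    stopf("sample_meta needs columns id and locality")
  if (any(!dosages %in% c(0L, 1L, 2L, NA))) stopf("dosages must be 0, 1, 2 or NA")
  if (any(!nzchar(snp_meta$ref)) || any(!nzchar(snp_meta$alt)))
    stopf("allele labels must be non-empty")
  for (cc in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == cc]
    if (any(diff(sort(p)) <= 0)) stopf("positions must be distinct within chromosome %s", cc)
  }
  rownames(dosages) <- sample_meta$id
  colnames(dosages) <- snp_meta$id
  structure(list(dosages = dosages,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_meta = as.data.frame(sample_meta, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.1f%% missing), %d localities\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages)), length(unique(x$sample_meta$locality))))
  invisible(x)
}

n_snps <- function(gm) ncol(gm$dosages)
n_ind <- function(gm) nrow(gm$dosages)

subset_snps <- function(gm, keep) {
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  gm$snp_meta[keep, , drop = FALSE],
                  gm$sample_meta)
}

#' Read a VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only (multiallelic sites and indels are
#' skipped with a message); the dosage is the count of alternate alleles in
#' the GT field, with `./.` read as missing.
#'
#' @param path VCF file (v4.x, GT format field present).
#' @param sample_meta optional data frame (`id`, `locality`, `longitude`,
#'   `latitude`) merged by sample id; defaults to one locality per sample.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path, sample_meta = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ok <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  ok[is.na(ok)] <- FALSE
  n_skip <- sum(!ok)
  if (n_skip) message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  if (!any(ok)) stopf("no usable biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  allele1 <- substr(gt, 1, 1); allele3 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- allele1 %in% c("0", "1") & allele3 %in% c("0", "1")
  dos[known] <- (allele1 == "1")[known] + (allele3 == "1")[known]
  dos <- t(dos)
  ids <- fix$ID[ok]
  ids[is.na(ids) | ids == "."] <- sprintf("%s_%s", fix$CHROM[ok], fix$POS[ok])[is.na(ids) | ids == "."]
  snp_meta <- data.frame(id = ids, chrom = fix$CHROM[ok],
                         pos = as.integer(fix$POS[ok]),
                         ref = fix$REF[ok], alt = fix$ALT[ok],
                         stringsAsFactors = FALSE)
  samples <- colnames(gt)
  if (is.null(sample_meta))
    sample_meta <- data.frame(id = samples, locality = samples,
                              longitude = NA_real_, latitude = NA_real_,
                              stringsAsFactors = FALSE)
  else {
    sample_meta <- sample_meta[match(samples, sample_meta$id), , drop = FALSE]
    if (anyNA(sample_meta$id)) stopf("sample_meta does not cover all VCF samples")
  }
  genotype_matrix(dos, snp_meta, sample_meta)
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=landgea",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_meta$id), collapse = "\t")), con)
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- gm$dosages
  for (j in seq_len(ncol(dos))) {
    g <- gtcode[as.character(dos[, j])]
    g[is.na(g)] <- "./."
    writeLines(paste(c(gm$snp_meta$chrom[j], gm$snp_meta$pos[j],
                       gm$snp_meta$id[j], gm$snp_meta$ref[j],
                       gm$snp_meta$alt[j], ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' SNPs with a missing-call fraction above `max_missing` are removed first;
#' the minor allele frequency is then computed on the remaining non-missing
#' calls and SNPs below `min_maf` are removed.  Column order of survivors is
#' preserved.
#'
#' @param gm a [genotype_matrix].
#' @param max_missing maximum tolerated missing fraction per SNP
#'   (default 0.2).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return list with `genotypes` (filtered) and `report` (a `filter_report`:
#'   `n_input`, `n_removed_missing`, `n_removed_maf`, `n_removed_ld`,
#'   `n_output`).
#' @export
filter_genotypes <- function(gm, max_missing = 0.2, min_maf = 0.01) {
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1)
    stopf("thresholds must be in [0, 1]")
  dos <- gm$dosages
  miss_frac <- colMeans(is.na(dos))
  keep1 <- miss_frac <= max_missing
  n_removed_missing <- sum(!keep1)
  af <- colMeans(dos[, keep1, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep2 <- maf >= min_maf
  n_removed_maf <- sum(!keep2)
  keep <- which(keep1)[keep2]
  if (!length(keep))
    stopf("all %d SNPs removed; review max_missing/min_maf thresholds", n_snps(gm))
  report <- filter_report(n_input = n_snps(gm),
                          n_removed_missing = n_removed_missing,
                          n_removed_maf = n_removed_maf,
                          n_removed_ld = 0L,
                          n_output = length(keep))
  list(genotypes = subset_snps(gm, keep), report = report)
}

filter_report <- function(n_input, n_removed_missing = 0L, n_removed_maf = 0L,
                          n_removed_ld = 0L, n_output) {
  r <- list(n_input = as.integer(n_input),
            n_removed_missing = as.integer(n_removed_missing),
            n_removed_maf = as.integer(n_removed_maf),
            n_removed_ld = as.integer(n_removed_ld),
            n_output = as.integer(n_output))
  stopifnot(r$n_output == r$n_input - r$n_removed_missing - r$n_removed_maf - r$n_removed_ld,
            all(unlist(r) >= 0))
  structure(r, class = "filter_report")
}

#' Impute missing dosages from allele frequencies
#'
#' Each missing call is drawn as binomial(2, p-hat) with p-hat the
#' alternate-allele frequency in the individual's locality; if the locality
#' has no non-missing call at that SNP the global frequency is used.
#' Haplotype-based imputation is deliberately not attempted: the downstream
#' statistics use dosages only and no reference panel exists for the target
#' species.
#'
#' @param gm a [genotype_matrix].
#' @param mode `"per_locality_frequency"` (default) or `"global_frequency"`.
#' @param seed integer RNG seed; imputation is deterministic given the seed.
#' @return a [genotype_matrix] with no missing entries.
#' @export
impute_missing <- function(gm, mode = c("per_locality_frequency", "global_frequency"),
                           seed = 1L) {
  mode <- match.arg(mode)
  dos <- gm$dosages
  if (!anyNA(dos)) return(gm)
  global_p <- colMeans(dos, na.rm = TRUE) / 2
  if (any(is.nan(global_p)))
    stopf("SNP(s) entirely missing: %s",
          paste(head(gm$snp_meta$id[is.nan(global_p)], 5), collapse = ", "))
  loc <- gm$sample_meta$locality
  dos <- with_seed(seed, {
    if (mode == "per_locality_frequency") {
      for (l in unique(loc)) {
        rows <- which(loc == l)
        sub <- dos[rows, , drop = FALSE]
        p <- colMeans(sub, na.rm = TRUE) / 2
        p[is.nan(p)] <- global_p[is.nan(p)]
        nas <- which(is.na(sub), arr.ind = TRUE)
        if (nrow(nas))
          dos[cbind(rows[nas[, 1]], nas[, 2])] <- rbinom(nrow(nas), 2, p[nas[, 2]])
      }
    } else {
      nas <- which(is.na(dos), arr.ind = TRUE)
      dos[nas] <- rbinom(nrow(nas), 2, global_p[nas[, 2]])
    }
    dos
  })
  genotype_matrix(dos, gm$snp_meta, gm$sample_meta)
}

#' Prune SNPs in linkage disequilibrium
#'
#' Greedy left-to-right scan per chromosome: for each retained SNP, any
#' later SNP within `window_bp` whose squared Pearson correlation of dosages
#' exceeds `r2_max` is dropped (the earlier-position SNP of a correlated
#' pair is kept).  Zero-variance SNPs are treated as uncorrelated.
#'
#' @param gm a [genotype_matrix]; r2 uses pairwise-complete calls if missing
#'   data remain.
#' @param r2_max squared-correlation threshold (default 0.5).
#' @param window_bp window size in base pairs (default 5000).
#' @return list with `genotypes` (pruned) and `report` (a `filter_report`).
#' @export
ld_prune <- function(gm, r2_max = 0.5, window_bp = 5000) {
  if (window_bp <= 0) stopf("window_bp must be positive")
  dos <- gm$dosages
  keep <- rep(TRUE, n_snps(gm))
  sds <- apply(dos, 2, sd, na.rm = TRUE)
  for (cc in unique(gm$snp_meta$chrom)) {
    idx <- which(gm$snp_meta$chrom == cc)
    idx <- idx[order(gm$snp_meta$pos[idx])]
    pos <- gm$snp_meta$pos[idx]
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (!keep[i]) next
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= window_bp) {
        j <- idx[b]
        if (keep[j]) {
          r2 <- if (sds[i] == 0 || sds[j] == 0 || is.na(sds[i]) || is.na(sds[j])) 0
            else suppressWarnings(cor(dos[, i], dos[, j], use = "pairwise.complete.obs"))^2
          if (!is.na(r2) && r2 > r2_max) keep[j] <- FALSE
        }
        b <- b + 1L
      }
    }
  }
  report <- filter_report(n_input = n_snps(gm), n_removed_ld = sum(!keep),
                          n_output = sum(keep))
  list(genotypes = subset_snps(gm, which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d in; %d removed (missingness), ",
                     "%d (MAF), %d (LD); %d out\n"),
              x$n_input, x$n_removed_missing, x$n_removed_maf,
              x$n_removed_ld, x$n_output))
  invisible(x)
}

#' Write a filter report as JSON
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
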