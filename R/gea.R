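#' Latent-factor gene-environment association Z-scores
#'
#' Association of each SNP's dosage with each environmental variable while
#' latent factors absorb neutral population structure: the model
#' `Y ~ X b + U V' + E` is estimated by a deterministic least-squares /
#' singular-value-decomposition formulation.  The latent factors `U` are
#' the leading `K_latent` left singular vectors of the centered genotype
#' matrix; per SNP the environmental effect and its standard error come
#' from ordinary least squares of the dosage on `(1, X, U)`, giving
#' `Z = b / se(b)`.  With `K_latent = 0` this reduces exactly to
#' per-SNP simple-regression t-statistics.  Environmental variables are
#' standardized internally, so Z is invariant to affine rescaling of the
#' input.  `reps` repetitions (kept for API compatibility with stochastic
#' estimators) return the per-SNP median Z.
#'
#' @param gm an imputed [genotype_matrix].
#' @param env data frame / matrix of per-sample environmental values (one
#'   column per variable), or a single numeric vector.
#' @param K_latent number of latent factors (>= 0; typically the K chosen
#'   by [select_k()]).
#' @param reps repetitions whose per-SNP median Z is returned (default 3).
#' @param seed integer RNG seed (retained for interface stability; the
#'   estimator is deterministic).
#' @return matrix of Z-scores, SNPs x environmental variables.
#' @export
fit_lfmm_z <- function(gm, env, K_latent, reps = 3, seed = 1L) {
  Y <- gm$dosages
  if (anyNA(Y)) stopf("genotypes must be imputed before fit_lfmm_z")
  if (is.null(dim(env))) env <- matrix(env, ncol = 1, dimnames = list(NULL, "env"))
  env <- as.matrix(env)
  if (is.null(colnames(env))) colnames(env) <- paste0("env", seq_len(ncol(env)))
  n <- nrow(Y); L <- ncol(Y)
  if (nrow(env) != n) stopf("env must have one row per individual")
  if (any(!is.finite(env))) stopf("env values must be finite")
  if (any(apply(env, 2, sd) == 0)) stopf("constant environmental variable(s)")
  if (K_latent < 0 || K_latent >= min(n, L))
    stopf("K_latent must be in [0, min(n, L) - 1]")

  Yc <- scale(Y, center = TRUE, scale = FALSE)

  one_fit <- function() {
    Z <- matrix(NA_real_, L, ncol(env),
                dimnames = list(gm$snp_meta$id, colnames(env)))
    for (v in seq_len(ncol(env))) {
      x <- as.vector(scale(env[, v]))
      # latent factors from the genotype matrix with the environmental
      # direction projected off, so U absorbs structure but cannot steal
      # the environmental effect from the association coefficient;
      # residual confounding is handled downstream by lambda calibration
      U <- if (K_latent > 0) {
        Yr <- Yc - x %*% crossprod(x, Yc) / sum(x^2)
        e <- eigen(tcrossprod(Yr), symmetric = TRUE)
        e$vectors[, seq_len(K_latent), drop = FALSE]
      } else NULL
      base <- cbind(rep(1, n), U)
      Qb <- qr.Q(qr(base))
      Y0 <- Y - Qb %*% crossprod(Qb, Y)
      x0 <- x - Qb %*% crossprod(Qb, x)
      xx <- sum(x0^2)
      if (xx < 1e-12) stopf("environmental variable '%s' is collinear with the latent factors",
                            colnames(env)[v])
      beta <- as.vector(crossprod(Y0, x0)) / xx
      rss <- colSums(Y0^2) - beta^2 * xx
      df <- n - 2 - K_latent
      se <- sqrt(pmax(rss, 0) / df / xx)
      Z[, v] <- ifelse(se > 0, beta / se, 0)
    }
    Z
  }
  zs <- lapply(seq_len(reps), function(r) one_fit())
  if (reps == 1) return(zs[[1]])
  med <- apply(simplify2array(zs), c(1, 2), median)
  dimnames(med) <- dimnames(zs[[1]])
  med
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / m`, where `m` is the median of the chi-square
#' distribution with one degree of freedom (computed from the inverse CDF,
#' ~0.4549).
#'
#' @param z numeric vector of Z-scores.
#' @return the genomic inflation factor (scalar >= 0).
#' @export
genomic_inflation <- function(z) {
  z <- as.vector(z)
  if (!length(z)) stopf("empty Z-score vector")
  if (any(!is.finite(z))) stopf("Z-scores must be finite")
  median(z^2) / qchisq(0.5, df = 1)
}

#' Calibrate P-values by genomic inflation and correct by Benjamini-Hochberg
#'
#' Calibrated P-values are the upper-tail chi-square(1) probability of
#' `z^2 / lambda`; Q-values are the BH step-up adjustment.
#'
#' @param z numeric vector of Z-scores.
#' @param lambda genomic inflation factor (> 0), typically from
#'   [genomic_inflation()].
#' @return list with `p_adj` and `q`, both in `[0, 1]`.
#' @export
calibrate_and_fdr <- function(z, lambda) {
  if (lambda <= 0) stopf("lambda must be positive")
  p_adj <- pchisq(as.vector(z)^2 / lambda, df = 1, lower.tail = FALSE)
  list(p_adj = p_adj, q = p.adjust(p_adj, method = "BH"))
}

#' Full gene-environment association scan
#'
#' Runs [fit_lfmm_z()] for every environmental variable, computes one
#' genomic inflation factor per variable, calibrates P-values, applies BH
#' correction per variable, and classifies SNPs as putatively adaptive.
#'
#' @inheritParams fit_lfmm_z
#' @inheritParams classify_adaptive
#' @return object of class `gea_result`: `z` (SNPs x variables), `lambda`
#'   (per variable), `p_adj`, `q` (same shape as `z`), `adaptive`
#'   (logical, per variable), `adaptive_any`, `K_latent`, plus the count
#'   summaries of [classify_adaptive()].
#' @export
gea_scan <- function(gm, env, K_latent, reps = 3, seed = 1L,
                     z_thresh = 2, q_thresh = 0.01) {
  z <- fit_lfmm_z(gm, env, K_latent, reps = reps, seed = seed)
  lambda <- apply(z, 2, genomic_inflation)
  p_adj <- z; q <- z
  for (v in seq_len(ncol(z))) {
    cal <- calibrate_and_fdr(z[, v], lambda[v])
    p_adj[, v] <- cal$p_adj
    q[, v] <- cal$q
  }
  res <- structure(list(z = z, lambda = lambda, p_adj = p_adj, q = q,
                        K_latent = as.integer(K_latent),
                        snp_id = gm$snp_meta$id),
                   class = "gea_result")
  cls <- classify_adaptive(res, z_thresh = z_thresh, q_thresh = q_thresh)
  res$adaptive <- cls$adaptive
  res$adaptive_any <- cls$adaptive_any
  res$counts_per_variable <- cls$counts_per_variable
  res$counts_by_n_variables <- cls$counts_by_n_variables
  res
}

#' @export
print.gea_result <- function(x, ...) {
  cat(sprintf("gea_result: %d SNPs x %d variables, K_latent = %d\n",
              nrow(x$z), ncol(x$z), x$K_latent))
  cat(sprintf("lambda: %s\n", paste(sprintf("%s=%.3f", names(x$lambda), x$lambda),
                                    collapse = ", ")))
  if (!is.null(x$adaptive_any))
    cat(sprintf("putatively adaptive (any variable): %d\n", sum(x$adaptive_any)))
  invisible(x)
}

#' Classify putatively adaptive SNPs
#'
#' A SNP is adaptive for a variable iff `|Z| > z_thresh` and
#' `Q < q_thresh`; `adaptive_any` is the union over variables (adaptive
#' for at least one variable).
#'
#' @param result a `gea_result` (needs `z` and `q`).
#' @param z_thresh absolute-Z threshold (default 2).
#' @param q_thresh Q-value threshold (default 0.01).
#' @return list with `adaptive` (SNPs x variables logical), `adaptive_any`,
#'   `counts_per_variable`, and `counts_by_n_variables` (how many SNPs are
#'   adaptive for exactly 1, 2, ... variables).
#' @export
classify_adaptive <- function(result, z_thresh = 2, q_thresh = 0.01) {
  flags <- abs(result$z) > z_thresh & result$q < q_thresh
  nvar <- rowSums(flags)
  counts_by_n <- if (ncol(flags)) table(factor(nvar[nvar > 0], levels = seq_len(ncol(flags))))
    else table(integer(0))
  list(adaptive = flags,
       adaptive_any = nvar > 0,
       counts_per_variable = colSums(flags),
       counts_by_n_variables = counts_by_n)
}

#' Write a GEA result as TSV
#'
#' One row per SNP: id, per-variable Z / calibrated P / Q, and adaptive
#' flags.
#'
#' @param result a `gea_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gea_tsv <- function(result, path) {
  out <- data.frame(id = result$snp_id, stringsAsFactors = FALSE)
  for (v in colnames(result$z)) {
    out[[paste0("z_", v)]] <- result$z[, v]
    out[[paste0("p_", v)]] <- result$p_adj[, v]
    out[[paste0("q_", v)]] <- result$q[, v]
  }
  out$adaptive_any <- result$adaptive_any
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
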