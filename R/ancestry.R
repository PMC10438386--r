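# one-hot encoding of a dosage matrix: n x 3L, triples = I(d==0,1,2)
one_hot_genotypes <- function(dos) {
  n <- nrow(dos); L <- ncol(dos)
  D <- matrix(0, n, 3L * L)
  ii <- rep(seq_len(n), L)
  jj <- rep(seq_len(L), each = n)
  D[cbind(ii, 3L * (jj - 1L) + as.vector(dos) + 1L)] <- 1
  D
}

#' Fit a sparse nonnegative matrix factorization ancestry model
#'
#' Factorizes the one-hot genotype encoding D (individuals x 3 SNPs) as
#' Q x H with nonnegative factors, Q rows constrained to the probability
#' simplex (soft constraint via an augmented column, renormalized on exit)
#' and an L2 sparsity penalty `alpha` on H.  Fitting uses multiplicative
#' updates, so the penalized least-squares training loss is non-increasing
#' across iterations.  A random fraction of genotype entries is masked out
#' of the fit and scored afterwards: the cross-entropy is the mean negative
#' log probability of the masked dosages under binomial(2, QG), the masked
#' prediction loss used for model choice.
#'
#' @param gm an imputed [genotype_matrix] (no missing entries).
#' @param K number of ancestral components, `1 <= K <= n` individuals.
#' @param alpha L2 regularization weight on the ancestral factor
#'   (default 10, the conventional order of magnitude).
#' @param max_iter maximum multiplicative-update iterations (default 200).
#' @param mask_fraction fraction of genotype entries held out (default 0.05).
#' @param seed integer RNG seed for initialization and masking.
#' @return object of class `ancestry_model`: `Q` (n x K, rows sum to 1),
#'   `G` (K x SNPs ancestral alternate-allele frequencies), `K`, `alpha`,
#'   `cross_entropy`, `loss` (training-loss trace), `seed`.
#' @export
fit_snmf <- function(gm, K, alpha = 10, max_iter = 200, mask_fraction = 0.05,
                     seed = 1L) {
  dos <- gm$dosages
  n <- nrow(dos); L <- ncol(dos)
  if (anyNA(dos)) stopf("genotypes must be imputed before fit_snmf")
  if (K < 1 || K > n) stopf("K must be between 1 and the number of individuals (%d)", n)

  with_seed(seed, {
    masked <- if (mask_fraction > 0)
      which(matrix(runif(n * L) < mask_fraction, n, L)) else integer(0)
    if (mask_fraction > 0 && !length(masked))
      masked <- sample(n * L, max(1, round(mask_fraction * n * L)))
    D <- one_hot_genotypes(dos)
    # masked genotype entries get zero weight in the factorization, so the
    # held-out cross-entropy is an honest out-of-sample prediction loss
    mi <- (masked - 1L) %% n + 1L
    mj <- (masked - 1L) %/% n + 1L
    W <- matrix(1, n, 3L * L)
    for (g in 0:2) W[cbind(mi, 3L * (mj - 1L) + g + 1L)] <- 0
    Dw <- D * W

    if (K == 1) {
      # closed form: Q is the all-ones column and the weighted least-squares
      # H is the observed genotype profile, i.e. G = global allele frequencies
      Q <- matrix(1, n, 1)
      H <- matrix(colSums(Dw) / pmax(colSums(W), 1), 1)
      loss <- sum(W * (D - Q %*% H)^2) + alpha * sum(H^2)
    } else {
      Q <- matrix(runif(n * K, 0.1, 1), n, K); Q <- Q / rowSums(Q)
      H <- matrix(runif(K * 3 * L, 0, 1), K) * mean(Dw)
      g_aug <- 1          # weight of the soft row-simplex constraint on Q
      eps <- 1e-10
      loss <- numeric(max_iter)
      for (it in seq_len(max_iter)) {
        # weighted ridge-penalized multiplicative updates
        P <- Q %*% H
        H <- H * (crossprod(Q, Dw)) / (crossprod(Q, W * P) + alpha * H + eps)
        P <- Q %*% H
        # Q update on the augmented system [D, sqrt(g) 1] ~ Q [H, sqrt(g) 1]
        num <- Dw %*% t(H) + g_aug
        den <- (W * P) %*% t(H) + g_aug * rowSums(Q) + eps
        Q <- Q * num / den
        loss[it] <- sum(W * (D - Q %*% H)^2) + alpha * sum(H^2) +
          g_aug * sum((rowSums(Q) - 1)^2)
        if (it > 1 && abs(loss[it - 1] - loss[it]) < 1e-10 * abs(loss[it - 1])) {
          loss <- loss[seq_len(it)]
          break
        }
      }
      Q <- Q / rowSums(Q)   # soft constraint keeps row sums ~1; make exact
    }
    if (any(!is.finite(loss))) stopf("sNMF training loss became non-finite")

    # ancestral alt-allele frequencies from the genotype-probability triples
    trip <- function(g) H[, 3 * (seq_len(L) - 1) + g + 1, drop = FALSE]
    tot <- pmax(trip(0) + trip(1) + trip(2), 1e-12)
    G <- (trip(1) + 2 * trip(2)) / (2 * tot)
    G <- pmin(pmax(G, 0), 1)

    # with no held-out entries the cross-entropy is the training loss
    ce <- snmf_cross_entropy(dos, Q, G,
                             if (length(masked)) masked else seq_len(n * L))
    structure(list(Q = Q, G = G, K = as.integer(K), alpha = alpha,
                   cross_entropy = ce, loss = loss, seed = as.integer(seed),
                   masked = masked),
              class = "ancestry_model")
  })
}

snmf_cross_entropy <- function(dos, Q, G, masked) {
  P <- pmin(pmax(Q %*% G, 1e-9), 1 - 1e-9)
  d <- dos[masked]; p <- P[masked]
  ll <- d * log(p) + (2 - d) * log(1 - p) +
    log(choose(2, d))
  -mean(ll)
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat(sprintf("ancestry_model: K = %d, %d individuals x %d SNPs, cross-entropy %.4f\n",
              x$K, nrow(x$Q), ncol(x$G), x$cross_entropy))
  invisible(x)
}

#' Choose the number of ancestral populations by masked cross-entropy
#'
#' Fits [fit_snmf()] for every K in `k_range` with `reps` repetitions
#' (distinct masks and initializations) and keeps the best (lowest)
#' cross-entropy per K.  The chosen K is the argmin of the curve, unless
#' the curve plateaus earlier: if the relative cross-entropy decrease
#' gained by moving one K up is below `plateau_tol`, the smaller K entering
#' the plateau is preferred.
#'
#' @inheritParams fit_snmf
#' @param k_range candidate K values (default 1:15).
#' @param reps repetitions per K (default 10).
#' @param plateau_tol relative-decrease tolerance declaring a plateau
#'   (default 0.01).
#' @return list with `K` (chosen), `curve` (data frame K / cross_entropy),
#'   and `models` (best model per K).
#' @export
select_k <- function(gm, k_range = 1:15, reps = 10, alpha = 10, max_iter = 200,
                     mask_fraction = 0.05, seed = 1L, plateau_tol = 0.01) {
  if (!length(k_range)) stopf("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  models <- vector("list", length(k_range))
  ce <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    for (r in seq_len(reps)) {
      m <- fit_snmf(gm, k_range[i], alpha = alpha, max_iter = max_iter,
                    mask_fraction = mask_fraction,
                    seed = child_seed(seed, i * 1000 + r))
      if (is.na(ce[i]) || m$cross_entropy < ce[i]) {
        ce[i] <- m$cross_entropy
        models[[i]] <- m
      }
    }
  }
  if (all(!is.finite(ce))) stopf("degenerate sNMF fits at every K")
  chosen <- k_range[which.min(ce)]
  for (i in seq_along(k_range)[-length(k_range)]) {
    rel <- (ce[i] - ce[i + 1]) / abs(ce[i])
    if (rel < plateau_tol) { chosen <- k_range[i]; break }
  }
  list(K = chosen, curve = data.frame(K = k_range, cross_entropy = ce),
       models = models)
}

#' FST outlier scan from ancestry coefficients
#'
#' Per SNP, FST is computed from the ancestral allele frequencies G
#' weighted by the mean ancestry coefficients (variance of component
#' frequencies over total heterozygosity).  FST is converted to a squared
#' z-statistic via the chi-square transform with K - 1 degrees of freedom
#' (stat = FST (n - K) / (1 - FST), an interpretation of the standard
#' sNMF-FST outlier transform), genomic-inflation calibrated, and
#' BH-corrected; outliers are flagged at Q < `q_thresh`.
#'
#' @param model an [fit_snmf()] `ancestry_model` with K >= 2.
#' @param gm the genotype matrix the model was fitted on.
#' @param q_thresh outlier flagging threshold on Q-values (default 0.01).
#' @return data frame (`id`, `fst`, `stat`, `p_adj`, `q`, `outlier`) with
#'   attribute `lambda` (the genomic inflation factor used).
#' @export
fst_outliers <- function(model, gm, q_thresh = 0.01) {
  if (model$K < 2) stopf("FST is undefined for K = 1")
  if (ncol(model$G) != n_snps(gm)) stopf("model was not fitted on this genotype matrix")
  w <- colMeans(model$Q)
  pbar <- as.vector(w %*% model$G)
  v <- as.vector(w %*% (model$G - matrix(pbar, model$K, length(pbar), byrow = TRUE))^2)
  het <- pbar * (1 - pbar)
  fst <- ifelse(het > 0, v / het, 0)
  fst <- pmin(pmax(fst, 0), 1 - 1e-9)
  n <- nrow(model$Q)
  stat <- fst * (n - model$K) / (1 - fst)
  df <- model$K - 1
  lambda <- median(stat) / qchisq(0.5, df)
  if (lambda <= 0) lambda <- 1
  p_adj <- pchisq(stat / lambda, df, lower.tail = FALSE)
  q <- p.adjust(p_adj, method = "BH")
  out <- data.frame(id = gm$snp_meta$id, fst = fst, stat = stat,
                    p_adj = p_adj, q = q, outlier = q < q_thresh,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lambda
  out
}
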