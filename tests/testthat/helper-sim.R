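# Shared fixtures and independent oracles used across the suite.

# One synthetic study: landscape + samples + genotypes + extracted env.
sim_dataset <- function(seed, n_pops = 10, n_per_pop = 10, n_neutral = 300,
                        n_adaptive = 0, effect = 2, causal = "temp1",
                        target_fst = 0.15, K = 3, grid = 50,
                        autocorr = 3, n_env = 4, missing_rate = 0) {
  spec <- landscape_spec(grid, grid, n_env = n_env, autocorr_range = autocorr,
                         seed = seed)
  land <- simulate_landscape(spec)
  samples <- simulate_samples(n_pops, n_per_pop, land$current,
                              seed = seed + 1000L)
  truth <- make_truth(K, target_fst, n_adaptive, causal, effect)
  g <- simulate_genotypes(samples, land$current, n_neutral, truth,
                          missing_rate = missing_rate, seed = seed + 2000L)
  coords <- data.frame(x = g$genotypes$sample_meta$longitude,
                       y = g$genotypes$sample_meta$latitude)
  ext <- extract_at_points(land$current, coords)
  list(gm = g$genotypes, truth = g$truth, land = land, samples = samples,
       coords = coords, env = ext[, setdiff(names(ext), "in_mask")])
}

# Unstructured genotype matrix (pure binomial draws, no population structure).
sim_unstructured <- function(seed, n, L, p_range = c(0.1, 0.9)) {
  set.seed(seed)
  p0 <- runif(L, p_range[1], p_range[2])
  dos <- matrix(rbinom(n * L, 2, rep(p0, each = n)), n, L)
  genotype_matrix(dos,
                  data.frame(id = sprintf("s%05d", seq_len(L)), chrom = "chr1",
                             pos = seq_len(L) * 100L, ref = "A", alt = "T"),
                  data.frame(id = sprintf("i%04d", seq_len(n)), locality = "L1",
                             longitude = 0, latitude = 0))
}

# Weir-Cockerham multi-locus FST (ratio of averages) -- independent oracle.
wc_fst <- function(dos, pop) {
  r <- length(unique(pop))
  num <- den <- 0
  for (j in seq_len(ncol(dos))) {
    ni <- tapply(!is.na(dos[, j]), pop, sum)
    pi <- tapply(dos[, j], pop, function(x) mean(x, na.rm = TRUE) / 2)
    hi <- tapply(dos[, j] == 1, pop, function(x) mean(x, na.rm = TRUE))
    nbar <- mean(ni); pbar <- sum(ni * pi) / sum(ni); hbar <- sum(ni * hi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    num <- num + a
    den <- den + a + b + hbar / 2
  }
  num / den
}

# Best label-matching accuracy over all permutations of K cluster labels.
perm_accuracy <- function(lab, truth_lab, K) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  max(vapply(perms(seq_len(K)), function(p) mean(p[lab] == truth_lab),
             numeric(1)))
}

# Brute-force missingness + MAF filter (independent per-SNP double loop).
brute_filter <- function(dos, max_missing, min_maf) {
  keep <- logical(ncol(dos))
  for (j in seq_len(ncol(dos))) {
    x <- dos[, j]
    if (mean(is.na(x)) > max_missing) next
    x <- x[!is.na(x)]
    af <- sum(x) / (2 * length(x))
    maf <- min(af, 1 - af)
    if (is.nan(maf)) maf <- 0
    keep[j] <- maf >= min_maf
  }
  keep
}

# Brute-force greedy LD pruning (keep earlier-position SNP of a pair).
brute_ld_prune <- function(dos, chrom, pos, r2_max, window_bp) {
  keep <- rep(TRUE, ncol(dos))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    idx <- idx[order(pos[idx])]
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (pos[idx[b]] - pos[idx[a]] > window_bp) break
        if (!keep[idx[b]]) next
        sa <- sd(dos[, idx[a]], na.rm = TRUE)
        sb <- sd(dos[, idx[b]], na.rm = TRUE)
        r2 <- if (is.na(sa) || is.na(sb) || sa == 0 || sb == 0) 0 else
          suppressWarnings(cor(dos[, idx[a]], dos[, idx[b]],
                               use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2_max) keep[idx[b]] <- FALSE
      }
    }
  }
  keep
}

# Closed-form orthogonal Procrustes (translation + rotation/reflection +
# isotropic scaling) superimposing Y onto X; returns per-point residuals.
procrustes_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(Yc^2)
  Yrot <- scl * Yc %*% R
  sqrt(rowSums((Yrot - Xc)^2))
}
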