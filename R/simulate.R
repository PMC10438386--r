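#' Landscape specification for the synthetic-data generator
#'
#' Describes the synthetic environmental landscape: grid size, number of
#' environmental layers, spatial autocorrelation scale, and the target
#' pairwise correlation among layers.  Layer names default to a mix of
#' temperature-like (`temp*`) and precipitation-like (`prec*`) variables;
#' the default future scenario shifts temperature-like layers by +1 s.d.
#'
#' @param grid_rows,grid_cols grid dimension (>= 4).
#' @param n_env number of environmental layers (>= 1).
#' @param autocorr_range Gaussian-kernel smoothing scale, in cells.
#' @param env_cross_corr symmetric target correlation matrix with unit
#'   diagonal; default identity.
#' @param seed integer RNG seed.
#' @param layer_names optional layer names (length `n_env`).
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_rows, grid_cols, n_env = 4, autocorr_range = 5,
                           env_cross_corr = NULL, seed = 1L,
                           layer_names = NULL) {
  if (grid_rows < 4 || grid_cols < 4) stopf("grid_rows and grid_cols must be >= 4")
  if (n_env < 1) stopf("n_env must be >= 1")
  if (is.null(env_cross_corr)) env_cross_corr <- diag(n_env)
  env_cross_corr <- as.matrix(env_cross_corr)
  if (!isTRUE(all.equal(env_cross_corr, t(env_cross_corr))) ||
      any(abs(diag(env_cross_corr) - 1) > 1e-12) ||
      any(abs(env_cross_corr) > 1 + 1e-12))
    stopf("env_cross_corr must be symmetric with unit diagonal and entries in [-1, 1]")
  if (is.null(layer_names)) {
    n_temp <- ceiling(n_env / 2)
    layer_names <- c(sprintf("temp%d", seq_len(n_temp)),
                     sprintf("prec%d", seq_len(n_env - n_temp)))
  }
  if (length(layer_names) != n_env || anyDuplicated(layer_names))
    stopf("layer_names must be %d unique names", n_env)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_env = as.integer(n_env),
                 autocorr_range = autocorr_range,
                 env_cross_corr = env_cross_corr,
                 seed = as.integer(seed),
                 layer_names = layer_names),
            class = "landscape_spec")
}

# Smooth white noise with a separable Gaussian kernel (scale in cells).
smooth_field <- function(nr, nc, scale) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (scale <= 0) return(z)
  k1 <- function(n) {
    k <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * scale^2))
    k / rowSums(k)
  }
  k1(nr) %*% z %*% t(k1(nc))
}

#' Simulate current and future environmental raster stacks
#'
#' Generates `n_env` spatially autocorrelated layers, each standardized to
#' zero mean and unit variance over the grid, whose realized pairwise
#' correlations equal the requested `env_cross_corr` (imposed exactly by
#' orthogonalizing the smoothed fields and recolouring with the Cholesky
#' factor).  Future stacks are the current stack plus a per-layer shift
#' field; the default scenario shifts temperature-like layers by +1 s.d.,
#' emulating directional climate change.
#'
#' @param spec a [landscape_spec].
#' @param future_shift per-layer shift defining the future scenario: a named
#'   numeric vector (constant shift per layer), a named list of matrices
#'   (full shift fields), or `NULL` for the default +1 s.d. on `temp*`
#'   layers.  A named list of such specifications yields one future stack
#'   per scenario.
#' @return list with elements `current` (an [env_stack]) and `future`
#'   (named list of [env_stack]s, one per scenario).
#' @export
simulate_landscape <- function(spec, future_shift = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols; p <- spec$n_env
  R <- tryCatch(chol(spec$env_cross_corr),
                error = function(e) stopf(
                  "env_cross_corr is not positive definite; supply a valid correlation matrix"))
  layers <- with_seed(spec$seed, {
    raw <- vapply(seq_len(p), function(i) as.vector(smooth_field(nr, nc, spec$autocorr_range)),
                  numeric(nr * nc))
    raw <- scale(raw, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(raw))                       # centered, exactly orthonormal
    q <- q * sqrt(nr * nc - 1)               # unit sample variance
    w <- q %*% R                             # realized correlation == target
    lapply(seq_len(p), function(i) matrix(w[, i], nr, nc))
  })
  names(layers) <- spec$layer_names
  current <- env_stack(layers)

  if (is.null(future_shift)) {
    future_shift <- list(future = NULL)
  } else if (is.numeric(future_shift)) {
    future_shift <- list(future = future_shift)
  } else if (is.list(future_shift) && length(future_shift) &&
             all(vapply(future_shift, is.matrix, logical(1)))) {
    future_shift <- list(future = future_shift)   # one scenario of shift fields
  }
  future <- lapply(future_shift, function(sh) {
    if (is.null(sh)) {
      sh <- stats::setNames(rep(0, p), spec$layer_names)
      sh[grepl("^temp", spec$layer_names)] <- 1
    }
    shifted <- lapply(spec$layer_names, function(nm) {
      s <- 0
      if (is.list(sh)) s <- sh[[nm]] %||% 0
      else if (is.numeric(sh) && nm %in% names(sh)) s <- sh[[nm]]
      layers[[nm]] + s
    })
    names(shifted) <- spec$layer_names
    env_stack(shifted)
  })
  list(current = current, future = future)
}

#' Simulate sampled populations on a landscape
#'
#' Places `n_pops` populations at distinct grid cells and draws `n_per_pop`
#' individuals per population, all sharing the population's locality
#' coordinates (cell centre), mirroring locality-based field sampling.
#'
#' @param n_pops,n_per_pop number of populations / individuals each.
#' @param landscape an [env_stack] defining the grid.
#' @param seed integer RNG seed.
#' @return data frame with columns `sample_id`, `locality`, `longitude`,
#'   `latitude`, `row`, `col`.
#' @export
simulate_samples <- function(n_pops, n_per_pop, landscape, seed = 1L) {
  stopifnot(inherits(landscape, "env_stack"))
  if (n_pops < 1 || n_per_pop < 1) stopf("n_pops and n_per_pop must be >= 1")
  cells <- which(landscape$mask)
  if (n_pops > length(cells))
    stopf("n_pops (%d) exceeds the %d available grid cells", n_pops, length(cells))
  with_seed(seed, {
    chosen <- sample(cells, n_pops)
    ri <- (chosen - 1L) %% landscape$nrow + 1L
    ci <- (chosen - 1L) %/% landscape$nrow + 1L
    pop <- sprintf("L%02d", seq_len(n_pops))
    data.frame(
      sample_id = sprintf("%s_I%03d", rep(pop, each = n_per_pop),
                          rep(seq_len(n_per_pop), n_pops)),
      locality = rep(pop, each = n_per_pop),
      longitude = rep(ci - 0.5, each = n_per_pop),
      latitude = rep(ri - 0.5, each = n_per_pop),
      row = rep(ri, each = n_per_pop),
      col = rep(ci, each = n_per_pop),
      stringsAsFactors = FALSE)
  })
}

#' Ground-truth table for simulated genotypes
#'
#' Records which loci are adaptive, which environmental layer drives each,
#' the logistic-cline slope per environmental s.d., and the neutral
#' differentiation model (number of ancestral components and target
#' multi-locus FST).
#'
#' @param ancestral_K number of ancestral populations for the neutral
#'   admixture model.
#' @param target_fst target multi-locus FST in `[0, 0.5]`.
#' @param adaptive_locus_ids character ids of adaptive loci (may be empty).
#' @param causal_env_by_locus named character: locus id -> layer name.
#' @param effect_size_by_locus named numeric: locus id -> cline slope.
#' @return object of class `truth_table`.
#' @export
truth_table <- function(ancestral_K, target_fst,
                        adaptive_locus_ids = character(0),
                        causal_env_by_locus = character(0),
                        effect_size_by_locus = numeric(0)) {
  if (target_fst < 0 || target_fst > 0.5) stopf("target_fst must be in [0, 0.5]")
  if (ancestral_K < 1) stopf("ancestral_K must be >= 1")
  if (length(adaptive_locus_ids)) {
    if (!all(adaptive_locus_ids %in% names(causal_env_by_locus)) ||
        !all(adaptive_locus_ids %in% names(effect_size_by_locus)))
      stopf("causal_env_by_locus and effect_size_by_locus must cover every adaptive locus")
    if (any(!is.finite(effect_size_by_locus))) stopf("effect sizes must be finite")
  }
  structure(list(adaptive_locus_ids = adaptive_locus_ids,
                 causal_env_by_locus = causal_env_by_locus,
                 effect_size_by_locus = effect_size_by_locus,
                 ancestral_K = as.integer(ancestral_K),
                 target_fst = target_fst),
            class = "truth_table")
}

#' Convenience constructor for a truth table with uniform adaptive effects
#'
#' @param n_adaptive number of adaptive loci.
#' @param causal_env layer name(s) driving them (recycled).
#' @param effect_size cline slope(s) per env s.d. (recycled).
#' @inheritParams truth_table
#' @return object of class `truth_table`.
#' @export
make_truth <- function(ancestral_K, target_fst, n_adaptive = 0,
                       causal_env = character(0), effect_size = numeric(0)) {
  ids <- if (n_adaptive > 0) sprintf("adaptive_%04d", seq_len(n_adaptive)) else character(0)
  truth_table(ancestral_K, target_fst, ids,
              stats::setNames(rep_len(causal_env, length(ids)), ids),
              stats::setNames(rep_len(effect_size, length(ids)), ids))
}

#' Simulate diploid genotypes with planted environmental clines
#'
#' Neutral loci follow a Balding-Nichols admixture model: ancestral
#' components are differentiated at the target FST (beta-distributed
#' component frequencies) and populations mix them with spatially smooth,
#' fairly concentrated admixture proportions.  Adaptive loci have
#' population allele frequencies following a logistic cline in their causal
#' (standardized) environmental layer with the stated slope.  Dosages are
#' binomial(2, p) draws; missingness is completely at random.
#'
#' @param samples output of [simulate_samples()].
#' @param landscape the current [env_stack].
#' @param n_neutral number of neutral loci.
#' @param truth a [truth_table]; its `adaptive_locus_ids` define the
#'   adaptive loci.
#' @param missing_rate fraction of entries set missing, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param n_chrom number of synthetic chromosomes positions are spread over.
#' @param admix_concentration softmax sharpness of admixture proportions;
#'   larger values give purer populations.
#' @return list with `genotypes` (a [genotype_matrix]) and `truth` (the
#'   input truth table).
#' @export
simulate_genotypes <- function(samples, landscape, n_neutral, truth,
                               missing_rate = 0, seed = 1L, n_chrom = 2L,
                               admix_concentration = 8) {
  stopifnot(inherits(truth, "truth_table"), inherits(landscape, "env_stack"))
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  n_adaptive <- length(truth$adaptive_locus_ids)
  if (n_neutral + n_adaptive < 1) stopf("need at least one locus")
  if (n_adaptive &&
      !all(truth$causal_env_by_locus %in% names(landscape$layers)))
    stopf("causal env layers missing from landscape")

  pops <- unique(samples[, c("locality", "row", "col")])
  n_pops <- nrow(pops)
  pop_idx <- match(samples$locality, pops$locality)
  cell <- cbind(pops$row, pops$col)
  K <- truth$ancestral_K
  Fst <- truth$target_fst

  res <- with_seed(seed, {
    # Admixture proportions decay smoothly with distance from K ancestral
    # "centres of origin" anchored at well-separated population cells
    # (maximin greedy choice), giving isolation-by-distance-like structure
    # in which each component dominates somewhere on the landscape.
    Q <- if (K == 1) matrix(1, n_pops, 1) else {
      xy <- cbind(pops$col - 0.5, pops$row - 0.5)
      centers <- integer(K)
      centers[1] <- sample(n_pops, 1)
      if (K > 1) for (k in 2:min(K, n_pops)) {
        d_min <- apply(as.matrix(dist(xy))[, centers[seq_len(k - 1)], drop = FALSE], 1, min)
        centers[k] <- which.max(d_min)
      }
      if (K > n_pops) centers[(n_pops + 1):K] <- sample(n_pops, K - n_pops, replace = TRUE)
      dd <- sqrt(outer(xy[, 1], xy[centers, 1], "-")^2 +
                 outer(xy[, 2], xy[centers, 2], "-")^2)
      # decay at the scale of the spacing between ancestral centres (median
      # nearest-other-centre distance), so each component separates from
      # its neighbours regardless of the overall extent of the range
      dcc <- as.matrix(dist(xy[centers, , drop = FALSE]))
      diag(dcc) <- Inf
      dscale <- max(median(apply(dcc, 1, min)), 1e-9)
      noise <- matrix(rnorm(n_pops * K, sd = 0.25), n_pops, K)
      softmax_rows(admix_concentration * (-dd / dscale + noise))
    }

    # Neutral: Balding-Nichols component frequencies.  Admixture dilutes
    # population-level differentiation by a factor ~ mean_i ||Q_i - Qbar||^2,
    # so the component-level F is inflated by that factor to make the
    # realized multi-locus FST across populations hit target_fst.
    # realized FST ~ F * m / (1 - F*m): m is the sample variance (over
    # populations) of the admixture vectors; the denominator term accounts
    # for the heterozygosity lost to among-population differentiation
    p0 <- runif(n_neutral, 0.1, 0.9)
    mix_dilution <- if (K > 1 && n_pops > 1)
      sum((Q - matrix(colMeans(Q), n_pops, K, byrow = TRUE))^2) / (n_pops - 1)
      else 1
    F_eff <- if (Fst > 0 && K > 1)
      min(Fst / (max(mix_dilution, 1e-6) * (1 + Fst)), 0.6) else Fst
    G <- if (F_eff > 0 && K > 1) {
      a <- p0 * (1 - F_eff) / F_eff
      b <- (1 - p0) * (1 - F_eff) / F_eff
      matrix(rbeta(K * n_neutral, rep(a, each = K), rep(b, each = K)), K, n_neutral)
    } else matrix(rep(p0, each = K), K, n_neutral)
    pop_freq_neutral <- Q %*% G

    # adaptive: logistic cline in the causal standardized layer
    pop_freq_adaptive <- if (n_adaptive) {
      vapply(truth$adaptive_locus_ids, function(id) {
        env <- landscape$layers[[truth$causal_env_by_locus[[id]]]][cell]
        env <- (env - mean(env)) / max(sd(env), 1e-12)
        plogis(qlogis(runif(1, 0.3, 0.7)) + truth$effect_size_by_locus[[id]] * env)
      }, numeric(n_pops))
    } else matrix(numeric(0), n_pops, 0)

    pop_freq <- cbind(pop_freq_neutral, pop_freq_adaptive)
    ids <- c(sprintf("snp_%05d", seq_len(n_neutral)), truth$adaptive_locus_ids)
    ord <- sample(ncol(pop_freq))            # interleave adaptive among neutral
    pop_freq <- pop_freq[, ord, drop = FALSE]
    ids <- ids[ord]

    n <- nrow(samples); L <- length(ids)
    dos <- matrix(rbinom(n * L, 2, pop_freq[pop_idx, , drop = FALSE]), n, L)
    if (missing_rate > 0)
      dos[matrix(runif(n * L) < missing_rate, n, L)] <- NA_integer_

    chrom <- sprintf("chr%d", rep_len(seq_len(n_chrom), L))
    pos <- integer(L)
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- cumsum(sample(200:2000, length(i), replace = TRUE))
    }
    list(dos = dos, ids = ids, chrom = chrom, pos = pos, Q = Q)
  })

  snp_meta <- data.frame(id = res$ids, chrom = res$chrom, pos = res$pos,
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  sample_meta <- samples[, c("sample_id", "locality", "longitude", "latitude")]
  names(sample_meta)[1] <- "id"
  gm <- genotype_matrix(res$dos, snp_meta, sample_meta)
  truth$Q_pop <- res$Q              # realized per-population admixture
  rownames(truth$Q_pop) <- pops$locality
  truth$component_by_sample <- apply(res$Q, 1, which.max)[pop_idx]
  list(genotypes = gm, truth = truth)
}

#' Write a truth table as JSON
#' @param truth a [truth_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
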