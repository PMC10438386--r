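#' Maximum number of splits for density standardization
#'
#' `log2(0.368 p) / 2` for `p` predictor variables, the binning /
#' partition-depth control used when density-standardizing split
#' importances (it guarantees at least two points per partition).
#'
#' @param p number of predictor variables with `0.368 p > 1`.
#' @return the (non-integer) maximum number of splits.
#' @export
max_splits <- function(p) {
  if (p < 1 || 0.368 * p <= 1)
    stopf("max_splits needs 0.368 * p > 1 (p = %s)", format(p))
  log2(0.368 * p) / 2
}

# number of density-standardization bins derived from max_splits
turnover_bins <- function(p) max(2L, as.integer(ceiling(max_splits(p))))

#' Fit a gradient-forest allelic-turnover model
#'
#' Per SNP, a regression forest of allele frequency (dosage / 2) on the
#' environmental and spatial predictors; per-variable importance comes from
#' permutation on out-of-bag samples, conditioned within clusters of
#' correlated predictors (values are permuted within observation groups
#' formed by the medians of predictors correlated at `|r| > cor_threshold`).
#' SNPs with out-of-bag R-squared <= 0 are excluded from aggregation.  The
#' turnover function of each variable is the cumulative distribution of
#' split improvements along that predictor, density-standardized over
#' [turnover_bins()] equal-width bins, aggregated over SNPs weighted by
#' R-squared, and scaled so its total height equals the variable's
#' R-squared-weighted importance.
#'
#' @param gm_subset an imputed [genotype_matrix] holding the SNP set
#'   (adaptive or neutral) to model.
#' @param predictors data frame, sites x variables (environmental values
#'   plus PCNM eigenvectors), one row per individual in `gm_subset`.
#' @param n_trees trees per SNP forest (default 500).
#' @param mtry candidate variables per split; default `ceiling(p / 3)`.
#' @param min_node minimum node size to attempt a split (default 5).
#' @param cor_threshold absolute correlation defining predictor clusters for
#'   conditional permutation (default 0.5).
#' @param seed integer RNG seed.
#' @param snp_set_label `"adaptive"` or `"neutral"`, recorded on the model.
#' @return object of class `turnover_model`: `functions` (per variable,
#'   `knots` and non-decreasing `heights` starting at 0), `importance`
#'   (R-squared-weighted, per variable), `r2` (per SNP, out-of-bag),
#'   `n_trees`, `bins`, `snp_set_label`, `predictor_range`.
#' @export
fit_gradient_forest <- function(gm_subset, predictors, n_trees = 500,
                                mtry = NULL, min_node = 5,
                                cor_threshold = 0.5, seed = 1L,
                                snp_set_label = "adaptive") {
  X <- as.matrix(as.data.frame(predictors))
  storage.mode(X) <- "double"
  if (anyNA(X)) stopf("predictors must be complete")
  dos <- gm_subset$dosages
  if (anyNA(dos)) stopf("genotypes must be imputed before fit_gradient_forest")
  if (nrow(X) != nrow(dos)) stopf("predictors must have one row per individual")
  p <- ncol(X)
  if (any(apply(X, 2, function(x) length(unique(x))) < 2))
    stopf("every predictor needs at least 2 distinct values")
  if (is.null(mtry)) mtry <- ceiling(p / 3)

  # observation groups for cluster-conditional permutation: for variable v,
  # cells of the median-split grid of its correlated partners (at most two)
  cm <- abs(suppressWarnings(cor(X)))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  obs_group <- matrix(0L, nrow(X), p)
  for (v in seq_len(p)) {
    partners <- order(cm[, v], decreasing = TRUE)
    partners <- partners[cm[partners, v] > cor_threshold]
    partners <- head(partners, 2)
    if (length(partners)) {
      g <- rep(0L, nrow(X))
      for (w in partners) g <- g * 2L + as.integer(X[, w] > median(X[, w]))
      obs_group[, v] <- g
    }
  }

  L <- ncol(dos)
  fits <- with_seed(seed, lapply(seq_len(L), function(j) {
    .rf_fit(X, dos[, j] / 2, as.integer(n_trees), as.integer(mtry),
            as.integer(min_node), obs_group)
  }))

  y_var <- apply(dos / 2, 2, var)
  r2 <- vapply(seq_len(L), function(j) {
    f <- fits[[j]]
    ok <- !is.na(f$oob_pred)
    if (!any(ok) || y_var[j] == 0) return(NA_real_)
    1 - mean((f$oob_pred[ok] - dos[ok, j] / 2)^2) / y_var[j]
  }, numeric(1))
  names(r2) <- gm_subset$snp_meta$id
  include <- which(!is.na(r2) & r2 > 0)
  if (!length(include))
    stopf("no SNP achieved positive out-of-bag R-squared; the SNP set carries no predictable signal")

  bins <- turnover_bins(p)
  rng <- apply(X, 2, range)
  # per-variable bin densities of the training data (for standardization)
  dens <- lapply(seq_len(p), function(v) {
    br <- seq(rng[1, v], rng[2, v], length.out = bins + 1)
    d <- tabulate(pmin(findInterval(X[, v], br, rightmost.closed = TRUE), bins),
                  nbins = bins)
    pmax(d / nrow(X), 1 / (10 * nrow(X)))
  })

  # R2-weighted importances: per included SNP scale nonneg permutation
  # importances to sum to its R2, then average over SNPs
  imp_mat <- matrix(0, length(include), p)
  for (k in seq_along(include)) {
    raw <- pmax(fits[[include[k]]]$importance, 0)
    if (sum(raw) > 0) imp_mat[k, ] <- raw / sum(raw) * r2[include[k]]
  }
  importance <- colMeans(imp_mat)
  names(importance) <- colnames(X)

  functions <- vector("list", p)
  names(functions) <- colnames(X)
  for (v in seq_len(p)) {
    knots <- heights <- numeric(0)
    sp_val <- numeric(0); sp_w <- numeric(0)
    for (k in seq_along(include)) {
      f <- fits[[include[k]]]
      rows <- which(f$splits[, 1] == v)
      if (!length(rows)) next
      val <- f$splits[rows, 2]
      w <- f$splits[rows, 3]
      # density standardization
      br <- seq(rng[1, v], rng[2, v], length.out = bins + 1)
      b <- pmin(pmax(findInterval(val, br, rightmost.closed = TRUE), 1L), bins)
      w <- w / dens[[v]][b]
      if (sum(w) > 0 && imp_mat[k, v] > 0) {
        sp_val <- c(sp_val, val)
        sp_w <- c(sp_w, w / sum(w) * imp_mat[k, v])
      }
    }
    if (length(sp_val)) {
      # a split can land exactly on the predictor minimum in floating
      # point; nudge it right so the function stays 0 at the minimum
      span <- max(rng[2, v] - rng[1, v], 1e-12)
      sp_val[sp_val <= rng[1, v]] <- rng[1, v] + 1e-9 * span
      o <- order(sp_val)
      val <- sp_val[o]; w <- sp_w[o]
      grp <- cumsum(c(TRUE, diff(val) != 0))
      uval <- val[!duplicated(grp)]
      agg_w <- as.numeric(rowsum(w, grp))
      cum <- cumsum(agg_w) / length(include)
      knots <- c(rng[1, v], uval)
      heights <- c(0, cum)
    } else {
      knots <- rng[, v]
      heights <- c(0, 0)
    }
    functions[[v]] <- list(knots = unname(knots), heights = unname(heights))
  }

  structure(list(functions = functions, importance = importance, r2 = r2,
                 n_trees = as.integer(n_trees), bins = bins,
                 snp_set_label = snp_set_label,
                 predictor_range = rng,
                 predictor_names = colnames(X)),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf("turnover_model (%s set): %d SNPs (%d with R2 > 0), %d predictors, %d trees\n",
              x$snp_set_label, length(x$r2), sum(x$r2 > 0, na.rm = TRUE),
              length(x$functions), x$n_trees))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("importance:", paste(sprintf("%s=%.4g", names(imp), imp), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate turnover functions at new predictor values
#'
#' Linear interpolation between knots, clamped (constant) beyond the
#' training range; values below the training minimum map to 0.
#'
#' @param model a [fit_gradient_forest()] `turnover_model`.
#' @param newdata data frame / matrix with the model's predictor columns.
#' @return matrix, rows x predictors, of turnover-transformed values.
#' @export
turnover_transform <- function(model, newdata) {
  newdata <- as.matrix(as.data.frame(newdata))
  miss <- setdiff(model$predictor_names, colnames(newdata))
  if (length(miss)) stopf("missing predictor(s): %s", paste(miss, collapse = ", "))
  out <- vapply(model$predictor_names, function(v) {
    f <- model$functions[[v]]
    if (length(f$knots) == 1)
      return(rep(f$heights[1], nrow(newdata)))
    approx(f$knots, f$heights, xout = newdata[, v], rule = 2,
           ties = "ordered")$y
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, model$predictor_names))
  out
}

#' Project allelic turnover over a raster grid
#'
#' Maps every masked-in cell's predictor vector through the model's
#' turnover functions and summarizes the transformed vectors by PCA over
#' the mask (PC1-PC3 retained).
#'
#' @param model a `turnover_model`.
#' @param stack an [env_stack] containing every model predictor (append
#'   [pcnm_layers()] output for the spatial predictors).
#' @return object of class `turnover_grid`: `turnover` (cells x predictors),
#'   `scores` (cells x <=3 PCA scores, centered over the mask), `cells`,
#'   `mask`, `nrow`, `ncol`, `predictor_names`.
#' @export
project_turnover <- function(model, stack) {
  miss <- setdiff(model$predictor_names, names(stack$layers))
  if (length(miss)) stopf("missing predictor layer(s): %s", paste(miss, collapse = ", "))
  cells <- which(stack$mask)
  m <- stack_matrix(stack, cells)[, model$predictor_names, drop = FALSE]
  tv <- turnover_transform(model, m)
  npc <- min(3L, ncol(tv), nrow(tv) - 1L)
  pc <- prcomp(tv, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(npc), drop = FALSE]
  structure(list(turnover = tv, scores = scores, cells = cells,
                 mask = stack$mask, nrow = stack$nrow, ncol = stack$ncol,
                 predictor_names = model$predictor_names),
            class = "turnover_grid")
}

#' Procrustes residuals between adaptive and neutral turnover projections
#'
#' Superimposes the neutral PCA scores onto the adaptive scores by
#' orthogonal Procrustes rotation (translation, rotation/reflection,
#' isotropic scaling, via [vegan::procrustes()]) and returns the per-cell
#' Euclidean residual distance, mapping where adaptive genomic variation
#' deviates from neutral variation.
#'
#' @param adaptive,neutral `turnover_grid`s sharing mask and PCA
#'   dimensionality.
#' @return list with `residuals` (per masked-in cell), `grid` (matrix with
#'   residuals at mask cells, NA elsewhere), and the `vegan` fit.
#' @export
procrustes_residuals <- function(adaptive, neutral) {
  if (!identical(adaptive$cells, neutral$cells) ||
      !identical(dim(adaptive$mask), dim(neutral$mask)))
    stopf("adaptive and neutral grids must share one mask")
  if (ncol(adaptive$scores) != ncol(neutral$scores))
    stopf("PCA dimensionality differs between grids")
  fit <- vegan::procrustes(adaptive$scores, neutral$scores, symmetric = FALSE,
                           scale = TRUE)
  res <- unname(stats::residuals(fit))
  grid <- matrix(NA_real_, adaptive$nrow, adaptive$ncol)
  grid[adaptive$cells] <- res
  list(residuals = res, grid = grid, fit = fit)
}

#' Serialize a turnover model as JSON
#' @param model a `turnover_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_turnover_json <- function(model, path) {
  obj <- list(snp_set_label = model$snp_set_label, n_trees = model$n_trees,
              bins = model$bins, importance = as.list(model$importance),
              functions = model$functions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
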