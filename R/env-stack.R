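#' Environmental raster stack
#'
#' A set of named, co-registered raster layers stored as numeric matrices
#' (rows = grid rows from the top, columns = grid columns), together with a
#' per-layer kind (`"continuous"` or `"categorical"`) and a logical mask of
#' in-range cells.  Cell centres sit at planar coordinates
#' `(col - 0.5, row - 0.5)`, so a grid with `nc` columns spans `x` in
#' `[0, nc]` and `y` in `[0, nr]`.
#'
#' @param layers named list of numeric matrices sharing one dimension.
#' @param kind character vector (recycled) of `"continuous"`/`"categorical"`.
#' @param mask logical matrix of in-range cells; default all `TRUE`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, kind = "continuous", mask = NULL) {
  if (!length(layers)) stopf("env_stack needs at least one layer")
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stopf("layers must have unique names")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all layers must share one grid dimension (co-registration)")
  kind <- rep_len(kind, length(layers))
  if (!all(kind %in% c("continuous", "categorical")))
    stopf("kind must be 'continuous' or 'categorical'")
  names(kind) <- names(layers)
  if (is.null(mask)) mask <- matrix(TRUE, dims[1, 1], dims[2, 1])
  if (!identical(dim(mask), dim(layers[[1]])))
    stopf("mask dimension does not match layers")
  structure(list(layers = layers, kind = kind, mask = mask,
                 nrow = dims[1, 1], ncol = dims[2, 1]),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s), %d x %d grid, %d masked-in cells\n",
              length(x$layers), x$nrow, x$ncol, sum(x$mask)))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# cells x layers matrix over masked-in cells (column-major cell order)
stack_matrix <- function(stack, cells = which(stack$mask)) {
  m <- vapply(stack$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  m
}

#' Read / write a headered ASCII grid (ESRI .asc)
#'
#' Plain-text raster interchange used for all layer i/o: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, northernmost row first.
#'
#' @param path file path.
#' @param layer numeric matrix (row 1 = northernmost row).
#' @param cellsize,xll,yll grid geometry written into the header.
#' @return `read_ascii_grid` returns a numeric matrix with attributes
#'   `cellsize`, `xll`, `yll`; `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(layer, path, cellsize = 1, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(layer)),
    sprintf("nrows %d", nrow(layer)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    "NODATA_value -9999"), con)
  vals <- layer
  vals[is.na(vals)] <- -9999
  writeLines(apply(vals, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) stopf("'%s': expected %d values, found %d", path, nr * nc, length(body))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  structure(m, cellsize = vals[["cellsize"]], xll = vals[["xllcorner"]],
            yll = vals[["yllcorner"]])
}

#' Resample a raster layer to a new grid
#'
#' Continuous layers are resampled by bilinear interpolation, categorical
#' layers by nearest neighbour, the standard convention when harmonising
#' predictor rasters of mixed type onto one analysis grid.
#'
#' @param layer numeric matrix (source grid; cell centres at
#'   `(col - 0.5, row - 0.5)` of the unit-cell source frame).
#' @param target_nrow,target_ncol dimension of the target grid, which covers
#'   the same extent as the source.
#' @param kind `"continuous"` (bilinear) or `"categorical"` (nearest).
#' @return numeric matrix of dimension `target_nrow` x `target_ncol`.
#' @export
resample_to_grid <- function(layer, target_nrow, target_ncol,
                             kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  nr <- nrow(layer); nc <- ncol(layer)
  if (target_nrow < 1 || target_ncol < 1) stopf("target grid is empty (disjoint extent)")
  # target cell centres expressed in source cell units
  ys <- (seq_len(target_nrow) - 0.5) * nr / target_nrow
  xs <- (seq_len(target_ncol) - 0.5) * nc / target_ncol
  if (kind == "categorical") {
    ri <- pmin(pmax(ceiling(ys), 1L), nr)
    ci <- pmin(pmax(ceiling(xs), 1L), nc)
    return(layer[ri, ci, drop = FALSE])
  }
  # bilinear between the four surrounding source cell centres, clamped at edges
  interp_axis <- function(z, n) {
    f <- z - 0.5
    i0 <- pmin(pmax(floor(f) + 1L, 1L), n)
    i1 <- pmin(i0 + 1L, n)
    w <- f - (i0 - 1L)
    w[f < 0] <- 0; w[f > n - 1] <- 1
    list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
  }
  ay <- interp_axis(ys, nr); ax <- interp_axis(xs, nc)
  top <- layer[ay$i0, ax$i0, drop = FALSE] * outer(1 - ay$w, 1 - ax$w) +
    layer[ay$i0, ax$i1, drop = FALSE] * outer(1 - ay$w, ax$w)
  bot <- layer[ay$i1, ax$i0, drop = FALSE] * outer(ay$w, 1 - ax$w) +
    layer[ay$i1, ax$i1, drop = FALSE] * outer(ay$w, ax$w)
  top + bot
}

#' Extract layer values at point coordinates
#'
#' Returns the value of the containing cell of every layer for each site, in
#' the stack's planar coordinate frame.
#'
#' @param stack an [env_stack].
#' @param coords data frame or matrix with columns `x` and `y` (planar
#'   coordinates; `x` in `[0, ncol]`, `y` in `[0, nrow]`, `y` measured from
#'   the top row).
#' @return data frame, one row per site, one column per layer, plus a
#'   logical column `in_mask`.
#' @export
extract_at_points <- function(stack, coords) {
  coords <- as.data.frame(coords)
  x <- coords$x %||% coords[[1]]
  y <- coords$y %||% coords[[2]]
  bad <- which(x < 0 | x > stack$ncol | y < 0 | y > stack$nrow | is.na(x) | is.na(y))
  if (length(bad))
    stopf("coordinates outside grid extent for site(s): %s",
          paste(bad, collapse = ", "))
  ci <- pmin(pmax(ceiling(x), 1L), stack$ncol)
  ri <- pmin(pmax(ceiling(y), 1L), stack$nrow)
  idx <- cbind(ri, ci)
  out <- as.data.frame(lapply(stack$layers, function(l) l[idx]))
  out$in_mask <- stack$mask[idx]
  out
}

#' Drop highly intercorrelated variables
#'
#' Iteratively, while any variable pair exceeds the absolute-correlation
#' threshold, the member of the worst pair with the larger mean absolute
#' correlation against all remaining variables is removed and correlations
#' recomputed.  Ties are broken by removing the later column.
#'
#' @param table data frame or matrix, sites x variables.
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.7).
#' @return list with `table` (reduced) and `removed` (character vector, in
#'   removal order).
#' @export
prune_correlated <- function(table, threshold = 0.7) {
  tab <- as.data.frame(table)
  if (ncol(tab) < 2) return(list(table = tab, removed = character(0)))
  if (nrow(tab) < 2) stopf("need at least 2 sites to compute correlations")
  removed <- character(0)
  repeat {
    if (ncol(tab) < 2) break
    cm <- abs(cor(tab))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0   # constant columns correlate with nothing
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    meanabs <- rowMeans(cm)
    cand <- c(worst[["row"]], worst[["col"]])
    drop_i <- if (meanabs[cand[1]] > meanabs[cand[2]]) cand[1]
      else if (meanabs[cand[2]] > meanabs[cand[1]]) cand[2]
      else max(cand)
    removed <- c(removed, colnames(tab)[drop_i])
    tab <- tab[, -drop_i, drop = FALSE]
  }
  list(table = tab, removed = removed)
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Spatial eigenvectors from the truncated pairwise-distance matrix of the
#' sites: distances beyond the truncation are replaced by four times the
#' truncation, the matrix is double-centred and eigen-decomposed, and of the
#' positive-eigenvalue vectors the half with the largest eigenvalues
#' (broadest spatial scales) is kept.  The decomposition itself is done by
#' [vegan::pcnm()]; automatic truncation is the longest edge of the minimum
#' spanning tree.
#'
#' @param coords matrix/data frame of site coordinates (columns x, y).
#' @param truncation distance threshold, or `"auto"`.
#' @return list of class `spatial_vectors` with `vectors` (sites x kept),
#'   `eigenvalues` (descending, positive), `truncation_distance`.
#' @export
pcnm_vectors <- function(coords, truncation = "auto") {
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  if (nrow(unique(coords)) < 3) stopf("need at least 3 distinct sites for PCNM")
  d <- dist(coords)
  if (max(d) == 0) stopf("all sites identical: PCNM undefined")
  fit <- if (identical(truncation, "auto")) vegan::pcnm(d)
         else vegan::pcnm(d, threshold = truncation)
  pos <- fit$values > 1e-8
  npos <- sum(pos)
  keep <- seq_len(ceiling(npos / 2))
  v <- fit$vectors[, keep, drop = FALSE]
  colnames(v) <- paste0("PCNM", keep)
  structure(list(vectors = v,
                 eigenvalues = fit$values[keep],
                 truncation_distance = fit$threshold),
            class = "spatial_vectors")
}

#' Interpolate PCNM eigenvectors over a raster grid
#'
#' Turns site-based spatial eigenvectors into raster layers usable as
#' predictors for grid projection, by inverse-distance-squared weighting of
#' the site scores at every masked-in cell.
#'
#' @param sv a `spatial_vectors` object from [pcnm_vectors()].
#' @param coords the site coordinates the vectors were built from.
#' @param stack the target [env_stack] defining grid and mask.
#' @return named list of matrices, one per kept eigenvector.
#' @export
pcnm_layers <- function(sv, coords, stack) {
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  cells <- which(stack$mask)
  ri <- (cells - 1L) %% stack$nrow + 1L
  ci <- (cells - 1L) %/% stack$nrow + 1L
  cx <- ci - 0.5; cy <- ri - 0.5
  d2 <- outer(cx, coords[, 1], "-")^2 + outer(cy, coords[, 2], "-")^2
  w <- 1 / pmax(d2, 1e-6)
  w <- w / rowSums(w)
  scores <- w %*% sv$vectors
  lapply(stats::setNames(seq_len(ncol(scores)), colnames(sv$vectors)), function(j) {
    m <- matrix(NA_real_, stack$nrow, stack$ncol)
    m[cells] <- scores[, j]
    m
  })
}
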