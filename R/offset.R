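#' Future climate scenario specification
#'
#' @param gcm general circulation model name (non-empty).
#' @param ssp shared socioeconomic pathway: 126, 245, 370 or 585.
#' @param period 20-year window: `"2021-2040"`, `"2041-2060"`,
#'   `"2061-2080"` or `"2081-2100"`.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(gcm, ssp, period) {
  ssp <- as.integer(ssp)
  if (!nzchar(gcm)) stopf("gcm must be non-empty")
  if (!ssp %in% c(126L, 245L, 370L, 585L)) stopf("ssp must be one of 126, 245, 370, 585")
  periods <- c("2021-2040", "2041-2060", "2061-2080", "2081-2100")
  if (!period %in% periods) stopf("period must be one of %s", paste(periods, collapse = ", "))
  structure(list(gcm = gcm, ssp = ssp, period = period), class = "scenario_spec")
}

#' Genomic offset between current and future turnover grids
#'
#' Per grid cell, the Euclidean distance in turnover space between the
#' current and future environment: the square root of the sum over
#' predictors of squared differences of turnover-transformed values, the
#' required allelic change to track the environmental shift.  Set
#' `sqrt = FALSE` to keep the raw sum of squares instead of its root; the
#' two are monotonically related.
#'
#' @param current,future `turnover_grid`s sharing mask and predictor set.
#' @param scenario optional [scenario_spec] recorded on the map.
#' @param sqrt apply the square root (default `TRUE`, the Euclidean
#'   distance).
#' @return object of class `offset_map`: `raw` (per masked-in cell),
#'   `grid` (matrix form), `scenario`, `scaled` (`NULL` until
#'   [scale_offsets()]), `cells`, `mask`.
#' @export
genomic_offset <- function(current, future, scenario = NULL, sqrt = TRUE) {
  if (!identical(current$predictor_names, future$predictor_names))
    stopf("predictor sets differ between current and future grids")
  if (!identical(current$cells, future$cells))
    stopf("grids do not share a mask")
  d2 <- rowSums((future$turnover - current$turnover)^2)
  raw <- if (sqrt) base::sqrt(d2) else d2
  grid <- matrix(NA_real_, current$nrow, current$ncol)
  grid[current$cells] <- raw
  structure(list(raw = raw, grid = grid, scenario = scenario, scaled = NULL,
                 cells = current$cells, mask = current$mask,
                 nrow = current$nrow, ncol = current$ncol),
            class = "offset_map")
}

#' Min-max scale offsets across all scenarios
#'
#' The scaling constants (global minimum and maximum) are pooled over every
#' cell of every scenario of one species run, so scaled maps are comparable
#' across SSPs and periods.  If all values are equal the scaled maps are 0
#' and a degenerate-scaling warning is issued.
#'
#' @param offsets list of `offset_map`s sharing one mask.
#' @return the same list with `scaled` fields filled in (values in
#'   `[0, 1]`) and attributes `min`/`max` holding the pooled constants.
#' @export
scale_offsets <- function(offsets) {
  if (!length(offsets)) stopf("empty offset collection")
  if (inherits(offsets, "offset_map")) offsets <- list(offsets)
  cells <- offsets[[1]]$cells
  for (m in offsets) if (!identical(m$cells, cells)) stopf("offset maps do not share a mask")
  pooled <- unlist(lapply(offsets, `[[`, "raw"))
  lo <- min(pooled); hi <- max(pooled)
  if (hi == lo) {
    warning("degenerate min-max scaling: all offsets equal; scaled values set to 0")
    scale1 <- function(x) rep(0, length(x))
  } else scale1 <- function(x) (x - lo) / (hi - lo)
  out <- lapply(offsets, function(m) {
    m$scaled <- scale1(m$raw)
    sg <- matrix(NA_real_, m$nrow, m$ncol)
    sg[m$cells] <- m$scaled
    m$scaled_grid <- sg
    m
  })
  attr(out, "min") <- lo
  attr(out, "max") <- hi
  out
}

#' Per-variable contributions to the genomic offset
#'
#' Per cell, the contribution of a variable is its squared turnover
#' difference divided by the summed squared differences; cells with zero
#' offset are undefined (NA).  The range mean is the mean over defined
#' cells.
#'
#' @inheritParams genomic_offset
#' @return list with `fractions` (cells x variables) and `range_mean`
#'   (named per-variable means over defined cells).
#' @export
variable_contributions <- function(current, future) {
  if (!identical(current$predictor_names, future$predictor_names))
    stopf("predictor sets differ between current and future grids")
  if (!identical(current$cells, future$cells)) stopf("grids do not share a mask")
  d2 <- (future$turnover - current$turnover)^2
  tot <- rowSums(d2)
  frac <- d2 / tot
  frac[tot == 0, ] <- NA_real_
  colnames(frac) <- current$predictor_names
  list(fractions = frac,
       range_mean = colMeans(frac, na.rm = TRUE))
}

#' Seed-source genomic similarity map
#'
#' The restoration site's predictor vector under the future scenario is
#' transformed through the turnover model; every cell of the current
#' landscape is compared to it by Euclidean distance in turnover space.
#' Distances are min-max scaled over the mask and reversed, so 1 marks the
#' most genomically similar current seed sources and 0 the most dissimilar.
#'
#' @param site numeric `c(x, y)` planar coordinates of the restoration
#'   site (must fall on a masked-in cell).
#' @param model a `turnover_model` (adaptive-SNP model by default in the
#'   pipeline).
#' @param current_stack,future_stack co-registered [env_stack]s holding
#'   every model predictor for the current landscape and the future
#'   scenario.
#' @param scenario optional [scenario_spec] recorded on the result.
#' @return object of class `similarity_map`: `similarity` (per masked-in
#'   cell, in `[0, 1]`), `grid` (matrix form), `site`, `site_cell`,
#'   `scenario`.
#' @export
similarity_map <- function(site, model, current_stack, future_stack,
                           scenario = NULL) {
  if (!identical(dim(current_stack$mask), dim(future_stack$mask)))
    stopf("current and future stacks are not co-registered")
  x <- site[[1]]; y <- site[[2]]
  ci <- ceiling(x); ri <- ceiling(y)
  if (ri < 1 || ri > current_stack$nrow || ci < 1 || ci > current_stack$ncol ||
      !current_stack$mask[ri, ci])
    stopf("restoration site (%.2f, %.2f) is outside the masked range", x, y)
  site_cell <- (ci - 1L) * current_stack$nrow + ri

  fut_vals <- extract_at_points(future_stack, data.frame(x = x, y = y))
  fut_vals <- fut_vals[, setdiff(names(fut_vals), "in_mask"), drop = FALSE]
  site_turnover <- turnover_transform(model, fut_vals)

  cells <- which(current_stack$mask)
  cur <- turnover_transform(model, stack_matrix(current_stack, cells))
  d <- sqrt(rowSums((cur - matrix(site_turnover, nrow(cur), ncol(cur),
                                  byrow = TRUE))^2))
  lo <- min(d); hi <- max(d)
  sim <- if (hi == lo) rep(1, length(d)) else 1 - (d - lo) / (hi - lo)
  grid <- matrix(NA_real_, current_stack$nrow, current_stack$ncol)
  grid[cells] <- sim
  structure(list(similarity = sim, distance = d, grid = grid,
                 site = c(x = x, y = y), site_cell = site_cell,
                 cells = cells, scenario = scenario),
            class = "similarity_map")
}
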