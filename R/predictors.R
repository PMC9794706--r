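#' Aggregate a raster to grid cells by mean
#'
#' Arithmetic mean of the raster values whose pixel centers fall inside each
#' grid cell; `NA` (nodata) pixels are excluded. Membership is by pixel
#' center, matching common resample/zonal-statistics behaviour.
#'
#' @param raster a [grid_raster()] sharing the grid's CRS; its resolution
#'   should not exceed the cell size.
#' @param grid a [grid_spec()].
#' @param fun aggregation function over in-cell pixel values (default
#'   `mean`); it receives values with `NA`s already removed.
#' @return An `n_rows x n_cols` matrix of per-cell values; cells with no
#'   valid pixel are `NA`.
#' @export
aggregate_mean <- function(raster, grid, fun = mean) {
  stopifnot(inherits(raster, "grid_raster"), inherits(grid, "grid_spec"))
  if (raster$cellsize > grid$cell_size) {
    stop("raster resolution is coarser than the analysis cell size")
  }
  px <- pixel_centers(raster)
  loc <- locate_in_grid(px$x, px$y, grid)
  keep <- !is.na(loc$row) & !is.na(px$value)
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  if (!any(keep)) return(out)
  idx <- loc$row[keep] * grid$n_cols + loc$col[keep]   # 0-based linear key
  agg <- tapply(px$value[keep], idx, fun)
  lin <- as.integer(names(agg))
  out[cbind(lin %/% grid$n_cols + 1L, lin %% grid$n_cols + 1L)] <- as.numeric(agg)
  out
}

#' Habitat heterogeneity: per-cell elevational relief
#'
#' Topographic relief of each grid cell, computed as the difference between
#' the maximum and minimum DEM values among pixels whose centers fall in the
#' cell (nodata excluded). Invariant under adding a constant to the DEM.
#'
#' @param dem a DEM [grid_raster()] (m).
#' @inheritParams aggregate_mean
#' @return Matrix of per-cell relief (m); empty cells are `NA`.
#' @export
hhet <- function(dem, grid) {
  mx <- aggregate_mean(dem, grid, fun = max)
  mn <- aggregate_mean(dem, grid, fun = min)
  mx - mn
}

#' Disturbance: human-footprint change per cell
#'
#' Per-cell mean change in the Human Footprint Index (HFI) between two
#' years. With the default `"semantic"` orientation the sign follows the
#' disturbance reading: positive values mean the footprint decreased
#' (habitat undisturbed or restored), negative values mean it increased
#' (disturbance), i.e. DIST = mean(HFI_start - HFI_end). The `"literal"`
#' orientation returns the plain later-minus-earlier difference instead.
#'
#' @param hfi_start,hfi_end aligned HFI [grid_raster()]s for the earlier and
#'   later year.
#' @inheritParams aggregate_mean
#' @param order `"semantic"` (default; start minus end) or `"literal"`
#'   (end minus start).
#' @return Matrix of per-cell signed index change.
#' @export
dist_change <- function(hfi_start, hfi_end, grid, order = c("semantic", "literal")) {
  order <- match.arg(order)
  stop_if_misaligned(hfi_start, hfi_end, "HFI rasters")
  diff_raster <- grid_raster(hfi_start$values - hfi_end$values,
                             hfi_start$xmin, hfi_start$ymin,
                             hfi_start$cellsize, hfi_start$crs)
  out <- aggregate_mean(diff_raster, grid)
  if (order == "literal") -out else out
}

#' Build the per-cell predictor table
#'
#' Assembles the five impact variables at the analysis resolution: mean
#' annual temperature (MAT, degrees C), mean annual precipitation (MAP,
#' mm/yr) and potential evapotranspiration (PET, mm/yr) as per-cell raster
#' means; habitat heterogeneity (HHET, m) as per-cell elevational relief;
#' and disturbance (DIST) as the per-cell human-footprint change. Cells with
#' any missing predictor are dropped and reported via a message.
#'
#' @param rasters named list with elements `dem`, `mat`, `map`, `pet`,
#'   `hfi_start`, `hfi_end`, all aligned [grid_raster()]s.
#' @param grid a [grid_spec()].
#' @param dist_order passed to [dist_change()].
#' @return Data frame with columns `row`, `col` (zero-based cell indices)
#'   and `MAT`, `MAP`, `PET`, `HHET`, `DIST`; complete cases only.
#' @export
predictor_table <- function(rasters, grid, dist_order = "semantic") {
  needed <- c("dem", "mat", "map", "pet", "hfi_start", "hfi_end")
  missing <- setdiff(needed, names(rasters))
  if (length(missing)) {
    stop("missing rasters: ", paste(missing, collapse = ", "))
  }
  for (nm in needed[-1]) stop_if_misaligned(rasters$dem, rasters[[nm]], nm)
  vals <- list(
    MAT = aggregate_mean(rasters$mat, grid),
    MAP = aggregate_mean(rasters$map, grid),
    PET = aggregate_mean(rasters$pet, grid),
    HHET = hhet(rasters$dem, grid),
    DIST = dist_change(rasters$hfi_start, rasters$hfi_end, grid,
                       order = dist_order)
  )
  nr <- grid$n_rows
  nc <- grid$n_cols
  out <- data.frame(
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr)
  )
  for (nm in names(vals)) out[[nm]] <- as.vector(vals[[nm]])
  out <- out[order(out$row, out$col), , drop = FALSE]
  cc <- stats::complete.cases(out)
  if (any(!cc)) {
    message(sprintf("%d cell(s) with missing predictor values dropped",
                    sum(!cc)))
  }
  rownames(out) <- NULL
  out[cc, , drop = FALSE]
}

#' Standardize predictor columns to z-scores
#'
#' Centers and scales the predictor columns so coefficients are comparable
#' across variables; centers and scales are kept as attributes so raw values
#' can be recovered.
#'
#' @param tab a [predictor_table()] result (or any data frame).
#' @param cols columns to standardize.
#' @return `tab` with the named columns replaced by z-scores; attributes
#'   `center` and `scale` record the transformation.
#' @export
standardize_predictors <- function(tab, cols = c("MAT", "MAP", "PET", "HHET", "DIST")) {
  cols <- intersect(cols, names(tab))
  z <- scale(as.matrix(tab[cols]))
  tab[cols] <- as.data.frame(z)
  attr(tab, "center") <- stats::setNames(attr(z, "scaled:center"), cols)
  attr(tab, "scale") <- stats::setNames(attr(z, "scaled:scale"), cols)
  tab
}
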