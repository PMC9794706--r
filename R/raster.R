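#' Single-band raster grids
#'
#' A `grid_raster` is a lightweight single-band raster: a numeric matrix whose
#' first row is the northern edge, plus a geotransform (lower-left corner and
#' square cell size, in the metres of a projected CRS). Missing cells are `NA`.
#' Rasters are exchanged on disk as ESRI ASCII grids (`.asc`), a plain-text
#' single-band format that keeps pipeline artifacts diffable and portable.
#'
#' @param values numeric matrix; row 1 is the top (northernmost) row.
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param cellsize square cell edge (m).
#' @param crs free-text CRS identifier carried through outputs.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin, ymin, cellsize, crs = "local-projected") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d rows x %d cols, cell %g m\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] (%s)\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize, x$crs))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

# Coordinates of every pixel center, row-major from the top-left pixel.
pixel_centers <- function(r) {
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  ymax <- r$ymin + nr * r$cellsize
  list(
    x = rep(r$xmin + (seq_len(nc) - 0.5) * r$cellsize, each = nr),
    y = rep(ymax - (seq_len(nr) - 0.5) * r$cellsize, times = nc),
    value = as.vector(r$values)
  )
}

rasters_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!rasters_aligned(a, b)) {
    stop(sprintf(
      "%s are not aligned: (%g, %g, cell %g, %d x %d) vs (%g, %g, cell %g, %d x %d)",
      what, a$xmin, a$ymin, a$cellsize, nrow(a$values), ncol(a$values),
      b$xmin, b$ymin, b$cellsize, nrow(b$values), ncol(b$values)))
  }
  invisible(TRUE)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' @param r a [grid_raster()].
#' @param path file path (conventionally `.asc`).
#' @param nodata value standing in for `NA` on disk.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [grid_raster()].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  write.table(format(v, digits = 10, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs CRS identifier to attach on read (the format itself carries none).
#' @export
read_ascii_grid <- function(path, crs = "local-projected") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA_real_
  grid_raster(v, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
              cellsize = h[["cellsize"]], crs = crs)
}
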