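#' Analysis grid specification
#'
#' A regular grid of square cells laid over a projected extent, used to
#' aggregate occurrence records and rasters to the analysis resolution
#' (20 km by default). Cells are half-open intervals with a top-left origin:
#' a point on a shared vertical edge belongs to the cell whose left edge it
#' is, and a point on a shared horizontal edge to the cell whose top edge it
#' is. Cell indices `(row, col)` are zero-based from the top-left cell.
#'
#' @param origin_x,origin_y coordinates (m) of the grid's top-left corner.
#' @param cell_size cell edge (m), default 20000.
#' @param n_cols,n_rows grid dimensions (cells).
#' @param crs free-text CRS identifier.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 20000,
                      n_cols, n_rows, crs = "local-projected") {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (top-left %g, %g; %s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

# (row, col) of points in a grid; NA outside the extent.
locate_in_grid <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_size)
  row <- floor((grid$origin_y - y) / grid$cell_size)
  out <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Assign occurrence records to grid cells
#'
#' Maps each occurrence point into its half-open grid cell and collects the
#' per-cell species sets; duplicate records of a species within a cell count
#' once. Points outside the grid extent are excluded and reported in the
#' `rejects` attribute. If a `region` is supplied, each cell also gets the
#' fraction of its area inside the study region (`area_fraction`), computed
#' over a subgrid of sample points per cell; without a region all fractions
#' are 1.
#'
#' @param occurrences data frame with columns `species`, `x`, `y` in the
#'   grid's CRS.
#' @param grid a [grid_spec()].
#' @param region optional study-region definition: either a [grid_raster()]
#'   mask (nonzero/`TRUE` = inside, `NA`/0 = outside) or a two-column matrix
#'   of polygon vertices.
#' @param area_samples per-axis count of sample points per cell used to
#'   estimate `area_fraction` from a polygon region.
#' @return A `grid_cells` object: list of cells, each with `row`, `col`,
#'   `species` (character vector), `richness` and `area_fraction`, ordered by
#'   `(row, col)`; attribute `rejects` holds excluded occurrence rows.
#' @export
assign_to_grid <- function(occurrences, grid, region = NULL,
                           area_samples = 5) {
  stopifnot(inherits(grid, "grid_spec"),
            all(c("species", "x", "y") %in% names(occurrences)))
  loc <- locate_in_grid(occurrences$x, occurrences$y, grid)
  outside <- is.na(loc$row)
  rejects <- occurrences[outside, , drop = FALSE]
  if (any(outside)) {
    message(sprintf("%d occurrence(s) outside the grid extent were excluded",
                    sum(outside)))
  }
  keep <- !outside
  key <- paste(loc$row[keep], loc$col[keep], sep = "_")
  sp_by_cell <- split(as.character(occurrences$species)[keep], key)
  frac <- cell_area_fractions(grid, region, area_samples)
  cells <- lapply(names(sp_by_cell), function(k) {
    rc <- as.integer(strsplit(k, "_", fixed = TRUE)[[1]])
    sp <- sort(unique(sp_by_cell[[k]]))
    list(row = rc[1], col = rc[2], species = sp, richness = length(sp),
         area_fraction = frac[rc[1] + 1L, rc[2] + 1L])
  })
  ord <- order(vapply(cells, `[[`, integer(1), "row"),
               vapply(cells, `[[`, integer(1), "col"))
  structure(cells[ord], class = "grid_cells", rejects = rejects, grid = grid)
}

# Per-cell fraction of area inside the region, as an n_rows x n_cols matrix.
cell_area_fractions <- function(grid, region, area_samples = 5) {
  if (is.null(region)) {
    return(matrix(1, grid$n_rows, grid$n_cols))
  }
  m <- area_samples
  off <- (seq_len(m) - 0.5) / m * grid$cell_size
  fx <- grid$origin_x + rep(off, times = m)
  fy <- rep(off, each = m)
  frac <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      px <- fx + cc * grid$cell_size
      py <- grid$origin_y - r * grid$cell_size - fy
      inside <- if (inherits(region, "grid_raster")) {
        v <- raster_value_at(region, px, py)
        !is.na(v) & v != 0
      } else {
        point_in_polygon(px, py, region)
      }
      frac[r + 1L, cc + 1L] <- mean(inside)
    }
  }
  frac
}

raster_value_at <- function(r, x, y) {
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  ymax <- r$ymin + nr * r$cellsize
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- floor((ymax - y) / r$cellsize) + 1L
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' @export
print.grid_cells <- function(x, ...) {
  rich <- vapply(x, `[[`, integer(1), "richness")
  cat(sprintf("<grid_cells> %d occupied cells, %d species, richness %d-%d\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "species")))),
              if (length(rich)) min(rich) else 0L,
              if (length(rich)) max(rich) else 0L))
  invisible(x)
}

#' @export
as.data.frame.grid_cells <- function(x, ...) {
  data.frame(
    row = vapply(x, `[[`, integer(1), "row"),
    col = vapply(x, `[[`, integer(1), "col"),
    richness = vapply(x, `[[`, integer(1), "richness"),
    area_fraction = vapply(x, `[[`, numeric(1), "area_fraction")
  )
}

#' Drop low-coverage grid cells
#'
#' Retains cells whose `area_fraction` is at least `min_area_fraction`
#' (default 0.5): cells with less than half their area inside the study
#' region are excluded, and a cell exactly at the threshold is kept.
#'
#' @param cells a [assign_to_grid()] result.
#' @param min_area_fraction retention threshold in `[0, 1]`.
#' @return The filtered `grid_cells` object.
#' @export
filter_cells <- function(cells, min_area_fraction = 0.5) {
  keep <- vapply(cells, function(cl) cl$area_fraction >= min_area_fraction,
                 logical(1))
  structure(unclass(cells)[keep], class = "grid_cells",
            rejects = attr(cells, "rejects"), grid = attr(cells, "grid"))
}

#' Greedy complementarity hotspot selection
#'
#' Classic complementarity (greedy set-cover) ordering of grid cells: first
#' the cell with the highest species richness, then repeatedly the cell
#' contributing the most species not yet represented, until every species is
#' covered. Cells adding no new species are never selected. Ties are broken
#' deterministically by `(row, col)` ascending. The first cell(s) of the
#' order are the richness hotspots; any prefix of the order is a
#' complementarity-optimal greedy reserve set.
#'
#' @param cells a [assign_to_grid()] result with at least one non-empty cell.
#' @return A data frame, one row per selected cell in selection order:
#'   `rank`, `row`, `col`, `richness`, `new_species` (species added at that
#'   step) and `cum_species`.
#' @export
hotspot_complementarity <- function(cells) {
  if (length(cells) == 0 || all(vapply(cells, `[[`, integer(1), "richness") == 0)) {
    stop("no non-empty cells to select from")
  }
  sets <- lapply(cells, `[[`, "species")
  rows <- vapply(cells, `[[`, integer(1), "row")
  cols <- vapply(cells, `[[`, integer(1), "col")
  all_species <- unique(unlist(sets))
  covered <- character(0)
  picked <- integer(0)
  out <- list()
  while (length(covered) < length(all_species)) {
    gain <- vapply(seq_along(sets), function(i) {
      if (i %in% picked) return(-1L)
      length(setdiff(sets[[i]], covered))
    }, integer(1))
    best_gain <- max(gain)
    if (best_gain <= 0) break
    cand <- which(gain == best_gain)
    cand <- cand[order(rows[cand], cols[cand])][1]
    picked <- c(picked, cand)
    covered <- union(covered, sets[[cand]])
    out[[length(out) + 1L]] <- data.frame(
      rank = length(out) + 1L, row = rows[cand], col = cols[cand],
      richness = length(sets[[cand]]), new_species = best_gain,
      cum_species = length(covered))
  }
  do.call(rbind, out)
}
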