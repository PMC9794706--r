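# Small deterministic fixtures shared across test files.

toy_ranges <- function() {
  data.frame(species = c("A", "B"),
             min_elev = c(200, 300),
             max_elev = c(400, 500),
             stringsAsFactors = FALSE)
}

# A raster whose values are 1..(nr*nc) row-major from the top-left pixel.
seq_raster <- function(nr = 10, nc = 10, cellsize = 10, xmin = 0, ymin = 0) {
  grid_raster(matrix(seq_len(nr * nc), nr, nc, byrow = TRUE),
              xmin = xmin, ymin = ymin, cellsize = cellsize)
}

# A small scene configuration that keeps generator tests fast: 10 x 10
# analysis cells at the default 20-km size, 2-km pixels.
small_scene_config <- function(seed = 11, n_species = 60, ...) {
  scene_config(extent_m = c(200000, 200000), cell_size_m = 2000,
               n_species = n_species, seed = seed, ...)
}

# Build grid_cells directly from a named list of species sets, bypassing
# point assignment, for complementarity tests.
cells_from_sets <- function(sets, area_fraction = 1) {
  cells <- lapply(seq_along(sets), function(i) {
    list(row = i - 1L, col = 0L, species = sort(unique(sets[[i]])),
         richness = length(unique(sets[[i]])), area_fraction = area_fraction)
  })
  structure(cells, class = "grid_cells")
}
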