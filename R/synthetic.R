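#' Configure a synthetic landscape scene
#'
#' Parameters of the simulated mountain-province landscape on which the
#' full analysis is exercised with known ground truth. Defaults mirror the
#' study system the package is built around: a large projected extent
#' gridded into 20-km analysis cells, a DEM spanning 188-7556 m with
#' east-west relief, temperature tied to elevation through a lapse rate,
#' precipitation of 430-1785 mm/yr, potential evapotranspiration of
#' 113-1568 mm/yr, human-footprint fields on the 0-50 index scale, and 137
#' species with 100-m-resolved elevational ranges.
#'
#' @param extent_m width and height of the extent (m); must be divisible by
#'   `cell_size_m` and by `grid_size_m`.
#' @param cell_size_m raster resolution (m).
#' @param grid_size_m analysis cell size (m), default 20,000.
#' @param n_species number of species.
#' @param elev_range_m DEM range `(min, max)` (m).
#' @param lapse_rate temperature lapse (degrees C per m, negative).
#' @param t0 sea-level mean annual temperature (degrees C).
#' @param map_range_mm,pet_range_mm target raster ranges for MAP (mm/yr) and
#'   PET (mm/yr).
#' @param mat_noise_sd spatial noise added to the lapse-rate temperature
#'   field (degrees C).
#' @param seed integer seed; every derived artifact is a pure function of
#'   the configuration including this seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(extent_m = c(400000, 400000),
                         cell_size_m = 4000,
                         grid_size_m = 20000,
                         n_species = 137,
                         elev_range_m = c(188, 7556),
                         lapse_rate = -0.004,
                         t0 = 22.5,
                         map_range_mm = c(430, 1785),
                         pet_range_mm = c(113, 1568),
                         mat_noise_sd = 0.3,
                         seed = 1) {
  if (any(extent_m <= 0) || cell_size_m <= 0 || grid_size_m <= 0) {
    stop("invalid config: extent and cell sizes must be positive")
  }
  if (any(extent_m %% cell_size_m != 0)) {
    stop("invalid config: extent must be divisible by cell_size_m")
  }
  if (any(extent_m %% grid_size_m != 0)) {
    stop("invalid config: extent must be divisible by grid_size_m")
  }
  if (n_species < 1) stop("invalid config: n_species must be >= 1")
  if (elev_range_m[1] >= elev_range_m[2]) {
    stop("invalid config: elev_range_m must satisfy min < max")
  }
  structure(list(
    extent_m = extent_m, cell_size_m = cell_size_m, grid_size_m = grid_size_m,
    n_species = as.integer(n_species), elev_range_m = elev_range_m,
    lapse_rate = lapse_rate, t0 = t0, map_range_mm = map_range_mm,
    pet_range_mm = pet_range_mm, mat_noise_sd = mat_noise_sd,
    seed = as.integer(seed)), class = "scene_config")
}

#' Ground-truth parameters of the generative richness model
#'
#' The generative twin of the fitted negative-binomial richness GLM:
#' per-cell species counts are drawn from NB(mean = exp(beta0 + beta . z),
#' theta) with z the standardized cell predictors. Defaults encode a
#' water-energy-dominated landscape (strong positive PET and MAP effects, a
#' negative disturbance effect) with overdispersed counts and a mean cell
#' richness of about 4-5 species.
#'
#' @param beta0 intercept on the log scale.
#' @param beta named coefficients for MAT, MAP, PET, HHET, DIST on the log
#'   scale of standardized predictors.
#' @param theta NB dispersion (> 0).
#' @return A `true_params` list.
#' @export
true_params <- function(beta0 = log(4.5),
                        beta = c(MAT = 0.10, MAP = 0.30, PET = 0.50,
                                 HHET = 0.15, DIST = -0.25),
                        theta = 3) {
  stopifnot(theta > 0,
            all(c("MAT", "MAP", "PET", "HHET", "DIST") %in% names(beta)))
  structure(list(beta0 = beta0,
                 beta = beta[c("MAT", "MAP", "PET", "HHET", "DIST")],
                 theta = theta),
            class = "true_params")
}

# Smooth mean-0/sd-1 random field: a sum of random-direction cosines over
# normalized coordinates, so fields are spatially coherent at raster scale.
smooth_field <- function(nr, nc, n_waves = 6) {
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  v <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 3)
    fy <- stats::runif(1, 0.5, 3)
    amp <- stats::runif(1, 0.5, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * cos(2 * pi * (fx * u + fy * v) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

rescale_to <- function(m, lo, hi) {
  r <- range(m)
  if (r[1] == r[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Generate the synthetic raster stack
#'
#' Builds the six aligned rasters of a scene: a smooth DEM rescaled exactly
#' to the configured elevation range with a west-high ramp; MAT from the
#' lapse rate plus spatial noise; MAP and PET as eastward moisture/energy
#' gradients with spatial texture, rescaled exactly to their configured
#' ranges (PET additionally declines with elevation); and two human
#' footprint fields, the second differing by a localized change field, both
#' clipped to the 0-50 index scale. Deterministic given the config seed.
#'
#' @param cfg a [scene_config()].
#' @return Named list of aligned [grid_raster()]s: `dem`, `mat`, `map`,
#'   `pet`, `hfi_start`, `hfi_end`.
#' @export
make_rasters <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nc <- as.integer(cfg$extent_m[1] / cfg$cell_size_m)
  nr <- as.integer(cfg$extent_m[2] / cfg$cell_size_m)
  with_seed(cfg$seed, {
    u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
    dem <- rescale_to((1 - u) + 0.35 * smooth_field(nr, nc),
                      cfg$elev_range_m[1], cfg$elev_range_m[2])
    mat <- cfg$t0 + cfg$lapse_rate * dem +
      cfg$mat_noise_sd * (if (cfg$mat_noise_sd > 0) smooth_field(nr, nc) else 0)
    map <- rescale_to(u + 0.30 * smooth_field(nr, nc),
                      cfg$map_range_mm[1], cfg$map_range_mm[2])
    dem01 <- (dem - cfg$elev_range_m[1]) / diff(cfg$elev_range_m)
    pet <- rescale_to(0.6 * u + 0.4 * (1 - dem01) + 0.25 * smooth_field(nr, nc),
                      cfg$pet_range_mm[1], cfg$pet_range_mm[2])
    hfi1 <- rescale_to(u + 0.30 * smooth_field(nr, nc), 3, 45)
    change <- 6 * smooth_field(nr, nc, n_waves = 8) * u   # change concentrated east
    hfi2 <- pmin(pmax(hfi1 + change, 0), 50)
    hfi1 <- pmin(pmax(hfi1, 0), 50)
    g <- function(m) grid_raster(m, xmin = 0, ymin = 0,
                                 cellsize = cfg$cell_size_m)
    list(dem = g(dem), mat = g(mat), map = g(map), pet = g(pet),
         hfi_start = g(hfi1), hfi_end = g(hfi2))
  })
}

#' Draw species range sizes from a distribution specification
#'
#' The range size-frequency distribution is a first-class control of the
#' scene: `spec` is a list with element `dist` one of `"lognormal"`
#' (`meanlog`, `sdlog`), `"uniform"` (`min`, `max`) or `"fixed"` (`size`).
#' Draws outside `(0, max_size]` are rejected and resampled; an error is
#' raised if too few valid draws accumulate within `max_tries` passes.
#'
#' @param n number of sizes.
#' @param spec distribution specification list.
#' @param max_size largest admissible size (the elevational domain span, m).
#' @param max_tries bounded rejection-sampling passes.
#' @return Numeric vector of `n` sizes in `(0, max_size]`.
#' @export
draw_range_sizes <- function(n, spec, max_size, max_tries = 1000) {
  draw <- switch(spec$dist,
    lognormal = function(m) stats::rlnorm(m, spec$meanlog, spec$sdlog),
    uniform = function(m) stats::runif(m, spec$min, spec$max),
    fixed = function(m) rep(spec$size, m),
    stop("unknown size distribution: ", spec$dist)
  )
  if (spec$dist == "fixed" && (spec$size <= 0 || spec$size > max_size)) {
    stop("fixed range size outside (0, max_size]")
  }
  out <- numeric(0)
  for (i in seq_len(max_tries)) {
    cand <- draw(n - length(out))
    out <- c(out, cand[cand > 0 & cand <= max_size])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop(sprintf("could not draw %d valid range sizes in %d passes", n, max_tries))
}

#' Generate species elevational ranges
#'
#' Each species receives an elevational range whose size is drawn from the
#' configured range size-frequency distribution and whose midpoint is
#' uniform over the feasible positions of the species domain; limits are
#' then snapped to 100-m marks (minimum down, maximum up). The species
#' domain defaults to the DEM range snapped inward to 100-m marks, keeping
#' the elevational and spatial layers mutually consistent.
#'
#' @param cfg a [scene_config()].
#' @param size_dist a [draw_range_sizes()] specification; the default is a
#'   lognormal with median 1500 m, a realistic right-skewed range-size
#'   mixture.
#' @param domain optional `(min, max)` species elevational domain (m),
#'   100-m multiples.
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @return A species range table: data frame `species`, `min_elev`,
#'   `max_elev`.
#' @export
make_ranges <- function(cfg, size_dist = list(dist = "lognormal",
                                              meanlog = log(1500), sdlog = 0.6),
                        domain = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  if (is.null(domain)) {
    domain <- c(ceiling(cfg$elev_range_m[1] / 100) * 100,
                floor(cfg$elev_range_m[2] / 100) * 100)
  }
  span <- domain[2] - domain[1]
  with_seed(seed %||% (cfg$seed + 1L), {
    sizes <- draw_range_sizes(cfg$n_species, size_dist, max_size = span)
    mid <- stats::runif(cfg$n_species, domain[1] + sizes / 2,
                        domain[2] - sizes / 2)
    mn <- pmax(floor((mid - sizes / 2) / 100) * 100, domain[1])
    mx <- pmin(ceiling((mid + sizes / 2) / 100) * 100, domain[2])
    data.frame(
      species = sprintf("sp%03d", seq_len(cfg$n_species)),
      min_elev = mn, max_elev = mx, stringsAsFactors = FALSE)
  })
}

#' Generate occurrence points from the ground-truth richness model
#'
#' Occurrence intensity is defined at the analysis-cell level: for each
#' 20-km cell the species count is drawn from the negative-binomial model of
#' [true_params()] applied to the cell's standardized predictors, that many
#' distinct species are sampled among those whose elevational range overlaps
#' the cell's DEM range, and each selected species receives one point placed
#' uniformly inside the cell. Counts exceeding the number of eligible
#' species are capped with a warning.
#'
#' @param rasters a [make_rasters()] stack.
#' @param ranges a [make_ranges()] table.
#' @param cfg the [scene_config()].
#' @param truth a [true_params()] object.
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return Data frame `species`, `x`, `y`; attribute `truth_cells` holds the
#'   per-cell generative table (predictors, standardized values, NB mean and
#'   drawn count) for recovery tests.
#' @export
make_occurrences <- function(rasters, ranges, cfg, truth = true_params(),
                             seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"), inherits(truth, "true_params"))
  grid <- scene_grid(cfg)
  pred <- predictor_table(rasters, grid)
  z <- standardize_predictors(pred)
  zmat <- as.matrix(z[, names(truth$beta)])
  mu <- exp(truth$beta0 + as.numeric(zmat %*% truth$beta))
  dem_min <- aggregate_mean(rasters$dem, grid, fun = min)
  dem_max <- aggregate_mean(rasters$dem, grid, fun = max)
  with_seed(seed %||% (cfg$seed + 2L), {
    counts <- stats::rnbinom(length(mu), size = truth$theta, mu = mu)
    rows <- vector("list", length(mu))
    capped <- 0L
    for (i in seq_along(mu)) {
      if (counts[i] == 0) next
      r <- pred$row[i]
      cc <- pred$col[i]
      lo <- dem_min[r + 1L, cc + 1L]
      hi <- dem_max[r + 1L, cc + 1L]
      eligible <- which(ranges$max_elev >= lo & ranges$min_elev <= hi)
      k <- counts[i]
      if (k > length(eligible)) {
        capped <- capped + 1L
        k <- length(eligible)
        counts[i] <- k
      }
      if (k == 0) next
      sp <- ranges$species[eligible[sample.int(length(eligible), k)]]
      rows[[i]] <- data.frame(
        species = sp,
        x = grid$origin_x + (cc + stats::runif(k)) * grid$cell_size,
        y = grid$origin_y - (r + stats::runif(k)) * grid$cell_size,
        stringsAsFactors = FALSE)
    }
    if (capped > 0) {
      warning(sprintf(
        "%d cell count(s) exceeded the eligible species pool and were capped",
        capped))
    }
    occ <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(occ)) {
      occ <- data.frame(species = character(0), x = numeric(0), y = numeric(0))
    }
    rownames(occ) <- NULL
    zdf <- as.data.frame(zmat)
    names(zdf) <- paste0("z_", colnames(zmat))
    truth_cells <- cbind(pred, zdf, mu = mu, count = counts)
    attr(occ, "truth_cells") <- truth_cells
    occ
  })
}

# Analysis grid covering the scene extent, top-left origin at (0, extent_h).
scene_grid <- function(cfg) {
  grid_spec(origin_x = 0, origin_y = cfg$extent_m[2],
            cell_size = cfg$grid_size_m,
            n_cols = cfg$extent_m[1] / cfg$grid_size_m,
            n_rows = cfg$extent_m[2] / cfg$grid_size_m)
}

#' Simulate a complete synthetic scene
#'
#' Convenience wrapper producing the full scene: rasters, species ranges,
#' occurrence points and stored ground truth, all derived deterministically
#' from the configuration seed.
#'
#' @param cfg a [scene_config()].
#' @param truth a [true_params()].
#' @param size_dist range size-frequency specification (see [make_ranges()]).
#' @return A `synthetic_scene`: list with `config`, `truth`, `rasters`,
#'   `ranges`, `occurrences`, `grid` and `truth_cells`.
#' @export
simulate_scene <- function(cfg = scene_config(), truth = true_params(),
                           size_dist = list(dist = "lognormal",
                                            meanlog = log(1500), sdlog = 0.6)) {
  rasters <- make_rasters(cfg)
  ranges <- make_ranges(cfg, size_dist = size_dist)
  occ <- make_occurrences(rasters, ranges, cfg, truth)
  structure(list(
    config = cfg, truth = truth, rasters = rasters, ranges = ranges,
    occurrences = occ, grid = scene_grid(cfg),
    truth_cells = attr(occ, "truth_cells")),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d species, %d occurrences, %d x %d analysis cells\n",
    nrow(x$ranges), nrow(x$occurrences), x$grid$n_rows, x$grid$n_cols))
  cat(sprintf("  DEM %g-%g m, seed %d\n",
              x$config$elev_range_m[1], x$config$elev_range_m[2],
              x$config$seed))
  invisible(x)
}

#' Write a scene's artifacts to disk
#'
#' Rasters go out as ASCII grids, the range table and occurrences as CSV
#' (`species,min_elev,max_elev` and `species,x,y`), and the ground-truth
#' parameters as JSON.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$rasters)) {
    write_ascii_grid(scene$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  utils::write.csv(scene$ranges, file.path(dir, "ranges.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(beta0 = scene$truth$beta0, beta = as.list(scene$truth$beta),
         theta = scene$truth$theta, seed = scene$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
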