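test_that("raster generation hits configured ranges and is deterministic", {
  cfg <- small_scene_config(seed = 31)
  r1 <- make_rasters(cfg)
  r2 <- make_rasters(cfg)
  for (nm in names(r1)) expect_identical(r1[[nm]], r2[[nm]])

  expect_equal(range(r1$dem$values), cfg$elev_range_m)
  expect_equal(range(r1$map$values), cfg$map_range_mm)
  expect_equal(range(r1$pet$values), cfg$pet_range_mm)
  expect_true(all(r1$hfi_start$values >= 0 & r1$hfi_start$values <= 50))
  expect_true(all(r1$hfi_end$values >= 0 & r1$hfi_end$values <= 50))
  expect_true(all(vapply(r1, function(x)
    identical(dim(x$values), dim(r1$dem$values)), logical(1))))

  # degenerate lapse: zero lapse and zero noise -> constant temperature
  flat <- small_scene_config(seed = 31, lapse_rate = 0, mat_noise_sd = 0)
  rf <- make_rasters(flat)
  expect_true(all(rf$mat$values == flat$t0))

  expect_error(scene_config(extent_m = c(-1000, 1000)), "invalid config")
  expect_error(scene_config(extent_m = c(401000, 400000)), "divisible")
  expect_error(scene_config(n_species = 0), "n_species")
  expect_error(scene_config(elev_range_m = c(500, 100)), "min < max")
})

test_that("range generation honours the size distribution and the domain", {
  cfg <- small_scene_config(seed = 17, n_species = 1)
  dom <- c(200, 7500)
  span <- dom[2] - dom[1]

  # forced placement: one species with the full-domain size
  r <- make_ranges(cfg, size_dist = list(dist = "fixed", size = span),
                   domain = dom)
  expect_equal(c(r$min_elev, r$max_elev), dom)

  # degenerate distribution: every drawn size equals the fixed size, and
  # snapped table sizes widen by at most one band width
  set.seed(1)
  expect_true(all(draw_range_sizes(1000, list(dist = "fixed", size = 1200),
                                   max_size = span) == 1200))
  cfg2 <- small_scene_config(seed = 17, n_species = 1000)
  r2 <- make_ranges(cfg2, size_dist = list(dist = "fixed", size = 1200),
                    domain = dom)
  sizes <- r2$max_elev - r2$min_elev
  expect_true(all(sizes %in% c(1200, 1300)))

  # domain validity holds for every generated range
  r3 <- make_ranges(small_scene_config(seed = 8, n_species = 500))
  ddef <- c(200, 7500)
  expect_true(all(r3$min_elev >= ddef[1] & r3$max_elev <= ddef[2]))
  expect_true(all(r3$min_elev <= r3$max_elev))
  expect_true(all(r3$min_elev %% 100 == 0 & r3$max_elev %% 100 == 0))

  # determinism
  expect_identical(make_ranges(cfg2, domain = dom, seed = 3),
                   make_ranges(cfg2, domain = dom, seed = 3))

  # oversized draws are rejected; impossible specs error out
  expect_error(
    make_ranges(cfg, size_dist = list(dist = "fixed", size = span + 100),
                domain = dom),
    "outside")
  expect_error(draw_range_sizes(10, list(dist = "uniform", min = 5000,
                                         max = 9000), max_size = 100,
                                max_tries = 5),
               "could not draw")
})

test_that("drawn range sizes follow the requested distribution (KS check)", {
  spec <- list(dist = "uniform", min = 100, max = 1000)
  set.seed(909)
  sizes <- draw_range_sizes(5000, spec, max_size = 4600)
  ks <- suppressWarnings(ks.test(sizes, "punif", 100, 1000))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(sizes >= 100 & sizes <= 1000))
})

test_that("occurrences follow the generative NB richness model", {
  # intercept-only limit: near-Poisson counts with mean about 3
  cfg <- small_scene_config(seed = 3, n_species = 100)
  rasters <- make_rasters(cfg)
  ranges <- make_ranges(cfg)
  tp <- true_params(beta0 = log(3),
                    beta = c(MAT = 0, MAP = 0, PET = 0, HHET = 0, DIST = 0),
                    theta = 1e6)
  occ <- make_occurrences(rasters, ranges, cfg, tp)
  tc <- attr(occ, "truth_cells")
  expect_equal(mean(tc$count), 3, tolerance = 0.2)   # 100 cells, SE ~ 0.17

  # positive PET effect induces a positive PET-richness association
  cfg2 <- scene_config(extent_m = c(300000, 300000), cell_size_m = 3000,
                       n_species = 120, seed = 6)   # 15 x 15 = 225 cells
  rs <- make_rasters(cfg2)
  rg <- make_ranges(cfg2)
  tp2 <- true_params(beta0 = log(4),
                     beta = c(MAT = 0, MAP = 0, PET = 0.6, HHET = 0, DIST = 0),
                     theta = 5)
  occ2 <- suppressWarnings(make_occurrences(rs, rg, cfg2, tp2))
  tc2 <- attr(occ2, "truth_cells")
  expect_gt(cor(tc2$PET, tc2$count, method = "spearman"), 0)

  # determinism of the full occurrence list
  occ_a <- make_occurrences(rasters, ranges, cfg, tp, seed = 5)
  occ_b <- make_occurrences(rasters, ranges, cfg, tp, seed = 5)
  expect_identical(occ_a, occ_b)
})

test_that("scenes are internally consistent and fully reproducible", {
  cfg <- small_scene_config(seed = 12)
  s1 <- suppressWarnings(simulate_scene(cfg))
  s2 <- suppressWarnings(simulate_scene(cfg))
  expect_identical(s1$ranges, s2$ranges)
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$rasters$dem$values, s2$rasters$dem$values)

  # every occurrence lies inside the extent and names a known species
  expect_true(all(s1$occurrences$x >= 0 &
                    s1$occurrences$x <= cfg$extent_m[1]))
  expect_true(all(s1$occurrences$y >= 0 &
                    s1$occurrences$y <= cfg$extent_m[2]))
  expect_true(all(s1$occurrences$species %in% s1$ranges$species))

  # a species may only occur in cells whose DEM range overlaps its range
  g <- s1$grid
  loc <- richscape:::locate_in_grid(s1$occurrences$x, s1$occurrences$y, g)
  dem_min <- aggregate_mean(s1$rasters$dem, g, fun = min)
  dem_max <- aggregate_mean(s1$rasters$dem, g, fun = max)
  idx <- match(s1$occurrences$species, s1$ranges$species)
  expect_true(all(
    s1$ranges$max_elev[idx] >= dem_min[cbind(loc$row + 1, loc$col + 1)] &
      s1$ranges$min_elev[idx] <= dem_max[cbind(loc$row + 1, loc$col + 1)]))
})

test_that("scene artifacts round-trip through their on-disk formats", {
  cfg <- small_scene_config(seed = 44, n_species = 20)
  scene <- suppressWarnings(simulate_scene(cfg))
  dir <- tempfile()
  write_scene(scene, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "dem.asc", "mat.asc", "map.asc", "pet.asc", "hfi_start.asc",
    "hfi_end.asc", "ranges.csv", "occurrences.csv", "truth.json")))))

  dem_rt <- read_ascii_grid(file.path(dir, "dem.asc"))
  expect_equal(dem_rt$values, scene$rasters$dem$values, tolerance = 1e-8)
  expect_equal(dem_rt$cellsize, cfg$cell_size_m)

  ranges_rt <- read_ranges(file.path(dir, "ranges.csv"))
  expect_equal(ranges_rt, scene$ranges)
  occ_rt <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(occ_rt$species, scene$occurrences$species)
  expect_equal(occ_rt$x, scene$occurrences$x, tolerance = 1e-9)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$theta, scene$truth$theta)

  # nodata round-trips as NA
  withna <- grid_raster(matrix(c(1, NA, 3, 4), 2, 2), 0, 0, 10)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(withna, p)
  expect_equal(read_ascii_grid(p)$values, withna$values)
})
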