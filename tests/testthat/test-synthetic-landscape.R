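cfg64 <- landscape_config(grid_rows = 64, grid_cols = 64, seed = 1)

test_that("generated DEM is deterministic, seed-sensitive and bounded", {
  d1 <- generate_dem(cfg64)
  d2 <- generate_dem(cfg64)
  expect_identical(d1$values, d2$values)
  d3 <- generate_dem(landscape_config(grid_rows = 64, grid_cols = 64,
                                      seed = 2))
  expect_false(identical(d1$values, d3$values))
  mx <- max(d1$values, na.rm = TRUE)
  expect_gte(mx, 0.8 * cfg64$ridge_height)
  expect_lte(mx, 1.0 * cfg64$ridge_height)
  expect_true(all(d1$values >= 0, na.rm = TRUE))
  # ocean ring of nodata around the border
  expect_true(all(is.na(d1$values[1, ])))
  expect_true(all(is.na(d1$values[, 1])))
  expect_error(generate_dem(landscape_config(grid_rows = 16)),
               "grid_rows")
})

test_that("climate surfaces follow the lapse rate and scenario offsets", {
  cfg <- landscape_config(grid_rows = 40, grid_cols = 40,
                          temp_noise_sd = 0, precip_noise_sd = 0)
  dem <- generate_dem(cfg)
  clim <- generate_climate(dem, scenario_delta(), cfg)
  # two cells differing by known elevation: mst differs by -lapse * dz/1000
  cc <- raster_to_tibble(dem)
  i <- which.max(cc$value); j <- which.min(cc$value)
  dz <- cc$value[i] - cc$value[j]
  mst <- clim$mst$values
  dt <- mst[cc$row[i], cc$col[i]] - mst[cc$row[j], cc$col[j]]
  expect_equal(dt, -cfg$lapse_rate * dz / 1000, tolerance = 1e-10)

  warm <- generate_climate(dem, scenario_delta("Can", "8.5", "2085",
                                               d_mst = 4), cfg)
  diff <- warm$mst$values - clim$mst$values
  expect_equal(range(diff, na.rm = TRUE), c(4, 4))

  halfsnow <- generate_climate(dem, scenario_delta("Can", "8.5", "2085",
                                                   d_pas = 0.5), cfg)
  expect_equal(halfsnow$pas$values, clim$pas$values * 0.5)
  expect_identical(is.na(clim$mst$values), is.na(dem$values))
})

test_that("generated landscapes have the assumed correlation structure", {
  dem <- generate_dem(cfg64)
  clim <- generate_climate(dem, scenario_delta(), cfg64)
  e <- as.vector(dem$values)
  expect_lt(cor(e, as.vector(clim$mst$values), use = "complete.obs"), 0)
  expect_gt(cor(e, as.vector(clim$pas$values), use = "complete.obs"), 0)
})

test_that("zone banding partitions the valid cells", {
  dem <- generate_dem(cfg64)
  z <- generate_zones(dem, config = cfg64)
  zv <- z$values
  expect_identical(is.na(zv), is.na(dem$values))
  expect_true(all(zv[!is.na(zv)] %in% 1:3))
  expect_equal(sum(table(zv)), sum(!is.na(dem$values)))
  # highest band is alpine
  expect_true(all(zv[!is.na(zv) & dem$values >= 1350] == 3))
  # a DEM entirely below the lowest break is all coastal forest
  low <- raster_grid(matrix(100, 40, 40))
  expect_true(all(generate_zones(low, config = cfg64)$values == 1))
  # monotone east-rising ramp: zone boundaries are two vertical contours
  ramp <- plane_dem(n = 40, a = 0.5, cell = 100)
  zr <- generate_zones(ramp, config = cfg64)$values
  expect_true(all(apply(zr, 2, function(cl) length(unique(cl)) == 1)))
  expect_equal(length(rle(zr[1, ])$values), 3)
  expect_true(!is.unsorted(zr[1, ]))
})

test_that("scenario table validates ordering and baseline identity", {
  tab <- default_scenario_table()
  expect_equal(nrow(tab), 19)
  expect_silent(validate_scenario_table(tab))
  bad <- tab
  bad$d_mst[bad$gcm == "Can" & bad$rcp == "4.5" & bad$period == "2055"] <- 9
  expect_error(validate_scenario_table(bad), "non-decreasing")
  bad2 <- tab
  bad2$d_msp[bad2$period == "baseline"] <- 2
  expect_error(validate_scenario_table(bad2), "identity")
})

test_that("simulated occurrences honour counts, seeds and the truth bias", {
  dem <- generate_dem(cfg64)
  terr <- terrain_layers(dem)
  clim <- generate_climate(dem, scenario_delta(), cfg64)
  st <- build_predictor_stack(dem, clim, terrain = terr)
  zones <- generate_zones(dem, config = cfg64)
  occ <- simulate_occurrences(st, zones, cfg64)
  expect_equal(sum(occ$source == "field"), 207)
  expect_equal(sum(occ$source == "public"), 137)
  occ2 <- simulate_occurrences(st, zones, cfg64)
  expect_identical(occ, occ2)

  # the generating truth is elevation-loaded: presences sit higher than a
  # random background sample (Monte-Carlo, seeded)
  cells <- cell_of_xy(dem, occ$x, occ$y)
  occ_elev <- dem$values[cbind(cells$row, cells$col)]
  withr::with_seed(99, {
    bg <- sample(which(!is.na(dem$values)), 2000, replace = TRUE)
    expect_gt(mean(occ_elev, na.rm = TRUE), mean(dem$values[bg]) + 200)
  })

  # raw records exercise every downstream filter
  expect_gt(sum(format(occ$date, "%m") %in% sprintf("%02d", c(1:5, 11:12))),
            0)
  expect_gt(sum(occ$life_stage == "juvenile"), 0)
  expect_gt(sum(occ$accuracy_m > 100), 0)
  expect_gt(sum(duplicated(paste(occ$x, occ$y))), 0)
})

test_that("occurrence CSV round-trips the schema", {
  dem <- generate_dem(cfg64)
  terr <- terrain_layers(dem)
  clim <- generate_climate(dem, scenario_delta(), cfg64)
  st <- build_predictor_stack(dem, clim, terrain = terr)
  zones <- generate_zones(dem, config = cfg64)
  occ <- simulate_occurrences(st, zones, cfg64, n_field = 20, n_public = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, p)
  back <- read_occurrences(p)
  expect_equal(names(back),
               c("id", "source", "date", "x", "y", "individual_id",
                 "life_stage", "accuracy_m"))
  expect_equal(back$x, occ$x)
  expect_equal(as.numeric(back$date), as.numeric(occ$date), tolerance = 1)
})
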