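test_that("slope and aspect match analytic planes", {
  # plane rising east at 0.1 m/m: slope atan(0.1), downslope aspect 270
  east <- plane_dem(n = 9, a = 0.1)
  sa <- compute_slope_aspect(east)
  interior <- sa$slope$values[3:7, 3:7]
  expect_equal(interior, matrix(atan(0.1) * 180 / pi, 5, 5),
               tolerance = 1e-10)
  expect_equal(sa$aspect$values[3:7, 3:7], matrix(270, 5, 5),
               tolerance = 1e-10)
  # plane rising north: downslope aspect 180 (south)
  north <- plane_dem(n = 9, b = 0.2)
  sa2 <- compute_slope_aspect(north)
  expect_equal(sa2$aspect$values[5, 5], 180, tolerance = 1e-10)
  expect_equal(sa2$slope$values[5, 5], atan(0.2) * 180 / pi,
               tolerance = 1e-10)
  # border cells have no full window
  expect_true(all(is.na(sa$slope$values[1, ])))
})

test_that("flat terrain has zero slope and undefined aspect", {
  flat <- raster_grid(matrix(500, 8, 8))
  sa <- compute_slope_aspect(flat)
  expect_equal(sa$slope$values[4, 4], 0)
  expect_true(is.na(sa$aspect$values[4, 4]))
  expect_error(compute_slope_aspect(raster_grid(matrix(NA_real_, 8, 8))),
               "no valid")
})

test_that("mirroring the DEM reflects aspect", {
  dem <- random_dem(n = 12, seed = 4)
  sa <- compute_slope_aspect(dem)
  flipped <- raster_grid(dem$values[, ncol(dem$values):1],
                         cell_size = dem$cell_size)
  sa_f <- compute_slope_aspect(flipped)
  a <- sa$aspect$values[3:10, 3:10]
  af <- sa_f$aspect$values[3:10, 10:3]
  ok <- !is.na(a) & !is.na(af)
  delta <- abs((a[ok] + af[ok]) %% 360)
  expect_true(all(pmin(delta, 360 - delta) < 1e-8))
  # slope is mirror-invariant
  expect_equal(sa_f$slope$values[3:10, 10:3], sa$slope$values[3:10, 3:10])
})

test_that("aspect transform hits its endpoints and the flat-slope rule", {
  expect_equal(transform_aspect(0, 20), -1)
  expect_equal(transform_aspect(180, 20), 1)
  expect_equal(transform_aspect(123, 4.9), 0)
  expect_equal(transform_aspect(90, 30), 0, tolerance = 1e-12)
  expect_equal(transform_aspect(5, 5), -cos(5 * pi / 180))  # boundary: >= 5
  # undefined aspect (flat cell) is neutral
  expect_equal(transform_aspect(NA_real_, 2), 0)
  # raster form stays in [-1, 1] and shares the nodata mask
  dem <- random_dem(n = 15, seed = 2)
  sa <- compute_slope_aspect(dem)
  at <- transform_aspect(sa$aspect, sa$slope)
  v <- at$values[!is.na(at$values)]
  expect_true(all(v >= -1 & v <= 1))
  expect_identical(is.na(at$values), is.na(sa$slope$values))
})

test_that("D8 accumulation on an east-tilted plane counts upstream cells", {
  # west high, flow runs east: column j (0-based) accumulates j cells
  dem <- plane_dem(n = 5, a = -0.05, c = 1000)
  acc <- flow_accumulation_d8(dem)
  expect_equal(acc$values, matrix(rep(0:4, each = 5), 5, 5))
})

test_that("an unfilled bowl drains everything into its sink", {
  n <- 5
  d2 <- outer(seq_len(n), seq_len(n),
              function(r, c) (r - 3)^2 + (c - 3)^2)
  bowl <- raster_grid(100 + 10 * d2)
  acc <- flow_accumulation_d8(bowl, fill = FALSE)
  expect_equal(acc$values[3, 3], n * n - 1)
  # after filling, the sink drains out and no cell retains everything
  accf <- flow_accumulation_d8(bowl, fill = TRUE)
  expect_lt(max(accf$values), n * n - 1)
})

test_that("D8 accumulation matches the brute-force path-tracing oracle", {
  for (s in 1:4) {
    dem <- random_dem(n = 8 + s, seed = s, border_na = s %% 2 == 0)
    got <- flow_accumulation_d8(dem, fill = FALSE)$values
    expect_equal(got, d8_accumulation_oracle(dem))
  }
})

test_that("flow is conserved: outlets account for every valid cell", {
  for (s in c(3, 11)) {
    dem <- random_dem(n = 10, seed = s)
    acc <- flow_accumulation_d8(dem, fill = FALSE)
    recv <- attr(acc, "receiver")
    valid <- !is.na(as.vector(dem$values))
    outlets <- which(valid & is.na(recv))
    expect_equal(sum(acc$values[outlets] + 1), sum(valid))
  }
})

test_that("CTI follows its closed form and monotonicities", {
  g <- raster_grid(matrix(0, 3, 3), cell_size = 100)
  acc0 <- raster_grid(matrix(0, 3, 3), cell_size = 100)
  s45 <- raster_grid(matrix(45, 3, 3), cell_size = 100)
  cti <- compute_cti(g, acc0, s45)
  expect_equal(cti$values[2, 2], log(10000), tolerance = 1e-12)
  # doubling (acc + 1) adds log(2)
  acc1 <- raster_grid(matrix(1, 3, 3), cell_size = 100)
  cti2 <- compute_cti(g, acc1, s45)
  expect_equal(cti2$values[2, 2] - cti$values[2, 2], log(2))
  # decreasing in slope above the floor
  s30 <- raster_grid(matrix(30, 3, 3), cell_size = 100)
  expect_gt(compute_cti(g, acc0, s30)$values[2, 2], cti$values[2, 2])
  # flats stay finite via the slope floor
  s0 <- raster_grid(matrix(0, 3, 3), cell_size = 100)
  expect_true(is.finite(compute_cti(g, acc0, s0)$values[2, 2]))
})

test_that("CTI on a synthetic alpine landscape spans a plausible envelope", {
  cfg <- landscape_config(grid_rows = 64, grid_cols = 64, seed = 1)
  terr <- terrain_layers(generate_dem(cfg))
  v <- terr$cti$values[!is.na(terr$cti$values)]
  expect_gt(min(v), 5)
  expect_lt(max(v), 30)
  expect_gt(mean(v >= 9 & v <= 19.5), 0.8)
})

test_that("VRM is zero on uniform terrain and high for dispersed normals", {
  s <- raster_grid(matrix(30, 5, 5))
  a <- raster_grid(matrix(135, 5, 5))
  expect_equal(compute_vrm(s, a)$values[3, 3], 0, tolerance = 1e-12)
  # nine maximally dispersed orientations: eight compass aspects at 90
  # degree slope cancel; the resultant is one vertical-ish vector
  s9 <- raster_grid(matrix(90, 3, 3))
  a9 <- raster_grid(matrix(c(0, 45, 90, 135, 180, 225, 270, 315, 0), 3, 3))
  expect_gt(compute_vrm(s9, a9)$values[2, 2], 0.8)
})

test_that("VRM matches per-cell direct recomputation and its invariants", {
  dem <- random_dem(n = 12, seed = 7)
  sa <- compute_slope_aspect(dem)
  got <- compute_vrm(sa$slope, sa$aspect)$values
  expect_equal(got, vrm_oracle(sa$slope, sa$aspect), tolerance = 1e-12)
  v <- got[!is.na(got)]
  expect_true(all(v >= 0 & v <= 1))
  # invariant to adding a constant to the DEM
  dem2 <- raster_grid(dem$values + 500, cell_size = dem$cell_size)
  sa2 <- compute_slope_aspect(dem2)
  expect_equal(compute_vrm(sa2$slope, sa2$aspect)$values, got)
})

test_that("terrain layer ranges hold on generated landscapes", {
  cfg <- landscape_config(grid_rows = 48, grid_cols = 48, seed = 3)
  terr <- terrain_layers(generate_dem(cfg))
  sl <- terr$slope$values
  expect_true(all(sl >= 0 & sl <= 90, na.rm = TRUE))
  expect_true(all(terr$flow_acc$values >= 0, na.rm = TRUE))
  expect_true(all(terr$vrm$values >= 0 & terr$vrm$values <= 1, na.rm = TRUE))
  expect_true(all(terr$aspect_t$values >= -1 & terr$aspect_t$values <= 1,
                  na.rm = TRUE))
})
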