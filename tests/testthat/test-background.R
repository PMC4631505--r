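all_cma_zones <- function(n = 20, cell = 100) {
  z <- raster_grid(matrix(3, n, n), cell_size = cell, layer = "zones")
  attr(z, "levels") <- c("CWH", "MH", "CMA")
  z
}

test_that("minimum convex polygon matches brute-force checks", {
  tri <- tibble::tibble(x = c(0, 4, 1), y = c(0, 0, 3))
  h <- minimum_convex_polygon(tri)
  expect_equal(nrow(h), 3)
  expect_setequal(paste(h$x, h$y), paste(tri$x, tri$y))

  sq <- tibble::tibble(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
  h2 <- minimum_convex_polygon(sq)
  expect_equal(nrow(h2), 4)
  expect_false("0.5 0.5" %in% paste(h2$x, h2$y))

  withr::with_seed(11, {
    pts <- tibble::tibble(x = runif(50), y = runif(50))
    h3 <- minimum_convex_polygon(pts)
    expect_true(brute_hull_contains_all(h3, pts))
    expect_true(all(paste(h3$x, h3$y) %in% paste(pts$x, pts$y)))
  })

  expect_error(minimum_convex_polygon(tibble::tibble(x = 1:2, y = 1:2)),
               "3 distinct")
  expect_error(minimum_convex_polygon(tibble::tibble(x = 1:5, y = 1:5)),
               "collinear")
})

test_that("background eligibility combines hull buffer, zones and validity", {
  g <- raster_grid(matrix(0, 20, 20), cell_size = 100)
  zones <- all_cma_zones(20)
  corners <- tibble::tibble(x = c(10, 1990, 1990, 10), y = c(10, 10, 1990, 1990))
  m <- build_background(corners, zones, g)
  expect_true(all(m$eligible$values))
  expect_error(build_background(corners, zones, g, zones_allowed = c()),
               "non-empty")
  expect_error(build_background(corners, zones, g,
                                zones_allowed = "NOPE"), "unknown zone")
  # zone restriction removes disallowed cells
  z2 <- all_cma_zones(20)
  z2$values[, 1:10] <- 1  # west half coastal forest
  m2 <- build_background(corners, z2, g)
  expect_true(all(!m2$eligible$values[, 1:10]))
  expect_true(all(m2$eligible$values[, 11:20]))
})

test_that("the 200 m hull buffer is exact at cell centres", {
  g <- raster_grid(matrix(0, 4, 30), cell_size = 100)
  zones <- all_cma_zones(4)
  zones <- raster_grid(matrix(3, 4, 30), cell_size = 100)
  attr(zones, "levels") <- c("CWH", "MH", "CMA")
  # hull is a rectangle whose right edge is the vertical line x = e; the
  # centre at (1250, 250) is then at distance 1250 - e from the hull
  mk <- function(e) tibble::tibble(x = c(100, e, e, 100),
                                   y = c(50, 50, 350, 350))
  in199 <- build_background(mk(1051), zones, g, buffer_m = 200)
  expect_true(in199$eligible$values[2, 13])   # centre (1250, 250): 199 m
  out201 <- build_background(mk(1049), zones, g, buffer_m = 200)
  expect_false(out201$eligible$values[2, 13]) # 201 m
})

test_that("presence exclusion removes a closed 200 m ball of cell centres", {
  g <- raster_grid(matrix(0, 11, 11), cell_size = 100)
  zones <- all_cma_zones(11)
  pts <- tibble::tibble(x = c(50, 1050, 1050, 50), y = c(50, 50, 1050, 1050))
  m <- build_background(pts, zones, g)
  # single presence at the centre of cell (6, 6)
  p <- tibble::tibble(x = 550, y = 550)
  m2 <- exclude_presence_buffer(m, p, radius_m = 200)
  ev <- m2$eligible$values
  expect_false(ev[6, 6])              # 0 m
  expect_false(ev[6, 7]); expect_false(ev[5, 6])   # 100 m
  expect_false(ev[5, 7])              # ~141.4 m
  expect_false(ev[6, 8]); expect_false(ev[4, 6])   # exactly 200 m: closed
  expect_true(ev[4, 7])               # ~223.6 m
  expect_true(ev[3, 3])
  # no presences: identity; radius 0: only exact centre collisions
  expect_equal(exclude_presence_buffer(m, p[0, ])$eligible$values,
               m$eligible$values)
  m3 <- exclude_presence_buffer(m, p, radius_m = 0)
  expect_false(m3$eligible$values[6, 6])
  expect_true(m3$eligible$values[6, 7])
})

test_that("pseudo-absence sampling respects counts, capacity and the mask", {
  g <- raster_grid(matrix(0, 40, 40), cell_size = 100)
  zones <- all_cma_zones(40)
  pts <- tibble::tibble(x = c(50, 3950, 3950, 50), y = c(50, 50, 3950, 3950))
  m <- build_background(pts, zones, g)
  m <- exclude_presence_buffer(m, pts, radius_m = 200)
  ab <- sample_pseudo_absences(m, n_presences = 344, ratio = 2, seed = 9)
  expect_equal(nrow(ab), 688)
  expect_true(all(ab$label == 0))
  expect_equal(nrow(dplyr::distinct(ab, x, y)), 688)
  # every draw is an eligible cell and clears the exclusion radius
  cells <- cell_of_xy(g, ab$x, ab$y)
  expect_true(all(m$eligible$values[cbind(cells$row, cells$col)]))
  for (i in seq_len(nrow(pts))) {
    expect_true(all((ab$x - pts$x[i])^2 + (ab$y - pts$y[i])^2 > 200^2))
  }
  # capacity shortfall is rejected with the shortfall stated
  small <- build_background(tibble::tibble(x = c(50, 350, 350, 50),
                                           y = c(50, 50, 350, 350)),
                            zones, g, buffer_m = 0)
  expect_error(sample_pseudo_absences(small, 100, ratio = 10, seed = 1),
               "shortfall")
})

test_that("sampling is uniform over eligible cells across seeds", {
  g <- raster_grid(matrix(0, 6, 6), cell_size = 100)
  zones <- all_cma_zones(6)
  pts <- tibble::tibble(x = c(50, 550, 550, 50), y = c(50, 50, 550, 550))
  m <- build_background(pts, zones, g)
  n_cells <- sum(m$eligible$values)
  counts <- integer(n_cells)
  key <- function(df) paste(df$x, df$y)
  cells <- cell_centers(m$eligible)
  elig_keys <- paste(cells$x, cells$y)[as.vector(m$eligible$values)]
  for (s in 1:400) {
    ab <- sample_pseudo_absences(m, n_presences = 5, ratio = 2, seed = s)
    counts <- counts + as.integer(elig_keys %in% key(ab))
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})
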