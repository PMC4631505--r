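# Independent oracles and small fixtures shared across test files.
# Every oracle here is deliberately written with a different algorithm than
# the implementation it checks.

# A plane DEM z = a*x + b*y + c (x east, y north, metres), full grid valid.
plane_dem <- function(n = 9, a = 0, b = 0, c = 100, cell = 100) {
  g <- raster_grid(matrix(0, n, n), cell_size = cell)
  cc <- cell_centers(g)
  vals <- matrix(NA_real_, n, n)
  vals[cbind(cc$row, cc$col)] <- a * cc$x + b * cc$y + c
  raster_grid(vals, cell_size = cell)
}

# Random smooth-ish DEM with optional NA border.
random_dem <- function(n = 10, seed = 1, cell = 100, border_na = FALSE) {
  withr::local_seed(seed)
  m <- matrix(cumsum(rnorm(n * n, sd = 5)), n, n) +
    outer(seq_len(n), seq_len(n), function(r, c) 3 * r + 2 * c)
  if (border_na) {
    m[1, ] <- NA; m[n, ] <- NA; m[, 1] <- NA; m[, n] <- NA
  }
  raster_grid(m, cell_size = cell)
}

# Brute-force D8 accumulation: independently recompute each cell's receiver
# with explicit loops, then trace every cell's full path, counting visits.
d8_accumulation_oracle <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  recv <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(z[r, cc])) next
    best <- 0; bestj <- NA_integer_
    for (k in 1:8) {
      rr <- r + dr[k]; c2 <- cc + dc[k]
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      if (is.na(z[rr, c2])) next
      d <- if (dr[k] != 0 && dc[k] != 0) sqrt(2) else 1
      g <- (z[r, cc] - z[rr, c2]) / (d * dem$cell_size)
      if (g > best) { best <- g; bestj <- (c2 - 1) * nr + rr }
    }
    recv[r, cc] <- bestj
  }
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(z[r, cc])) next
    j <- recv[r, cc]
    guard <- 0
    while (!is.na(j) && guard < nr * nc + 1) {
      acc[j] <- acc[j] + 1
      j <- recv[j]
      guard <- guard + 1
    }
  }
  acc[is.na(z)] <- NA
  acc
}

# Direct per-cell VRM recomputation with explicit loops.
vrm_oracle <- function(slope, aspect) {
  s <- slope$values * pi / 180
  a <- aspect$values * pi / 180
  nr <- nrow(s); nc <- ncol(s)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(s[r, cc])) next
    xs <- ys <- zs <- 0; n <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      if (is.na(s[rr, c2])) next
      si <- s[rr, c2]; ai <- a[rr, c2]
      if (is.na(ai)) { xi <- 0; yi <- 0 } else {
        xi <- sin(si) * sin(ai); yi <- sin(si) * cos(ai)
      }
      xs <- xs + xi; ys <- ys + yi; zs <- zs + cos(si); n <- n + 1
    }
    out[r, cc] <- 1 - sqrt(xs^2 + ys^2 + zs^2) / n
  }
  out
}

# Label-propagation connected components (relax min labels to fixpoint) —
# independent of the BFS implementation.
flood_fill_oracle <- function(binary, connectivity = 8) {
  v <- binary$values
  nr <- nrow(v); nc <- ncol(v)
  hab <- !is.na(v) & v == 1
  lab <- matrix(0L, nr, nc)
  lab[hab] <- seq_len(sum(hab))
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!hab[r, cc]) next
      for (o in offs) {
        rr <- r + o[1]; c2 <- cc + o[2]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (hab[rr, c2] && lab[rr, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[rr, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab[!hab & !is.na(v)] <- 0L
  lab[is.na(v)] <- NA_integer_
  lab
}

# Number of distinct components and a canonical relabelling for comparison.
canonical_labels <- function(lab) {
  ok <- !is.na(lab) & lab > 0
  match(lab[ok], unique(lab[ok]))
}

# O(n^3) convex hull: a point is a hull vertex iff it is not strictly inside
# the hull, checked by whether all points lie on one side of some edge.
brute_hull_contains_all <- function(hull, pts) {
  n <- nrow(hull)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ex <- hull$x[j] - hull$x[i]; ey <- hull$y[j] - hull$y[i]
    cr <- ex * (pts$y - hull$y[i]) - ey * (pts$x - hull$x[i])
    if (any(cr < -1e-9)) return(FALSE)
  }
  TRUE
}

# Exhaustive threshold scan oracle.
threshold_scan_oracle <- function(probs, labels, req = 0.9) {
  cand <- sort(unique(c(0, probs, 1)))
  p1 <- probs[labels == 1]
  best <- -Inf
  for (t in cand) if (mean(p1 >= t) >= req && t > best) best <- t
  best
}

# Shared full-size default pipeline run, computed once per test session.
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- suppressWarnings(run_pipeline(landscape_config()))
  }
  .run_cache$run
}

# Small occurrence tibble builder.
make_records <- function(dates, x = NULL, y = NULL, source = "field",
                         individual_id = NA_character_,
                         life_stage = "adult", accuracy_m = 10) {
  n <- length(dates)
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    source = rep_len(source, n),
    date = as.POSIXct(dates, tz = "UTC"),
    x = if (is.null(x)) seq(150, by = 100, length.out = n) else rep_len(x, n),
    y = if (is.null(y)) rep(150, n) else rep_len(y, n),
    individual_id = rep_len(individual_id, n),
    life_stage = rep_len(life_stage, n),
    accuracy_m = rep_len(accuracy_m, n)
  )
}
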