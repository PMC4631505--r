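# Neighbor offsets in the fixed tie-break order N, NE, E, SE, S, SW, W, NW
# (row 1 = north edge, so "N" is row - 1).
NB_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
NB_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

# Shift a matrix by (dr, dc), padding with NA. shift(m, -1, 0)[r, c] is the
# value of the cell one row north of (r, c).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs + dr; csrc <- cs + dc
  rok <- rsrc >= 1L & rsrc <= nr; cok <- csrc >= 1L & csrc <= nc
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

#' Slope and aspect by Horn's 3x3 method
#'
#' Finite-difference gradients over the 3x3 window with double weight on the
#' cardinal neighbours. Cells on the grid border or adjacent to nodata have
#' no full window and are set to nodata. Flat cells get slope 0 and an
#' undefined (NA) aspect.
#'
#' @param dem elevation raster_grid, metres.
#' @return Named list of raster_grids: `slope` (degrees, 0-90) and `aspect`
#'   (degrees clockwise from north, `[0, 360)`).
#' @export
compute_slope_aspect <- function(dem) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  if (all(is.na(z))) stop("DEM has no valid cells")
  cs <- dem$cell_size
  nw <- shift_mat(z, -1L, -1L); n <- shift_mat(z, -1L, 0L)
  ne <- shift_mat(z, -1L, 1L)
  w  <- shift_mat(z, 0L, -1L);  e <- shift_mat(z, 0L, 1L)
  sw <- shift_mat(z, 1L, -1L);  s <- shift_mat(z, 1L, 0L)
  se <- shift_mat(z, 1L, 1L)
  gx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cs)
  gy <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * cs)
  ok <- !is.na(z) & !is.na(gx) & !is.na(gy)
  slope <- matrix(NA_real_, nrow(z), ncol(z))
  slope[ok] <- atan(sqrt(gx[ok]^2 + gy[ok]^2)) * 180 / pi
  aspect <- matrix(NA_real_, nrow(z), ncol(z))
  nonflat <- ok & (gx != 0 | gy != 0)
  aspect[nonflat] <- (atan2(-gx[nonflat], -gy[nonflat]) * 180 / pi) %% 360
  list(slope = new_like(dem, slope, "slope"),
       aspect = new_like(dem, aspect, "aspect"))
}

#' Solar-incidence aspect transform
#'
#' Maps aspect onto `[-1, 1]` as `-cos(aspect * pi / 180)`: -1 on
#' north-facing slopes (low solar incidence) through +1 on south-facing
#' slopes. Because aspect is meaningless on near-level ground, cells with
#' slope below `flat_slope` degrees (default 5) — or with undefined aspect —
#' are assigned the neutral value 0.
#'
#' @param aspect aspect raster_grid (degrees clockwise from north), or a
#'   bare numeric vector for pointwise evaluation.
#' @param slope slope raster_grid (degrees), or numeric vector matching
#'   `aspect`.
#' @param flat_slope slope threshold in degrees below which aspect is
#'   neutralized.
#' @return A raster_grid (or numeric vector) of transformed aspect in
#'   `[-1, 1]`.
#' @export
transform_aspect <- function(aspect, slope, flat_slope = 5) {
  if (is_raster_grid(aspect)) {
    check_aligned(aspect, slope)
    a <- aspect$values; s <- slope$values
  } else {
    a <- aspect; s <- slope
    stopifnot(length(a) == length(s))
  }
  x <- -cos(a * pi / 180)
  x[is.na(a)] <- 0
  x[!is.na(s) & s < flat_slope] <- 0
  x[is.na(s)] <- NA_real_
  if (is_raster_grid(aspect)) new_like(aspect, x, "aspect_t") else x
}

# Binary min-heap keyed on numeric priority, used by the priority flood.
# Implemented over preallocated vectors; push/pop are O(log n).
heap_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$key <- numeric(n); env$val <- integer(n); env$size <- 0L
  env
}
heap_push <- function(h, key, val) {
  i <- h$size + 1L
  h$size <- i
  h$key[i] <- key; h$val[i] <- val
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[p] <= h$key[i]) break
    tk <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tk
    tv <- h$val[p]; h$val[p] <- h$val[i]; h$val[i] <- tv
    i <- p
  }
}
heap_pop <- function(h) {
  out <- h$val[1L]
  n <- h$size
  h$key[1L] <- h$key[n]; h$val[1L] <- h$val[n]
  h$size <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= h$size && h$key[l] < h$key[m]) m <- l
    if (r <= h$size && h$key[r] < h$key[m]) m <- r
    if (m == i) break
    tk <- h$key[m]; h$key[m] <- h$key[i]; h$key[i] <- tk
    tv <- h$val[m]; h$val[m] <- h$val[i]; h$val[i] <- tv
    i <- m
  }
  out
}

#' Fill closed depressions by priority flood
#'
#' Raises every internally drained cell to the lowest spill level reachable
#' from the grid boundary (cells on the edge or touching nodata), plus a tiny
#' epsilon per step so filled flats acquire a deterministic drainage gradient
#' toward their spill point. Processing order is a min-heap on filled
#' elevation with the fixed neighbour order as tie-break, so the result is
#' deterministic.
#'
#' @param dem elevation raster_grid.
#' @param eps elevation increment (m) applied along filled flats.
#' @return A raster_grid of hydrologically conditioned elevations.
#' @export
fill_pits <- function(dem, eps = 1e-4) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  n_valid <- sum(valid)
  if (n_valid == 0) stop("DEM has no valid cells")
  filled <- z
  seen <- matrix(FALSE, nr, nc)
  h <- heap_new(n_valid)
  # seeds: valid cells on the grid edge or adjacent to nodata
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  near_na <- matrix(FALSE, nr, nc)
  for (k in 1:8) {
    nb <- shift_mat(z, NB_DR[k], NB_DC[k])
    inb <- shift_mat(matrix(1, nr, nc), NB_DR[k], NB_DC[k])
    near_na <- near_na | (!is.na(inb) & is.na(nb))
  }
  seeds <- which(valid & (edge | near_na))
  for (i in seeds) {
    heap_push(h, z[i], i)
    seen[i] <- TRUE
  }
  while (h$size > 0L) {
    i <- heap_pop(h)
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + NB_DR[k]; ccc <- cc + NB_DC[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      j <- (ccc - 1L) * nr + rr
      if (seen[j] || !valid[j]) next
      filled[j] <- max(z[j], filled[i] + eps)
      heap_push(h, filled[j], j)
      seen[j] <- TRUE
    }
  }
  new_like(dem, filled, "elevation_filled")
}

#' D8 flow accumulation
#'
#' Routes each cell to its steepest-descent neighbour of eight
#' (distance-weighted drop; diagonal distance is `cell_size * sqrt(2)`) and
#' counts, for every cell, the number of cells whose flow path passes
#' through it, excluding the cell itself. Ties in steepest descent break by
#' the fixed order N, NE, E, SE, S, SW, W, NW. Cells with no lower valid
#' neighbour (grid edge, nodata margin, or pits when filling is off) are
#' outlets.
#'
#' @param dem elevation raster_grid.
#' @param fill fill depressions first with [fill_pits()] (default `TRUE`);
#'   set `FALSE` to study raw-surface routing.
#' @return A raster_grid of upstream cell counts (>= 0).
#' @export
flow_accumulation_d8 <- function(dem, fill = TRUE) {
  stopifnot(is_raster_grid(dem))
  z0 <- if (fill) fill_pits(dem)$values else dem$values
  nr <- nrow(z0); nc <- ncol(z0)
  n <- nr * nc
  dist <- dem$cell_size * ifelse(NB_DR != 0 & NB_DC != 0, sqrt(2), 1)
  grad <- matrix(-Inf, n, 8L)
  for (k in 1:8) {
    nbz <- shift_mat(z0, NB_DR[k], NB_DC[k])
    g <- (z0 - nbz) / dist[k]
    g[is.na(g)] <- -Inf
    grad[, k] <- as.vector(g)
  }
  best_k <- max.col(grad, ties.method = "first")
  best_g <- grad[cbind(seq_len(n), best_k)]
  receiver <- rep(NA_integer_, n)
  has_rec <- !is.na(as.vector(z0)) & best_g > 0
  idx <- which(has_rec)
  receiver[idx] <- idx + NB_DR[best_k[idx]] + NB_DC[best_k[idx]] * nr
  acc <- rep(0, n)
  valid_idx <- which(!is.na(as.vector(z0)))
  ord <- valid_idx[order(z0[valid_idx], decreasing = TRUE)]
  for (i in ord) {
    r <- receiver[i]
    if (!is.na(r)) acc[r] <- acc[r] + acc[i] + 1
  }
  acc[is.na(as.vector(z0))] <- NA
  out <- matrix(acc, nr, nc)
  res <- new_like(dem, out, "flow_acc")
  attr(res, "receiver") <- receiver
  res
}

#' Compound topographic index
#'
#' The wetness index `ln(As / tan(beta))` with contributing area
#' `As = (flow accumulation + 1) * cell area` in square metres and `beta`
#' the slope in radians, floored at `beta_min` so level cells keep a finite
#' index. Low values mark ridges and steep slopes; high values mark
#' depressions and gentle drainage accumulations.
#'
#' @param dem elevation raster (supplies the cell area and nodata mask).
#' @param flow_acc D8 accumulation raster from [flow_accumulation_d8()].
#' @param slope slope raster in degrees.
#' @param beta_min slope floor, radians.
#' @return A raster_grid of CTI values.
#' @export
compute_cti <- function(dem, flow_acc, slope, beta_min = 0.001) {
  check_aligned(dem, flow_acc, slope)
  area <- dem$cell_size^2
  As <- (flow_acc$values + 1) * area
  beta <- pmax(slope$values * pi / 180, beta_min)
  new_like(dem, log(As / tan(beta)), "cti")
}

#' Vector ruggedness measure
#'
#' Terrain heterogeneity over each cell's 3x3 neighbourhood: unit surface
#' normals `(sin s sin a, sin s cos a, cos s)` are summed, and
#' `vrm = 1 - |resultant| / n` where `n` counts the valid cells in the
#' window. 0 is a perfectly smooth surface (all normals parallel); values
#' approach 1 on maximally disordered terrain. Flat cells contribute a
#' vertical normal. Cells at the edge of the valid region use the
#' neighbours they have, with `n` adjusted.
#'
#' @param slope slope raster, degrees.
#' @param aspect aspect raster, degrees clockwise from north (NA on flats).
#' @return A raster_grid with values in `[0, 1]`.
#' @export
compute_vrm <- function(slope, aspect) {
  check_aligned(slope, aspect)
  s <- slope$values * pi / 180
  a <- aspect$values * pi / 180
  ok <- !is.na(s)
  zc <- cos(s); xc <- sin(s) * sin(a); yc <- sin(s) * cos(a)
  # flats: undefined aspect, vertical normal
  flat <- ok & is.na(a)
  xc[flat] <- 0; yc[flat] <- 0
  zc[!ok] <- NA
  nr <- nrow(s); nc <- ncol(s)
  sx <- matrix(0, nr, nc); sy <- sx; sz <- sx; nn <- sx
  offs <- rbind(cbind(NB_DR, NB_DC), c(0L, 0L))
  for (k in seq_len(nrow(offs))) {
    xs <- shift_mat(xc, offs[k, 1], offs[k, 2])
    ys <- shift_mat(yc, offs[k, 1], offs[k, 2])
    zs <- shift_mat(zc, offs[k, 1], offs[k, 2])
    nbok <- !is.na(zs)
    sx[nbok] <- sx[nbok] + xs[nbok]
    sy[nbok] <- sy[nbok] + ys[nbok]
    sz[nbok] <- sz[nbok] + zs[nbok]
    nn <- nn + nbok
  }
  vrm <- 1 - sqrt(sx^2 + sy^2 + sz^2) / nn
  vrm[!ok] <- NA
  vrm <- pmin(pmax(vrm, 0), 1)
  new_like(slope, vrm, "vrm")
}

#' Derive all terrain predictor layers from a DEM
#'
#' Convenience wrapper running [compute_slope_aspect()],
#' [transform_aspect()], [flow_accumulation_d8()], [compute_cti()] and
#' [compute_vrm()].
#'
#' @param dem elevation raster_grid.
#' @param flat_slope slope threshold for the aspect transform, degrees.
#' @return Named list of raster_grids: `slope`, `aspect`, `aspect_t`,
#'   `flow_acc`, `cti`, `vrm`.
#' @export
terrain_layers <- function(dem, flat_slope = 5) {
  sa <- compute_slope_aspect(dem)
  acc <- flow_accumulation_d8(dem)
  list(
    slope = sa$slope,
    aspect = sa$aspect,
    aspect_t = transform_aspect(sa$aspect, sa$slope, flat_slope),
    flow_acc = acc,
    cti = compute_cti(dem, acc, sa$slope),
    vrm = compute_vrm(sa$slope, sa$aspect)
  )
}

#' Assemble the eight-predictor stack
#'
#' Combines elevation, the terrain derivatives and the three climate
#' surfaces into the aligned named stack used for model fitting and
#' projection. All layers are masked to cells where every predictor is
#' defined (terrain derivatives are undefined along the nodata margin).
#'
#' @param dem elevation raster.
#' @param climate named list with `mst`, `msp`, `pas` rasters (see
#'   [generate_climate()]).
#' @param terrain optional precomputed [terrain_layers()] result.
#' @param scenario optional scenario label attached as an attribute.
#' @return A named list of 8 raster_grids (`elevation`, `aspect_t`, `slope`,
#'   `cti`, `vrm`, `mst`, `msp`, `pas`) with class `predictor_stack`.
#' @export
build_predictor_stack <- function(dem, climate, terrain = NULL,
                                  scenario = "baseline") {
  stopifnot(all(c("mst", "msp", "pas") %in% names(climate)))
  if (is.null(terrain)) terrain <- terrain_layers(dem)
  layers <- list(elevation = dem, aspect_t = terrain$aspect_t,
                 slope = terrain$slope, cti = terrain$cti,
                 vrm = terrain$vrm, mst = climate$mst, msp = climate$msp,
                 pas = climate$pas)
  do.call(check_aligned, layers)
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) {
    v <- l$values
    v[mask] <- NA
    new_like(l, v, l$layer)
  })
  structure(layers, class = "predictor_stack", scenario = scenario)
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> scenario '%s', layers: %s\n",
              attr(x, "scenario"), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Predictor values at every valid cell
#'
#' @param stack a predictor_stack.
#' @return A tibble with `row`, `col`, `x`, `y` and one column per layer;
#'   only cells valid in all layers are returned.
#' @export
stack_to_tibble <- function(stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  base <- cell_centers(stack[[1]])[, c("row", "col", "x", "y")]
  for (nm in names(stack)) base[[nm]] <- as.vector(stack[[nm]]$values)
  tidyr::drop_na(base, dplyr::all_of(names(stack)))
}
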