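#' Minimum convex polygon of a point set
#'
#' The convex hull of the occurrence points, the classic minimum-convex-
#' polygon range estimator.
#'
#' @param points tibble or data frame with `x` and `y` in metres.
#' @return A tibble of hull vertices (`x`, `y`) in counter-clockwise order.
#' @export
minimum_convex_polygon <- function(points) {
  stopifnot(all(c("x", "y") %in% names(points)))
  pts <- unique(tibble::tibble(x = points$x, y = points$y))
  if (nrow(pts) < 3) stop("need at least 3 distinct points for a hull")
  idx <- grDevices::chull(pts$x, pts$y)
  if (length(idx) < 3) stop("points are collinear; hull is degenerate")
  hull <- pts[rev(idx), , drop = FALSE]  # chull is clockwise; reverse to CCW
  tibble::as_tibble(hull)
}

# Ray-casting point-in-polygon (boundary counts as inside via the distance
# test used alongside it).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# Distance from points to a polygon boundary (minimum over edges).
dist_to_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- vx[i] - vx[j]; ey <- vy[i] - vy[j]
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) pmin(pmax(((px - vx[j]) * ex + (py - vy[j]) * ey) /
                                   len2, 0), 1) else 0
    dx <- px - (vx[j] + t * ex); dy <- py - (vy[j] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

#' Build the constrained pseudo-absence background
#'
#' A cell is eligible when its centre lies inside the minimum convex polygon
#' of the presences dilated outward by `buffer_m`, its zone is one of
#' `zones_allowed`, and it is a valid (non-nodata) cell. Eligibility is
#' decided at cell centres, matching the raster resolution.
#'
#' @param points presence tibble with `x`, `y`.
#' @param zones categorical zone raster from [generate_zones()].
#' @param grid reference raster_grid (defines valid cells).
#' @param buffer_m outward buffer around the hull, metres (default 200).
#' @param zones_allowed character zone labels eligible as background
#'   (default alpine + subalpine).
#' @return A `background_mask`: logical raster plus a `provenance` list.
#' @export
build_background <- function(points, zones, grid, buffer_m = 200,
                             zones_allowed = c("CMA", "MH")) {
  check_aligned(zones, grid)
  if (length(zones_allowed) == 0) stop("zones_allowed must be non-empty")
  lv <- attr(zones, "levels") %||% c("CWH", "MH", "CMA")
  codes <- match(zones_allowed, lv)
  if (anyNA(codes)) stop("unknown zone label(s): ",
                         paste(zones_allowed[is.na(codes)], collapse = ", "))
  hull <- minimum_convex_polygon(points)
  cc <- cell_centers(grid)
  inside <- point_in_polygon(cc$x, cc$y, hull$x, hull$y)
  near <- dist_to_polygon(cc$x, cc$y, hull$x, hull$y) <= buffer_m
  zone_ok <- as.vector(zones$values) %in% codes
  valid <- !is.na(as.vector(grid$values))
  elig <- (inside | near) & zone_ok & valid
  if (!any(elig)) stop("background is empty under the given constraints ",
                       "(hull + ", buffer_m, " m, zones ",
                       paste(zones_allowed, collapse = "/"), ")")
  mask <- new_like(grid, matrix(elig, nrow(grid$values)), "background")
  structure(list(
    eligible = mask,
    provenance = list(buffer_m = buffer_m, zones_allowed = zones_allowed,
                      exclusion_m = 0, n_hull_vertices = nrow(hull))
  ), class = "background_mask")
}

#' @export
print.background_mask <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<background_mask> %d eligible cells (MCP + %g m, zones %s, presence exclusion %g m)\n",
    sum(x$eligible$values, na.rm = TRUE), p$buffer_m,
    paste(p$zones_allowed, collapse = "/"), p$exclusion_m))
  invisible(x)
}

#' Exclude a buffer around presences from the background
#'
#' Cells whose centre lies within `radius_m` (a closed ball: exactly
#' `radius_m` counts as inside) of any presence become ineligible, so
#' pseudo-absences cannot fall where the species was, or trivially close to
#' where it was, observed.
#'
#' @param mask a `background_mask` from [build_background()].
#' @param points presence tibble with `x`, `y`.
#' @param radius_m exclusion radius, metres (default 200).
#' @return The updated `background_mask`.
#' @export
exclude_presence_buffer <- function(mask, points, radius_m = 200) {
  stopifnot(inherits(mask, "background_mask"))
  grid <- mask$eligible
  cc <- cell_centers(grid)
  elig <- as.vector(grid$values)
  cand <- which(elig)
  if (length(cand) && nrow(points)) {
    r2 <- radius_m^2
    for (i in seq_len(nrow(points))) {
      d2 <- (cc$x[cand] - points$x[i])^2 + (cc$y[cand] - points$y[i])^2
      cand <- cand[d2 > r2]
      if (!length(cand)) break
    }
    drop <- setdiff(which(elig), cand)
    elig[drop] <- FALSE
  }
  mask$eligible <- new_like(grid, matrix(elig, nrow(grid$values)),
                            "background")
  mask$provenance$exclusion_m <- radius_m
  mask
}

#' Sample pseudo-absence locations
#'
#' Draws `ratio` times the number of presences as distinct eligible cells,
#' uniformly without replacement, and returns their centres labelled 0.
#'
#' @param mask a `background_mask`.
#' @param n_presences number of presence locations.
#' @param ratio pseudo-absences per presence (default 2).
#' @param seed integer seed.
#' @return Tibble with `x`, `y`, `label` (= 0).
#' @export
sample_pseudo_absences <- function(mask, n_presences, ratio = 2, seed = 1L) {
  stopifnot(inherits(mask, "background_mask"))
  n_draw <- ratio * n_presences
  grid <- mask$eligible
  elig_idx <- which(as.vector(grid$values))
  if (length(elig_idx) < n_draw) {
    stop("only ", length(elig_idx), " eligible background cells for ",
         n_draw, " pseudo-absences (shortfall ",
         n_draw - length(elig_idx), ")")
  }
  withr::local_seed(seed)
  pick <- sample(elig_idx, n_draw)
  cc <- cell_centers(grid)
  tibble::tibble(x = cc$x[pick], y = cc$y[pick], label = 0L)
}
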