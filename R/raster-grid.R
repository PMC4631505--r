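#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix with square cells in a
#' projected coordinate system measured in metres. Row 1 is the northern
#' edge; cell centres sit at half-cell offsets from the lower-left corner
#' (`xmin`, `ymin`). Missing cells (ocean, outside the study area) are `NA`.
#'
#' @param values numeric matrix (row 1 = north edge).
#' @param cell_size cell edge length in metres (> 0).
#' @param xmin,ymin coordinates of the lower-left corner of the grid, metres.
#' @param layer optional layer name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 100, xmin = 0, ymin = 0,
                        layer = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values),
            is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         layer = layer %||% "layer"),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid '%s'> %d x %d cells, %g m resolution\n",
              x$layer, nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$xmin, x$xmin + ncol(x$values) * x$cell_size,
              x$ymin, x$ymin + nrow(x$values) * x$cell_size))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g] over %d valid cells (%d NA)\n",
                min(v), max(v), length(v), sum(is.na(x$values))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' Test whether an object is a raster_grid
#' @param x object.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Do two rasters share the same grid?
#'
#' Same dimensions, cell size and origin. Used as a precondition by every
#' operation that combines layers.
#' @param a,b raster_grid objects.
#' @export
same_grid <- function(a, b) {
  is_raster_grid(a) && is_raster_grid(b) &&
    identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xmin, b$xmin)) &&
    isTRUE(all.equal(a$ymin, b$ymin))
}

check_aligned <- function(..., .names = NULL) {
  grids <- list(...)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!same_grid(ref, g)) {
      stop("raster layers are not on the same grid (dimensions, cell size ",
           "and origin must match)", call. = FALSE)
    }
  }
  invisible(ref)
}

#' Coordinates of every cell centre
#'
#' @param grid a raster_grid.
#' @return A tibble with `row`, `col`, `x`, `y` and `value` for every cell
#'   (including `NA` cells).
#' @export
cell_centers <- function(grid) {
  stopifnot(is_raster_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  tibble::tibble(
    row = rows, col = cols,
    x = grid$xmin + (cols - 0.5) * grid$cell_size,
    y = grid$ymin + (nr - rows + 0.5) * grid$cell_size,
    value = as.vector(grid$values)
  )
}

#' Row/column of the cell containing each point
#'
#' Points on a cell boundary belong to the cell to the north-east of the
#' boundary (half-open cells), matching the usual raster convention.
#'
#' @param grid a raster_grid.
#' @param x,y point coordinates in metres.
#' @return A tibble with `row`, `col` and logical `inside`.
#' @export
cell_of_xy <- function(grid, x, y) {
  stopifnot(is_raster_grid(grid), length(x) == length(y))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xmin) / grid$cell_size) + 1L
  row <- nr - floor((y - grid$ymin) / grid$cell_size)
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 inside = inside)
}

#' Convert a raster to a long tibble of valid cells
#'
#' @param grid a raster_grid.
#' @param na_rm drop `NA` cells (default `TRUE`).
#' @export
raster_to_tibble <- function(grid, na_rm = TRUE) {
  out <- cell_centers(grid)
  if (na_rm) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

new_like <- function(grid, values, layer = grid$layer) {
  raster_grid(values, cell_size = grid$cell_size, xmin = grid$xmin,
              ymin = grid$ymin, layer = layer)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS; one header block
#' then rows north to south. `NA` cells are written as the nodata value.
#'
#' @param grid a raster_grid.
#' @param path output file path (conventionally `.asc`).
#' @param nodata numeric nodata sentinel (default -9999).
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$xmin),
    sprintf("yllcorner %.6f", grid$ymin),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param layer layer name to attach.
#' @return a raster_grid.
#' @export
read_ascii_grid <- function(path, layer = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  body <- lines[seq(i, length(lines))]
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, cell_size = hdr$cellsize, xmin = hdr$xllcorner,
              ymin = hdr$yllcorner,
              layer = layer %||% sub("\\.[^.]*$", "", basename(path)))
}
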