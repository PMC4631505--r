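#' Habitat area of a binary map
#'
#' Number of suitable cells times the cell area in square kilometres
#' (0.01 km^2 for 100 m cells).
#'
#' @param binary 0/1 habitat raster from [binarize()].
#' @return Area in km^2.
#' @export
habitat_area <- function(binary) {
  stopifnot(is_raster_grid(binary))
  cell_km2 <- (binary$cell_size / 1000)^2
  sum(binary$values == 1, na.rm = TRUE) * cell_km2
}

#' Range change between a baseline and a future habitat map
#'
#' `RC = 100 * (RG - RL) / BR`, with range gain `RG` (area suitable in the
#' future but not the baseline), range loss `RL` (suitable in the baseline
#' but not the future) and baseline range `BR`, all summed cell by cell in
#' km^2.
#'
#' @param baseline_bin,future_bin aligned 0/1 habitat rasters.
#' @return A one-row tibble with `rg_km2`, `rl_km2`, `br_km2`,
#'   `future_km2`, `rc_percent`.
#' @export
range_change <- function(baseline_bin, future_bin) {
  check_aligned(baseline_bin, future_bin)
  cell_km2 <- (baseline_bin$cell_size / 1000)^2
  b <- baseline_bin$values == 1
  f <- future_bin$values == 1
  br <- sum(b, na.rm = TRUE) * cell_km2
  if (br == 0) stop("baseline range is empty; range change undefined")
  rg <- sum(f & !b, na.rm = TRUE) * cell_km2
  rl <- sum(b & !f, na.rm = TRUE) * cell_km2
  tibble::tibble(rg_km2 = rg, rl_km2 = rl, br_km2 = br,
                 future_km2 = sum(f, na.rm = TRUE) * cell_km2,
                 rc_percent = 100 * (rg - rl) / br)
}

#' Label connected habitat patches
#'
#' Maximal connected components of suitable cells under queen (8) or rook
#' (4) adjacency, labelled 1..n by discovery order (row-major first cell).
#' Non-habitat cells are 0 and nodata stays NA.
#'
#' @param binary 0/1 habitat raster.
#' @param connectivity 8 (default; diagonals connect) or 4.
#' @return An integer raster_grid of patch labels.
#' @export
label_patches <- function(binary, connectivity = 8) {
  stopifnot(is_raster_grid(binary), connectivity %in% c(4, 8))
  v <- binary$values
  nr <- nrow(v); nc <- ncol(v)
  hab <- !is.na(v) & v == 1
  lab <- matrix(0, nr, nc)
  lab[is.na(v)] <- NA
  dr <- NB_DR; dc <- NB_DC
  if (connectivity == 4) {
    keep <- dr == 0 | dc == 0
    dr <- dr[keep]; dc <- dc[keep]
  }
  nextlab <- 0L
  queue <- integer(sum(hab))
  for (start in which(hab & lab == 0)) {
    if (lab[start] != 0) next
    nextlab <- nextlab + 1L
    lab[start] <- nextlab
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      i <- queue[head]; head <- head + 1L
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; ccc <- cc + dc[k]
        if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
        j <- (ccc - 1L) * nr + rr
        if (hab[j] && lab[j] == 0) {
          lab[j] <- nextlab
          tail <- tail + 1L
          queue[tail] <- j
        }
      }
    }
  }
  out <- new_like(binary, lab, "patches")
  attr(out, "scenario") <- attr(binary, "scenario")
  attr(out, "connectivity") <- connectivity
  out
}

#' Patch configuration report
#'
#' Per-patch areas and mean elevations plus landscape-level summaries: patch
#' count, mean patch size, mean patch elevation (the unweighted mean across
#' patches of each patch's mean cell elevation, with its SD across patches),
#' the largest-patch fraction of total habitat, and a patch-size histogram.
#'
#' @param labeled patch-label raster from [label_patches()].
#' @param dem aligned elevation raster.
#' @param size_bins histogram bin edges in km^2 (default
#'   `c(0, 0.5, 1, 2, 5, 10, Inf)`).
#' @return A `patch_report`; `tidy()` gives the per-patch tibble, `glance()`
#'   the one-row summary.
#' @export
patch_report <- function(labeled, dem,
                         size_bins = c(0, 0.5, 1, 2, 5, 10, Inf)) {
  check_aligned(labeled, dem)
  cell_km2 <- (labeled$cell_size / 1000)^2
  lv <- as.vector(labeled$values)
  ev <- as.vector(dem$values)
  inpatch <- !is.na(lv) & lv > 0
  if (!any(inpatch)) {
    patches <- tibble::tibble(patch = integer(), n_cells = integer(),
                              area_km2 = numeric(), mean_elev_m = numeric())
  } else {
    patches <- tibble::tibble(patch = as.integer(lv[inpatch]),
                              elev = ev[inpatch]) |>
      dplyr::group_by(.data$patch) |>
      dplyr::summarise(n_cells = dplyr::n(),
                       mean_elev_m = mean(.data$elev), .groups = "drop") |>
      dplyr::mutate(area_km2 = .data$n_cells * cell_km2) |>
      dplyr::select("patch", "n_cells", "area_km2", "mean_elev_m")
  }
  n <- nrow(patches)
  total <- sum(patches$area_km2)
  hist_counts <- if (n) {
    as.integer(table(cut(patches$area_km2, breaks = size_bins,
                         include.lowest = TRUE)))
  } else {
    rep(0L, length(size_bins) - 1L)
  }
  summary <- tibble::tibble(
    n_patches = n,
    total_area_km2 = total,
    mean_patch_size_km2 = if (n) total / n else NA_real_,
    mean_patch_elevation_m = if (n) mean(patches$mean_elev_m) else NA_real_,
    sd_patch_elevation_m = if (n > 1) sd(patches$mean_elev_m) else
      if (n == 1) 0 else NA_real_,
    largest_patch_fraction = if (n) max(patches$area_km2) / total else
      NA_real_
  )
  structure(list(patches = patches, summary = summary,
                 size_histogram = tibble::tibble(
                   bin_low = utils::head(size_bins, -1L),
                   bin_high = size_bins[-1L],
                   count = hist_counts),
                 scenario = attr(labeled, "scenario"),
                 connectivity = attr(labeled, "connectivity")),
            class = "patch_report")
}

#' @export
print.patch_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<patch_report> %d patches, %.2f km^2 total, mean size %.2f km^2, mean elevation %.0f m\n",
    s$n_patches, s$total_area_km2, s$mean_patch_size_km2,
    s$mean_patch_elevation_m))
  invisible(x)
}

#' @describeIn patch_report per-patch tibble.
#' @param x a `patch_report`.
#' @param ... unused.
#' @method tidy patch_report
#' @export
tidy.patch_report <- function(x, ...) x$patches

#' @describeIn patch_report one-row landscape summary.
#' @method glance patch_report
#' @export
glance.patch_report <- function(x, ...) x$summary

#' Mean elevation of suitable habitat
#'
#' The cell-weighted mean elevation of all suitable cells: where the
#' habitat actually sits, with each cell counting equally. Contrast with
#' the patch-weighted `mean_patch_elevation_m` of [patch_report()], which
#' weights every patch equally regardless of size.
#'
#' @param binary 0/1 habitat raster.
#' @param dem aligned elevation raster.
#' @return Mean elevation in metres, or `NA` when no cell is suitable.
#' @export
habitat_elevation <- function(binary, dem) {
  check_aligned(binary, dem)
  suit <- !is.na(binary$values) & binary$values == 1
  if (!any(suit)) return(NA_real_)
  mean(dem$values[suit], na.rm = TRUE)
}

#' Per-scenario configuration metrics for a projected map set
#'
#' For every future map in a `scenario_maps` object: range change against
#' the baseline, and the patch metrics of [patch_report()]. The baseline row
#' is included with `rc_percent = 0`.
#'
#' @param maps a `scenario_maps` object.
#' @param dem aligned elevation raster.
#' @param connectivity patch adjacency (default 8).
#' @return A tibble, one row per scenario.
#' @export
scenario_metrics <- function(maps, dem, connectivity = 8) {
  stopifnot(inherits(maps, "scenario_maps"))
  base <- maps$binary[["baseline"]]
  purrr::pmap_dfr(maps$meta, function(gcm, rcp, period, label) {
    b <- maps$binary[[label]]
    rc <- if (period == "baseline") {
      tibble::tibble(rg_km2 = 0, rl_km2 = 0,
                     br_km2 = habitat_area(base),
                     future_km2 = habitat_area(base), rc_percent = 0)
    } else {
      range_change(base, b)
    }
    rep <- patch_report(label_patches(b, connectivity), dem)
    dplyr::bind_cols(
      tibble::tibble(gcm = gcm, rcp = rcp, period = period, label = label),
      rc, glance(rep),
      tibble::tibble(habitat_elevation_m = habitat_elevation(b, dem)))
  })
}

#' Summarise scenario metrics across GCMs
#'
#' Per RCP x period: the mean and standard error (SD / sqrt(n GCMs)) across
#' GCMs of range change, patch count and mean patch size, and the mean and
#' SD of mean patch elevation. Requires the complete GCM factorial in every
#' RCP x period cell.
#'
#' @param metrics tibble from [scenario_metrics()] (baseline row optional
#'   and ignored).
#' @return A tibble, one row per RCP x period.
#' @export
scenario_summary <- function(metrics) {
  fut <- dplyr::filter(metrics, .data$period != "baseline")
  if (nrow(fut) == 0) stop("no future scenario rows to summarise")
  counts <- fut |>
    dplyr::count(.data$rcp, .data$period)
  if (length(unique(counts$n)) != 1 ||
      nrow(counts) != length(unique(fut$rcp)) *
        length(unique(fut$period))) {
    stop("incomplete GCM x RCP x period factorial")
  }
  se <- function(v) sd(v) / sqrt(length(v))
  fut |>
    dplyr::group_by(.data$rcp, .data$period) |>
    dplyr::summarise(
      n_gcm = dplyr::n(),
      rc_mean = mean(.data$rc_percent), rc_se = se(.data$rc_percent),
      area_mean_km2 = mean(.data$future_km2),
      area_se_km2 = se(.data$future_km2),
      n_patches_mean = mean(.data$n_patches),
      n_patches_se = se(.data$n_patches),
      patch_size_mean_km2 = mean(.data$mean_patch_size_km2),
      patch_size_se_km2 = se(.data$mean_patch_size_km2),
      elevation_mean_m = mean(.data$mean_patch_elevation_m),
      elevation_sd_m = sd(.data$mean_patch_elevation_m),
      .groups = "drop"
    )
}
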