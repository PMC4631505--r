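#' Configuration for a synthetic mountain-island landscape
#'
#' Bundles every knob of the synthetic generator: grid geometry, the shape of
#' the central north-south ridge, the elevation lapse rate that drives
#' temperature, the east-west precipitation gradient, the snow-fraction
#' coupling, and the coefficients of the true (generating) suitability
#' function used by [simulate_occurrences()].
#'
#' Defaults emulate a mid-latitude coastal mountain island: peak elevations
#' near 2200 m, a ~6 degC/km lapse rate, wetter western slopes, and snowfall
#' that grows with precipitation and falls off with temperature.
#'
#' @param grid_rows,grid_cols cell counts (each >= 32 so 3x3 terrain windows
#'   have room to work).
#' @param cell_size cell edge in metres.
#' @param seed master integer seed; identical seeds give bit-identical
#'   landscapes.
#' @param ridge_height target maximum elevation, metres.
#' @param sea_level_fraction approximate fraction of cells set to nodata as an
#'   ocean border ring.
#' @param lapse_rate temperature lapse rate, degC per km of elevation.
#' @param sea_level_temp mean summer temperature at sea level, degC.
#' @param precip_gradient increase in summer precipitation per km moving west
#'   from the east coast, mm.
#' @param precip_base summer precipitation at the east-coast sea level, mm.
#' @param precip_elev_coef orographic increase in precipitation, mm per metre
#'   of elevation.
#' @param annual_factor ratio of annual (snow-accounting) to summer
#'   precipitation.
#' @param pas_coefficient coupling of the snow fraction to temperature: the
#'   snow fraction is `plogis(-mst * pas_coefficient)`.
#' @param temp_noise_sd,precip_noise_sd standard deviations of the smooth
#'   climate noise fields (degC, mm). Set to 0 for noise-free surfaces.
#' @param noise_correlation correlation length of all smooth noise fields, in
#'   cells.
#' @param dem_noise_frac amplitude of terrain noise as a fraction of
#'   `ridge_height`.
#' @param zone_breaks two increasing elevations (m) separating the three
#'   surrogate biogeoclimatic zones (forest / subalpine / alpine).
#' @param truth_coefficients named weights of the generating suitability
#'   function on the standardized predictors `elevation`, `mst`, `pas`,
#'   `aspect_t`.
#' @param truth_intercept intercept of the generating suitability function
#'   on the logit scale. Negative values keep the suitability surface from
#'   saturating over the alpine zone, so occupancy contrasts with the
#'   zone-constrained background instead of blanketing it.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 128, grid_cols = 128,
                             cell_size = 100, seed = 1,
                             ridge_height = 2200,
                             sea_level_fraction = 0.1,
                             lapse_rate = 6.0,
                             sea_level_temp = 18,
                             precip_gradient = 15,
                             precip_base = 400,
                             precip_elev_coef = 0.2,
                             annual_factor = 6,
                             pas_coefficient = 0.15,
                             temp_noise_sd = 0.8,
                             precip_noise_sd = 30,
                             noise_correlation = 6,
                             dem_noise_frac = 0.06,
                             zone_breaks = c(750, 1350),
                             truth_coefficients = c(elevation = 1,
                                                    mst = -3,
                                                    pas = 1.5,
                                                    aspect_t = 0.3),
                             truth_intercept = -12) {
  stopifnot(grid_rows >= 32, grid_cols >= 32, cell_size > 0,
            ridge_height > 0, length(zone_breaks) == 2,
            diff(zone_breaks) > 0,
            all(c("elevation", "mst", "pas", "aspect_t") %in%
                  names(truth_coefficients)))
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, seed = as.integer(seed),
              ridge_height = ridge_height,
              sea_level_fraction = sea_level_fraction,
              lapse_rate = lapse_rate, sea_level_temp = sea_level_temp,
              precip_gradient = precip_gradient, precip_base = precip_base,
              precip_elev_coef = precip_elev_coef,
              annual_factor = annual_factor,
              pas_coefficient = pas_coefficient,
              temp_noise_sd = temp_noise_sd,
              precip_noise_sd = precip_noise_sd,
              noise_correlation = noise_correlation,
              dem_noise_frac = dem_noise_frac,
              zone_breaks = zone_breaks,
              truth_coefficients = truth_coefficients,
              truth_intercept = truth_intercept)
  structure(cfg, class = "landscape_config")
}

# Smooth (spatially correlated) unit-variance noise: white noise convolved
# with a separable Gaussian kernel, reflected at the edges, then standardized.
smooth_noise <- function(nr, nc, corr) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr <= 0) return(z)
  h <- max(1L, min(ceiling(2 * corr), nr - 1L, nc - 1L))
  k <- exp(-0.5 * (seq(-h, h) / corr)^2)
  k <- k / sum(k)
  pass <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(h)), seq_len(n), n + 1L - seq_len(h))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  z <- pass(z)
  z <- t(pass(t(z)))
  (z - mean(z)) / sd(z)
}

# Width of the nodata border ring whose area is closest to the requested
# ocean fraction.
ocean_ring_width <- function(nr, nc, fraction) {
  if (fraction <= 0) return(0L)
  w <- 0:floor(min(nr, nc) / 2 - 1)
  frac <- 1 - (nr - 2 * w) * (nc - 2 * w) / (nr * nc)
  max(1L, w[which.min(abs(frac - fraction))])
}

#' Generate a synthetic digital elevation model
#'
#' Builds a mountainous island: a central north-south spine of summits of
#' graded heights — highest mid-island, lower and more fragmented toward
#' the ends — plus smooth correlated noise, clamped to
#' `[0, ridge_height]`, with an ocean border ring of nodata cells. The
#' multi-summit hypsometry matters: high-elevation area declines gradually
#' with elevation, so a warming-driven uplift of the habitat band removes
#' area summit by summit rather than all at once. Deterministic per
#' `config$seed`.
#'
#' @param config a [landscape_config()].
#' @return A raster_grid of elevations in metres.
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  withr::local_seed(stage_seed(config$seed, "dem"))
  xf <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  yf <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  # summit heights as fractions of ridge_height, mid-island highest;
  # positions along the spine jittered per seed
  hfrac <- c(0.62, 0.78, 0.95, 0.88, 0.72, 0.58)
  npk <- length(hfrac)
  py <- seq(0.12, 0.88, length.out = npk) + runif(npk, -0.03, 0.03)
  px <- 0.5 + runif(npk, -0.05, 0.05)
  sx <- runif(npk, 0.09, 0.13)   # cross-island summit half-width
  sy <- runif(npk, 0.11, 0.16)   # along-spine summit half-width
  base <- matrix(0, nr, nc)
  for (p in seq_len(npk)) {
    d2 <- ((xf - px[p]) / sx[p])^2 + ((yf - py[p]) / sy[p])^2
    base <- pmax(base, hfrac[p] * config$ridge_height * exp(-d2))
  }
  noise <- smooth_noise(nr, nc, config$noise_correlation) *
    config$dem_noise_frac * config$ridge_height
  dem <- pmin(pmax(base + noise, 0), config$ridge_height)
  w <- ocean_ring_width(nr, nc, config$sea_level_fraction)
  if (w > 0) {
    ring <- seq_len(w)
    dem[ring, ] <- NA; dem[nr + 1L - ring, ] <- NA
    dem[, ring] <- NA; dem[, nc + 1L - ring] <- NA
  }
  raster_grid(dem, cell_size = config$cell_size, layer = "elevation")
}

#' Scenario offsets for one climate future
#'
#' A scenario is a (GCM, emission pathway, period) cell with the additive
#' temperature offset `d_mst` (degC) and multiplicative precipitation and
#' snowfall factors `d_msp`, `d_pas` applied to the baseline surfaces.
#'
#' @param gcm climate-model label (`"Can"`, `"CCSM"`, `"GFDL"`, or
#'   `"none"` for the baseline).
#' @param rcp emission-pathway label (`"4.5"`, `"8.5"`, or `"none"`).
#' @param period `"baseline"`, `"2025"`, `"2055"` or `"2085"`.
#' @param d_mst additive mean-summer-temperature offset, degC.
#' @param d_msp multiplicative summer-precipitation factor.
#' @param d_pas multiplicative snowfall factor.
#' @return A one-row tibble.
#' @export
scenario_delta <- function(gcm = "none", rcp = "none", period = "baseline",
                           d_mst = 0, d_msp = 1, d_pas = 1) {
  stopifnot(period %in% c("baseline", "2025", "2055", "2085"))
  if (period == "baseline") {
    stopifnot(d_mst == 0, d_msp == 1, d_pas == 1)
  }
  tibble::tibble(gcm = gcm, rcp = rcp, period = period,
                 d_mst = d_mst, d_msp = d_msp, d_pas = d_pas)
}

#' Default scenario-offset table
#'
#' One baseline row plus the full 3 GCM x 2 RCP x 3 period factorial.
#' Warming is ordered Can > GFDL > CCSM and RCP 8.5 > RCP 4.5, spanning
#' roughly +1 to +5 degC by 2085; precipitation rises most under the wettest
#' model. The snowfall factor `d_pas` is left at 1: snowfall already falls
#' endogenously with temperature through the generator's snow-fraction
#' coupling, and an additional exogenous multiplier would double-count the
#' same mechanism. These magnitudes are configuration defaults chosen for
#' qualitative realism, not data.
#'
#' @return A tibble with columns `gcm`, `rcp`, `period`, `d_mst`, `d_msp`,
#'   `d_pas`.
#' @export
default_scenario_table <- function() {
  warm <- tibble::tribble(
    ~gcm,   ~rcp,  ~d2025, ~d2055, ~d2085, ~wet,
    "Can",  "4.5", 1.4,    2.3,    2.9,    0.033,
    "Can",  "8.5", 1.7,    3.4,    5.0,    0.033,
    "GFDL", "4.5", 1.2,    2.0,    2.5,    0.018,
    "GFDL", "8.5", 1.5,    3.0,    4.3,    0.018,
    "CCSM", "4.5", 0.8,    1.3,    1.6,    0.006,
    "CCSM", "8.5", 1.0,    2.2,    3.4,    0.006
  )
  fut <- warm |>
    tidyr::pivot_longer(cols = c("d2025", "d2055", "d2085"),
                        names_to = "period", values_to = "d_mst") |>
    dplyr::mutate(period = sub("^d", "", .data$period),
                  d_msp = round(1 + .data$wet * .data$d_mst, 3),
                  d_pas = 1) |>
    dplyr::select("gcm", "rcp", "period", "d_mst", "d_msp", "d_pas")
  dplyr::bind_rows(scenario_delta(), fut)
}

#' Validate a scenario table
#'
#' Checks the baseline row carries identity offsets and that `d_mst` is
#' non-decreasing across periods within each GCM x RCP scenario.
#'
#' @param scenarios a tibble as returned by [default_scenario_table()].
#' @return The table, invisibly; errors on violation.
#' @export
validate_scenario_table <- function(scenarios) {
  base <- dplyr::filter(scenarios, .data$period == "baseline")
  if (nrow(base) && !all(base$d_mst == 0 & base$d_msp == 1 & base$d_pas == 1)) {
    stop("baseline scenario offsets must be identity (0, 1, 1)")
  }
  fut <- dplyr::filter(scenarios, .data$period != "baseline") |>
    dplyr::arrange(.data$gcm, .data$rcp, .data$period) |>
    dplyr::group_by(.data$gcm, .data$rcp) |>
    dplyr::summarise(ok = !is.unsorted(.data$d_mst), .groups = "drop")
  if (nrow(fut) && !all(fut$ok)) {
    stop("d_mst must be non-decreasing across periods within each scenario")
  }
  invisible(scenarios)
}

#' Generate climate surfaces for one scenario
#'
#' Baseline surfaces are built from the DEM and the landscape configuration,
#' then the scenario offsets are applied:
#' * `mst` (mean summer temperature, degC): sea-level temperature minus the
#'   lapse term, plus smooth noise, plus `d_mst`;
#' * `msp` (mean summer precipitation, mm): base plus the westward gradient
#'   plus orographic uplift plus noise, times `d_msp`;
#' * `pas` (precipitation as snow, mm): annualized precipitation times a
#'   logistic snow fraction that falls with temperature, times `d_pas`.
#'
#' Noise fields depend only on `config$seed`, so two scenarios on the same
#' landscape differ exactly by their offsets.
#'
#' @param dem raster_grid of elevations from [generate_dem()].
#' @param delta one-row scenario tibble (see [scenario_delta()]).
#' @param config the [landscape_config()] that produced `dem`.
#' @return Named list of raster_grids: `mst`, `msp`, `pas`.
#' @export
generate_climate <- function(dem, delta, config) {
  stopifnot(is_raster_grid(dem), inherits(config, "landscape_config"),
            nrow(delta) == 1)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  withr::local_seed(stage_seed(config$seed, "climate"))
  noise_t <- smooth_noise(nr, nc, config$noise_correlation) *
    config$temp_noise_sd
  noise_p <- smooth_noise(nr, nc, config$noise_correlation) *
    config$precip_noise_sd
  elev <- dem$values
  mst <- config$sea_level_temp - config$lapse_rate * elev / 1000 +
    noise_t + delta$d_mst
  west_km <- matrix(rep((nc - seq_len(nc) + 0.5) * dem$cell_size / 1000,
                        each = nr), nr, nc)
  msp <- pmax(config$precip_base + config$precip_gradient * west_km +
                config$precip_elev_coef * elev + noise_p, 1) * delta$d_msp
  pas <- msp * config$annual_factor *
    plogis(-mst * config$pas_coefficient) * delta$d_pas
  mask <- is.na(elev)
  mst[mask] <- NA; msp[mask] <- NA; pas[mask] <- NA
  list(mst = new_like(dem, mst, "mst"),
       msp = new_like(dem, msp, "msp"),
       pas = new_like(dem, pas, "pas"))
}

#' Surrogate biogeoclimatic zones by elevation banding
#'
#' Labels every valid cell as coastal forest (`CWH`), subalpine (`MH`) or
#' alpine (`CMA`). With only a DEM the bands are elevation contours at
#' `zone_breaks`; when a temperature surface is supplied the same breaks are
#' mapped through the lapse rate and applied in temperature space, so
#' anomalously cold pockets can classify as alpine below the nominal break.
#'
#' @param dem elevation raster.
#' @param mst optional mean-summer-temperature raster aligned to `dem`.
#' @param config a [landscape_config()] supplying `zone_breaks` (and, with
#'   `mst`, the lapse mapping).
#' @return An integer raster_grid with codes 1 = CWH, 2 = MH, 3 = CMA and a
#'   `"levels"` attribute.
#' @export
generate_zones <- function(dem, mst = NULL, config = landscape_config()) {
  stopifnot(is_raster_grid(dem))
  breaks <- config$zone_breaks
  if (is.null(mst)) {
    v <- dem$values
    z <- 1L + (v >= breaks[1]) + (v >= breaks[2])
  } else {
    check_aligned(dem, mst)
    tb <- config$sea_level_temp - config$lapse_rate * breaks / 1000
    v <- mst$values
    z <- 1L + (v <= tb[1]) + (v <= tb[2])
    z[is.na(dem$values)] <- NA
  }
  out <- new_like(dem, z, "zones")
  attr(out, "levels") <- c("CWH", "MH", "CMA")
  out
}

#' Simulate occurrence records from a known suitability truth
#'
#' Draws presence cells with probability proportional to
#' `plogis(truth_coefficients . standardized predictors)`, concentrated in
#' the alpine and subalpine zones, then dresses them up as realistic raw
#' sighting tables: a field-survey set with marked individuals, repeat
#' sightings less than a day apart, juveniles and exact-coordinate flock
#' duplicates; and a public set with mixed coordinate accuracy. Some records
#' in both sets fall outside June-October. Every downstream filtering rule
#' therefore has work to do.
#'
#' @param stack named list of predictor rasters; must include `elevation`,
#'   `mst`, `pas` and `aspect_t`.
#' @param zones zone raster from [generate_zones()].
#' @param config a [landscape_config()] (supplies `truth_coefficients` and
#'   the seed).
#' @param n_field,n_public raw (pre-filter) record counts for the two
#'   sources.
#' @return A tibble of occurrence records with columns `id`, `source`,
#'   `date`, `x`, `y`, `individual_id`, `life_stage`, `accuracy_m`.
#' @export
simulate_occurrences <- function(stack, zones, config,
                                 n_field = 207, n_public = 137) {
  stopifnot(inherits(config, "landscape_config"),
            all(c("elevation", "mst", "pas", "aspect_t") %in% names(stack)))
  check_aligned(stack$elevation, zones)
  withr::local_seed(stage_seed(config$seed, "occurrences"))

  cells <- cell_centers(stack$elevation) |>
    dplyr::mutate(
      elevation = as.vector(stack$elevation$values),
      mst = as.vector(stack$mst$values),
      pas = as.vector(stack$pas$values),
      aspect_t = as.vector(stack$aspect_t$values),
      zone = as.vector(zones$values)
    ) |>
    dplyr::filter(!is.na(.data$elevation), !is.na(.data$mst),
                  !is.na(.data$pas), !is.na(.data$aspect_t))
  if (nrow(cells) == 0) stop("no eligible cells to place occurrences in")

  co <- config$truth_coefficients
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  lp <- (config$truth_intercept %||% 0) +
    co[["elevation"]] * std(cells$elevation) +
    co[["mst"]] * std(cells$mst) +
    co[["pas"]] * std(cells$pas) +
    co[["aspect_t"]] * std(cells$aspect_t)
  w <- plogis(lp) * ifelse(cells$zone >= 2L, 1, 0.02)
  if (sum(w) <= 0) stop("no eligible cells to place occurrences in")

  season_date <- function(n, p_summer) {
    inside <- runif(n) < p_summer
    month <- ifelse(inside, sample(6:10, n, replace = TRUE),
                    sample(c(1:5, 11:12), n, replace = TRUE))
    day <- sample(1:28, n, replace = TRUE)
    as.POSIXct(sprintf("2013-%02d-%02d 00:00:00", month, day), tz = "UTC") +
      runif(n, 0, 86400)
  }

  # Field survey: marked individuals with home cells and repeat sightings.
  n_ind <- max(1L, ceiling(n_field / 4))
  home <- sample(nrow(cells), n_ind, replace = TRUE, prob = w)
  ind_of <- sort(sample(seq_len(n_ind), n_field, replace = TRUE))
  jit_x <- runif(n_ind, -30, 30); jit_y <- runif(n_ind, -30, 30)
  f_dates <- season_date(n_field, 0.85)
  # force some same-individual sightings < 1 day apart
  ord <- order(ind_of, f_dates)
  ind_of <- ind_of[ord]; f_dates <- f_dates[ord]
  rep_pos <- which(duplicated(ind_of))
  close <- rep_pos[runif(length(rep_pos)) < 0.4]
  f_dates[close] <- f_dates[close - 1L] + runif(length(close), 3600, 82800)
  field <- tibble::tibble(
    id = sprintf("F%04d", seq_len(n_field)),
    source = "field",
    date = f_dates,
    x = cells$x[home[ind_of]] + jit_x[ind_of],
    y = cells$y[home[ind_of]] + jit_y[ind_of],
    individual_id = sprintf("ind%03d", ind_of),
    life_stage = sample(c("adult", "juvenile", "unknown"), n_field,
                        replace = TRUE, prob = c(0.75, 0.15, 0.10)),
    accuracy_m = 10
  )

  # Public submissions: unmarked birds, variable coordinate accuracy,
  # coordinates snapped to cell centres so flock duplicates occur.
  p_cell <- sample(nrow(cells), n_public, replace = TRUE, prob = w)
  public <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n_public)),
    source = "public",
    date = season_date(n_public, 0.9),
    x = cells$x[p_cell],
    y = cells$y[p_cell],
    individual_id = NA_character_,
    life_stage = "unknown",
    accuracy_m = sample(c(10, 50, 100, 250, 1000), n_public,
                        replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
  )
  dplyr::bind_rows(field, public)
}

#' Write / read occurrence records as CSV
#'
#' Schema: `id,source,date,x,y,individual_id,life_stage,accuracy_m`, dates
#' in ISO 8601.
#'
#' @param records occurrence tibble.
#' @param path file path.
#' @export
write_occurrences <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), source = readr::col_character(),
    date = readr::col_datetime(), x = readr::col_double(),
    y = readr::col_double(), individual_id = readr::col_character(),
    life_stage = readr::col_character(), accuracy_m = readr::col_double()
  ))
}
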