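#' Run the full habitat-modelling pipeline
#'
#' Sequences every stage on one synthetic landscape: terrain derivatives
#' from a generated DEM, occurrence simulation and filtering, constrained
#' pseudo-absence sampling, ensemble fitting with sensitivity-constrained
#' thresholding, projection across the scenario factorial, and patch-based
#' configuration metrics. Per-stage seeds are derived deterministically from
#' the master seed in `config`, so the same configuration reproduces
#' identical maps.
#'
#' @param config a [landscape_config()].
#' @param scenarios scenario-offset table (default
#'   [default_scenario_table()]).
#' @param n_field,n_public raw occurrence counts passed to
#'   [simulate_occurrences()].
#' @param n_trees trees in the ensemble (default 1500).
#' @param required_sensitivity threshold constraint (default 0.90).
#' @param ratio pseudo-absences per presence (default 2).
#' @param buffer_m outward buffer around the presence hull, metres.
#' @param exclusion_m presence exclusion radius, metres.
#' @param zones_allowed background zones (default alpine + subalpine).
#' @param connectivity patch adjacency for the metrics (default 8).
#' @param out_dir optional directory; when given, rasters (ESRI ASCII),
#'   occurrence/point CSVs and a JSON manifest are written there.
#' @return A `habitat_run` with the fitted model, threshold, maps, metrics
#'   and summary.
#' @export
run_pipeline <- function(config = landscape_config(),
                         scenarios = default_scenario_table(),
                         n_field = 530, n_public = 340,
                         n_trees = 1500, required_sensitivity = 0.90,
                         ratio = 2, buffer_m = 200, exclusion_m = 200,
                         zones_allowed = c("CMA", "MH"),
                         connectivity = 8, out_dir = NULL) {
  validate_scenario_table(scenarios)
  t0 <- Sys.time()

  dem <- generate_dem(config)
  terr <- terrain_layers(dem)
  base_delta <- dplyr::filter(scenarios, .data$period == "baseline")
  if (nrow(base_delta) != 1) stop("scenario table needs one baseline row")
  clim <- generate_climate(dem, base_delta, config)
  baseline_stack <- build_predictor_stack(dem, clim, terrain = terr)
  attr(baseline_stack, "scenario") <-
    list(gcm = "none", rcp = "none", period = "baseline")
  zones <- generate_zones(dem, config = config)

  raw <- simulate_occurrences(baseline_stack, zones, config,
                              n_field = n_field, n_public = n_public)
  field <- raw |>
    dplyr::filter(.data$source == "field") |>
    filter_summer() |>
    filter_field_records(seed = stage_seed(config$seed, "thin")) |>
    thin_to_grid(dem, seed = stage_seed(config$seed, "thin"))
  public <- raw |>
    dplyr::filter(.data$source == "public") |>
    filter_summer() |>
    filter_public_records() |>
    thin_to_grid(dem, seed = stage_seed(config$seed, "thin"))
  presences <- merge_datasets(field, public, dem,
                              seed = stage_seed(config$seed, "merge"))

  mask <- build_background(presences, zones, dem, buffer_m = buffer_m,
                           zones_allowed = zones_allowed) |>
    exclude_presence_buffer(presences, radius_m = exclusion_m)
  absences <- sample_pseudo_absences(
    mask, nrow(presences), ratio = ratio,
    seed = stage_seed(config$seed, "background"))

  training <- build_training_table(baseline_stack, presences, absences)
  model <- fit_sdm(training, n_trees = n_trees,
                   seed = stage_seed(config$seed, "model"))
  thr <- select_threshold(model,
                          required_sensitivity = required_sensitivity)

  stacks <- purrr::pmap(scenarios, function(gcm, rcp, period, ...) {
    if (period == "baseline") return(baseline_stack)
    delta <- tibble::tibble(gcm = gcm, rcp = rcp, period = period, ...)
    cl <- generate_climate(dem, delta, config)
    st <- build_predictor_stack(dem, cl, terrain = terr)
    attr(st, "scenario") <- list(gcm = gcm, rcp = rcp, period = period)
    st
  })
  maps <- run_scenario_grid(model, thr, stacks)
  metrics <- scenario_metrics(maps, dem, connectivity = connectivity)
  summary <- scenario_summary(metrics)

  run <- structure(list(
    config = config, scenarios = scenarios,
    dem = dem, zones = zones, terrain = terr,
    presences = presences, pseudo_absences = absences,
    filter_report = filter_report(presences),
    background = mask, training = training,
    model = model, threshold = thr,
    maps = maps, metrics = metrics, summary = summary,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "habitat_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.habitat_run <- function(x, ...) {
  cat(sprintf(
    "<habitat_run> %dx%d landscape (seed %d): %d presences, %d pseudo-absences\n",
    x$config$grid_rows, x$config$grid_cols, x$config$seed,
    nrow(x$presences), nrow(x$pseudo_absences)))
  print(x$threshold)
  cat(sprintf("  %d scenario maps; baseline habitat %.2f km^2\n",
              nrow(x$maps$meta), habitat_area(x$maps$binary[["baseline"]])))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Rasters go out as ESRI ASCII grids, point sets as CSV, and a JSON
#' manifest records the configuration, filter report, threshold metrics and
#' file list.
#'
#' @param run a `habitat_run`.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "habitat_run"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("writing a run requires the jsonlite package")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wgrid <- function(g, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_ascii_grid(g, p)
    files[[name]] <<- p
  }
  wgrid(run$dem, "elevation")
  wgrid(run$zones, "zones")
  for (nm in names(run$terrain)) wgrid(run$terrain[[nm]], nm)
  for (lb in names(run$maps$binary)) {
    wgrid(run$maps$probability[[lb]], paste0(lb, "_prob"))
    wgrid(run$maps$binary[[lb]], paste0(lb, "_bin"))
  }
  readr::write_csv(run$presences, file.path(out_dir, "presences.csv"))
  readr::write_csv(run$pseudo_absences,
                   file.path(out_dir, "pseudo_absences.csv"))
  readr::write_csv(run$metrics, file.path(out_dir, "scenario_metrics.csv"))
  readr::write_csv(run$summary, file.path(out_dir, "scenario_summary.csv"))
  manifest <- list(
    seed = run$config$seed,
    grid = c(run$config$grid_rows, run$config$grid_cols),
    n_presences = nrow(run$presences),
    n_pseudo_absences = nrow(run$pseudo_absences),
    threshold = glance(run$threshold),
    filter_report = run$filter_report,
    elapsed_s = run$elapsed_s,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
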