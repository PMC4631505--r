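new_filter_report <- function(records, rule, removed) {
  prev <- attr(records, "filter_report")
  rep_row <- tibble::tibble(rule = rule, removed = as.integer(removed))
  dplyr::bind_rows(prev, rep_row)
}

#' Filtering report of an occurrence tibble
#'
#' Each filtering step appends a row (rule, records removed) to a report
#' carried on the tibble; this accessor returns it.
#'
#' @param records occurrence tibble that has passed through one or more
#'   filters.
#' @return A tibble with columns `rule` and `removed` (possibly empty).
#' @export
filter_report <- function(records) {
  attr(records, "filter_report") %||%
    tibble::tibble(rule = character(), removed = integer())
}

set_report <- function(records, report) {
  attr(records, "filter_report") <- report
  records
}

#' Keep summer observations
#'
#' Retains records dated June through October. Undated records cannot be
#' classified and are dropped with a warning.
#'
#' @param records occurrence tibble with a `date` column.
#' @param months integer months defining the season (default `6:10`).
#' @return Filtered tibble; see [filter_report()].
#' @export
filter_summer <- function(records, months = 6:10) {
  n0 <- nrow(records)
  undated <- is.na(records$date)
  if (any(undated)) {
    warning(sum(undated), " undated record(s) dropped")
  }
  keep <- !undated &
    as.integer(format(records$date, "%m")) %in% months
  out <- records[keep, , drop = FALSE]
  rep <- new_filter_report(records, "summer_window", n0 - nrow(out))
  set_report(out, rep)
}

#' Filter field-survey records
#'
#' Applies the field-survey cleaning cascade in order:
#' 1. drop juveniles (they sit at or near a parent's coordinate);
#' 2. drop exact-coordinate duplicates, keeping one record per point (a
#'    flock at one GPS point counts once);
#' 3. per marked individual, sweep chronologically and drop any record less
#'    than one day after the last kept record;
#' 4. per marked individual, keep at most two of the remaining records,
#'    chosen uniformly at random.
#' Records without an individual id skip the per-individual steps.
#'
#' @param records field-source occurrence tibble.
#' @param seed integer seed for the random per-individual selection.
#' @param max_per_individual cap on records per individual (default 2).
#' @return Filtered tibble with an updated [filter_report()].
#' @export
filter_field_records <- function(records, seed = 1L,
                                 max_per_individual = 2L) {
  rep <- attr(records, "filter_report")
  out <- records

  n0 <- nrow(out)
  out <- out[is.na(out$life_stage) | out$life_stage != "juvenile", ,
             drop = FALSE]
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "drop_juveniles", removed = n0 - nrow(out)))

  n0 <- nrow(out)
  out <- out[!duplicated(paste(out$x, out$y)), , drop = FALSE]
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "coordinate_duplicates", removed = n0 - nrow(out)))

  n0 <- nrow(out)
  marked <- !is.na(out$individual_id)
  swept <- out[marked, , drop = FALSE] |>
    dplyr::arrange(.data$individual_id, .data$date) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(sweep_keep(.data$date)) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(out[!marked, , drop = FALSE], swept)
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "within_day_repeats", removed = n0 - nrow(out)))

  n0 <- nrow(out)
  marked <- !is.na(out$individual_id)
  withr::local_seed(seed)
  capped <- out[marked, , drop = FALSE] |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::slice_sample(n = max_per_individual) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(out[!marked, , drop = FALSE], capped)
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "per_individual_cap", removed = n0 - nrow(out)))

  set_report(out, rep)
}

# Greedy chronological sweep: keep a record only if it is at least one day
# after the last kept record of the same individual.
sweep_keep <- function(dates) {
  keep <- logical(length(dates))
  last <- NULL
  for (i in seq_along(dates)) {
    if (is.null(last) ||
        as.numeric(difftime(dates[i], last, units = "days")) >= 1) {
      keep[i] <- TRUE
      last <- dates[i]
    }
  }
  keep
}

#' Filter public-submission records
#'
#' Keeps records whose stated coordinate accuracy is within
#' `max_accuracy_m` metres (boundary inclusive), then drops
#' exact-coordinate duplicates.
#'
#' @param records public-source occurrence tibble.
#' @param max_accuracy_m accuracy cutoff, metres (default 100).
#' @return Filtered tibble with an updated [filter_report()].
#' @export
filter_public_records <- function(records, max_accuracy_m = 100) {
  rep <- attr(records, "filter_report")
  n0 <- nrow(records)
  out <- records[!is.na(records$accuracy_m) &
                   records$accuracy_m <= max_accuracy_m, , drop = FALSE]
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "coarse_coordinates", removed = n0 - nrow(out)))
  n0 <- nrow(out)
  out <- out[!duplicated(paste(out$x, out$y)), , drop = FALSE]
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "coordinate_duplicates", removed = n0 - nrow(out)))
  set_report(out, rep)
}

#' Thin records to one per grid cell
#'
#' Randomly keeps exactly one record within each occupied cell of the
#' predictor grid. Records outside the grid extent are dropped with a
#' warning.
#'
#' @param records occurrence tibble.
#' @param grid a raster_grid defining the cells.
#' @param seed integer seed for the per-cell random choice.
#' @return Thinned tibble with an updated [filter_report()].
#' @export
thin_to_grid <- function(records, grid, seed = 1L) {
  rep <- attr(records, "filter_report")
  cells <- cell_of_xy(grid, records$x, records$y)
  if (any(!cells$inside)) {
    warning(sum(!cells$inside), " record(s) outside the grid extent dropped")
  }
  n0 <- nrow(records)
  out <- records[cells$inside, , drop = FALSE]
  if (nrow(out) > 0) {
    key <- paste(cells$row[cells$inside], cells$col[cells$inside])
    withr::local_seed(seed)
    pick <- unsplit(lapply(split(seq_along(key), key), function(ix) {
      sel <- if (length(ix) == 1L) ix else sample(ix, 1L)
      seq_along(ix) == match(sel, ix)
    }), key)
    out <- out[pick, , drop = FALSE]
  }
  rep <- dplyr::bind_rows(rep, tibble::tibble(
    rule = "grid_thinning", removed = n0 - nrow(out)))
  set_report(out, rep)
}

#' Merge two grid-thinned occurrence datasets
#'
#' Takes the union of the (already thinned) field and public records and,
#' where both datasets occupy the same grid cell, randomly keeps a single
#' record from that cell.
#'
#' @param field,public grid-thinned occurrence tibbles.
#' @param grid a raster_grid defining the cells.
#' @param seed integer seed.
#' @return Combined tibble, at most one record per cell.
#' @export
merge_datasets <- function(field, public, grid, seed = 1L) {
  combined <- dplyr::bind_rows(field, public)
  out <- thin_to_grid(set_report(combined, NULL), grid, seed = seed)
  rep <- dplyr::bind_rows(
    dplyr::bind_rows(filter_report(field), filter_report(public)) |>
      dplyr::group_by(.data$rule) |>
      dplyr::summarise(removed = sum(.data$removed), .groups = "drop"),
    tibble::tibble(rule = "merge_shared_cells",
                   removed = nrow(combined) - nrow(out)))
  set_report(out, rep)
}
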