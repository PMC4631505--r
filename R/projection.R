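#' Scenario label helper
#'
#' @param gcm,rcp,period scenario fields.
#' @return Label string, `"baseline"` for the baseline period.
#' @export
scenario_label <- function(gcm, rcp, period) {
  ifelse(period == "baseline", "baseline",
         paste(gcm, rcp, period, sep = "_"))
}

#' Predict habitat suitability over a raster stack
#'
#' Applies the fitted ensemble to every valid cell of the predictor stack;
#' the suitability value is the fraction of trees voting presence. Nodata
#' propagates.
#'
#' @param model an `sdm_fit`.
#' @param stack a `predictor_stack` whose layer names cover the training
#'   predictors.
#' @return A raster_grid of suitability in `[0, 1]` carrying the stack's
#'   scenario label.
#' @export
predict_stack <- function(model, stack) {
  stopifnot(inherits(model, "sdm_fit"))
  missing <- setdiff(model$predictors, names(stack))
  if (length(missing)) {
    stop("stack is missing predictor layer(s): ",
         paste(missing, collapse = ", "))
  }
  ref <- stack[[1]]
  vals <- lapply(model$predictors, function(nm) as.vector(stack[[nm]]$values))
  df <- as.data.frame(setNames(vals, model$predictors))
  ok <- stats::complete.cases(df)
  prob <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    prob[ok] <- predict(model$forest, newdata = df[ok, , drop = FALSE],
                        type = "prob")[, "1"]
  }
  out <- new_like(ref, matrix(prob, nrow(ref$values)), "suitability")
  attr(out, "scenario") <- attr(stack, "scenario")
  out
}

#' Binarize a suitability map
#'
#' Cells with suitability at or above the threshold are suitable (the
#' boundary is inclusive, consistent with a deliberately over-predicting,
#' omission-averse threshold).
#'
#' @param suitability suitability raster from [predict_stack()].
#' @param threshold cutoff in `[0, 1]`, or a `threshold_result`.
#' @return A 0/1 raster_grid (NA preserved) with `threshold` and scenario
#'   attributes.
#' @export
binarize <- function(suitability, threshold) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  stopifnot(is_raster_grid(suitability), threshold >= 0, threshold <= 1)
  v <- suitability$values
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  out <- new_like(suitability, b, "habitat")
  attr(out, "scenario") <- attr(suitability, "scenario")
  attr(out, "threshold") <- threshold
  out
}

#' Project the model across the full scenario factorial
#'
#' Predicts and binarizes one baseline map plus one map per
#' GCM x RCP x period combination. The stack list must contain the complete
#' factorial (missing combinations are reported by name). Optionally adds
#' GCM-ensemble maps per RCP x period: the mean of the GCM suitability
#' rasters, thresholded like any other map.
#'
#' @param model an `sdm_fit`.
#' @param threshold cutoff or `threshold_result`.
#' @param stacks named list of `predictor_stack`s; each must carry a
#'   `scenario` attribute, a list with `gcm`, `rcp`, `period` (the baseline
#'   stack uses `period = "baseline"`).
#' @param gcm_mean also compute GCM-averaged maps (default `TRUE`).
#' @return A `scenario_maps` object: suitability and binary rasters keyed by
#'   scenario label, a `meta` tibble, and the threshold.
#' @export
run_scenario_grid <- function(model, threshold, stacks, gcm_mean = TRUE) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  meta <- purrr::map_dfr(stacks, function(s) {
    sc <- attr(s, "scenario")
    if (is.null(sc) || !is.list(sc)) {
      stop("every stack needs a scenario attribute (gcm, rcp, period)")
    }
    tibble::tibble(gcm = sc$gcm, rcp = sc$rcp, period = sc$period)
  })
  meta$label <- scenario_label(meta$gcm, meta$rcp, meta$period)
  if (sum(meta$period == "baseline") != 1) {
    stop("exactly one baseline stack is required")
  }
  fut <- meta[meta$period != "baseline", ]
  want <- tidyr::expand_grid(gcm = unique(fut$gcm), rcp = unique(fut$rcp),
                             period = unique(fut$period))
  have <- paste(fut$gcm, fut$rcp, fut$period)
  miss <- want[!paste(want$gcm, want$rcp, want$period) %in% have, ]
  if (nrow(miss)) {
    stop("scenario factorial incomplete; missing: ",
         paste(scenario_label(miss$gcm, miss$rcp, miss$period),
               collapse = ", "))
  }
  names(stacks) <- meta$label
  prob <- purrr::map(stacks, function(s) predict_stack(model, s))
  bin <- purrr::map(prob, function(p) binarize(p, threshold))
  ens <- NULL
  if (gcm_mean && nrow(fut)) {
    combos <- unique(fut[, c("rcp", "period")])
    ens <- purrr::pmap(combos, function(rcp, period) {
      members <- meta$label[meta$rcp == rcp & meta$period == period &
                              meta$period != "baseline"]
      vals <- Reduce(`+`, lapply(prob[members],
                                 function(p) p$values)) / length(members)
      avg <- new_like(prob[[members[1]]], vals, "suitability")
      attr(avg, "scenario") <- list(gcm = "mean", rcp = rcp, period = period)
      binarize(avg, threshold)
    })
    names(ens) <- paste("mean", combos$rcp, combos$period, sep = "_")
  }
  structure(list(probability = prob, binary = bin, gcm_mean = ens,
                 meta = meta, threshold = threshold),
            class = "scenario_maps")
}

#' @export
print.scenario_maps <- function(x, ...) {
  cat(sprintf(
    "<scenario_maps> %d maps (1 baseline + %d future) at threshold %.3f\n",
    nrow(x$meta), sum(x$meta$period != "baseline"), x$threshold))
  invisible(x)
}

#' GCM agreement map
#'
#' For one RCP x period, counts per cell how many GCMs predict suitable
#' habitat (0 to the number of GCMs).
#'
#' @param maps a `scenario_maps` object.
#' @param rcp,period scenario cell to summarise.
#' @return An integer raster_grid of agreement counts.
#' @export
gcm_agreement <- function(maps, rcp, period) {
  stopifnot(inherits(maps, "scenario_maps"))
  members <- maps$meta$label[maps$meta$rcp == rcp &
                               maps$meta$period == period]
  if (!length(members)) stop("no maps for rcp ", rcp, " period ", period)
  vals <- Reduce(`+`, lapply(maps$binary[members], function(b) b$values))
  out <- new_like(maps$binary[[members[1]]], vals, "gcm_agreement")
  attr(out, "scenario") <- list(gcm = "agreement", rcp = rcp,
                                period = period)
  out
}
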