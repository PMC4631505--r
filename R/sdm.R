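#' Build the presence/pseudo-absence training table
#'
#' Extracts the eight predictor values at the grid cell containing each
#' point. Points falling on cells where any predictor is undefined are
#' dropped with a warning (the model cannot use them).
#'
#' @param stack a `predictor_stack`.
#' @param presences tibble with `x`, `y` (label 1).
#' @param absences tibble with `x`, `y` (label 0).
#' @return A tibble with the 8 predictor columns and a `label` column.
#' @export
build_training_table <- function(stack, presences, absences) {
  stopifnot(inherits(stack, "predictor_stack"))
  pts <- dplyr::bind_rows(
    tibble::tibble(x = presences$x, y = presences$y, label = 1L),
    tibble::tibble(x = absences$x, y = absences$y, label = 0L)
  )
  cells <- cell_of_xy(stack[[1]], pts$x, pts$y)
  if (any(!cells$inside)) stop("points outside the grid extent")
  nr <- nrow(stack[[1]]$values)
  lin <- (cells$col - 1L) * nr + cells$row
  for (nm in names(stack)) pts[[nm]] <- as.vector(stack[[nm]]$values)[lin]
  bad <- !stats::complete.cases(pts[names(stack)])
  if (any(bad)) {
    warning(sum(bad), " point(s) on cells with undefined predictors dropped")
    pts <- pts[!bad, , drop = FALSE]
  }
  dplyr::select(pts, dplyr::all_of(names(stack)), "label")
}

#' Fit the bootstrap-aggregated tree ensemble
#'
#' A classification random forest on the presence/pseudo-absence table:
#' `n_trees` trees, each grown on a bootstrap sample, with
#' `floor(sqrt(p))` predictors tried at each split. Out-of-bag (OOB)
#' probabilities — for each row, the vote fraction among trees whose
#' bootstrap excluded that row — and both permutation-accuracy and
#' impurity importances are retained.
#'
#' @param table training tibble from [build_training_table()] (predictor
#'   columns plus 0/1 `label`).
#' @param n_trees number of trees (default 1500).
#' @param seed integer seed; fits are deterministic per seed.
#' @return An `sdm_fit` object.
#' @export
fit_sdm <- function(table, n_trees = 1500, seed = 1L) {
  stopifnot("label" %in% names(table))
  labels <- as.integer(table$label)
  if (length(unique(labels)) < 2) {
    stop("training table must contain both classes")
  }
  preds <- setdiff(names(table), "label")
  if (anyNA(table[preds])) stop("training table has missing predictor values")
  x <- as.data.frame(table[preds])
  withr::local_seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = factor(labels, levels = c(0L, 1L)),
    ntree = n_trees, mtry = floor(sqrt(length(preds))),
    importance = TRUE
  )
  structure(list(
    forest = forest,
    predictors = preds,
    labels = labels,
    oob_prob = unname(forest$votes[, "1"]),
    n_trees = n_trees,
    mtry = floor(sqrt(length(preds))),
    seed = as.integer(seed)
  ), class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf(
    "<sdm_fit> %d trees, mtry %d, %d rows (%d presence / %d background)\n",
    x$n_trees, x$mtry, length(x$labels), sum(x$labels == 1),
    sum(x$labels == 0)))
  invisible(x)
}

#' @describeIn fit_sdm variable importances as a tibble, one row per
#'   predictor, sorted by mean decrease in accuracy.
#' @param x an `sdm_fit`.
#' @param ... unused.
#' @method tidy sdm_fit
#' @export
tidy.sdm_fit <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(
    predictor = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy))
}

#' @describeIn fit_sdm one-row model summary (OOB accuracy and AUC).
#' @method glance sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  oob_class <- as.integer(x$oob_prob >= 0.5)
  tibble::tibble(
    n = length(x$labels),
    n_trees = x$n_trees,
    mtry = x$mtry,
    oob_accuracy = mean(oob_class == x$labels),
    oob_auc = auc_rank(x$oob_prob, x$labels)
  )
}

#' Rank-based AUC
#'
#' Threshold-free area under the ROC curve via the Mann-Whitney statistic;
#' invariant under strictly monotone transforms of the scores.
#'
#' @param probs numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix accuracy metrics
#'
#' Sensitivity (presences correctly classified), specificity
#' (pseudo-absences correctly classified), Cohen's kappa with chance
#' agreement from the marginals, and the true skill statistic
#' `TSS = sensitivity + specificity - 1`.
#'
#' @param predicted 0/1 predictions.
#' @param labels 0/1 observed labels.
#' @return One-row tibble with `sensitivity`, `specificity`, `kappa`, `tss`.
#' @export
evaluate_metrics <- function(predicted, labels) {
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  stopifnot(length(predicted) == length(labels))
  if (length(labels) == 0) stop("empty input")
  tp <- sum(predicted == 1 & labels == 1)
  fn <- sum(predicted == 0 & labels == 1)
  tn <- sum(predicted == 0 & labels == 0)
  fp <- sum(predicted == 1 & labels == 0)
  n <- length(labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  tibble::tibble(sensitivity = sens, specificity = spec, kappa = kappa,
                 tss = sens + spec - 1)
}

#' Sensitivity-constrained threshold selection
#'
#' Scans every candidate cutoff (the unique score values plus 0 and 1) and
#' selects the largest cutoff whose sensitivity is still at least
#' `required_sensitivity`: the most conservative binarization that keeps the
#' required fraction of presences correctly classified. Suitability at or
#' above the cutoff counts as presence. All confusion metrics are evaluated
#' at that cutoff; AUC is threshold-free.
#'
#' @param oob_probs numeric scores, usually OOB probabilities from
#'   [fit_sdm()], or an `sdm_fit` object.
#' @param labels 0/1 labels (ignored when `oob_probs` is an `sdm_fit`).
#' @param required_sensitivity minimum sensitivity (default 0.90).
#' @return A `threshold_result` with fields `threshold`, `sensitivity`,
#'   `specificity`, `kappa`, `tss`, `auc`.
#' @export
select_threshold <- function(oob_probs, labels = NULL,
                             required_sensitivity = 0.90) {
  if (inherits(oob_probs, "sdm_fit")) {
    labels <- oob_probs$labels
    oob_probs <- oob_probs$oob_prob
  }
  labels <- as.integer(labels)
  if (!all(c(0L, 1L) %in% labels)) stop("both classes required")
  if (required_sensitivity > 1) {
    stop("required sensitivity above 1 is unattainable")
  }
  p1 <- oob_probs[labels == 1]
  cand <- sort(unique(c(0, oob_probs, 1)))
  sens <- vapply(cand, function(t) mean(p1 >= t), numeric(1))
  ok <- which(sens >= required_sensitivity)
  thr <- cand[max(ok)]
  m <- evaluate_metrics(as.integer(oob_probs >= thr), labels)
  structure(list(threshold = thr,
                 sensitivity = m$sensitivity,
                 specificity = m$specificity,
                 kappa = m$kappa, tss = m$tss,
                 auc = auc_rank(oob_probs, labels),
                 required_sensitivity = required_sensitivity),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> cutoff %.3f (sensitivity >= %.2f)\n",
    x$threshold, x$required_sensitivity))
  cat(sprintf(
    "  sensitivity %.3f | specificity %.3f | kappa %.3f | TSS %.3f | AUC %.3f\n",
    x$sensitivity, x$specificity, x$kappa, x$tss, x$auc))
  invisible(x)
}

#' @describeIn select_threshold metrics as a one-row tibble.
#' @param x a `threshold_result`.
#' @param ... unused.
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, sensitivity = x$sensitivity,
                 specificity = x$specificity, kappa = x$kappa,
                 tss = x$tss, auc = x$auc)
}

#' @describeIn select_threshold alias of `glance()` for pipe-friendly use.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) glance.threshold_result(x, ...)
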