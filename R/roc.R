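#' Cutoff selection criterion with asymmetric misclassification cost
#'
#' Automated tissue classification must be biased against calling nodal
#' tissue AWM: cutting through conduction tissue mistaken for working
#' myocardium is the costly error. The default criterion therefore weighs
#' a false positive (nodal classified as AWM) twice as heavily as a false
#' negative, and selects the threshold minimizing the cost-weighted
#' distance to the perfect-classification corner of the ROC plot,
#' `sqrt(fn_cost * (1 - tpr)^2 + fp_cost * fpr^2)`. The alternative
#' `"product"` rule maximizes `sensitivity * specificity`, which trades the
#' two error types symmetrically and ignores the costs.
#'
#' @param rule `"weighted_corner_distance"` (default) or `"product"`.
#' @param fp_cost,fn_cost positive relative costs of false positives and
#'   false negatives; defaults 2 and 1.
#' @return A list of class `cutoff_criterion`.
#' @export
cutoff_criterion <- function(rule = c("weighted_corner_distance", "product"),
                             fp_cost = 2, fn_cost = 1) {
  rule <- match.arg(rule)
  if (!is.numeric(fp_cost) || fp_cost <= 0 ||
      !is.numeric(fn_cost) || fn_cost <= 0)
    stop("misclassification costs must be positive")
  structure(list(rule = rule, fp_cost = fp_cost, fn_cost = fn_cost),
            class = "cutoff_criterion")
}

# normalize (scores, labels) input: either two vectors or a score_set()
# data frame with columns i15 and label
scored_input <- function(scores, labels) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("i15", "label") %in% names(scores)))
    labels <- scores$label
    scores <- scores$i15
  }
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  if (!all(labels %in% c("AWM", "NODAL")))
    stop("labels must be 'AWM' or 'NODAL'")
  if (anyNA(scores)) stop("scores contain NA")
  list(scores = as.numeric(scores), labels = as.character(labels))
}

#' Build a ROC curve from scored labeled images
#'
#' Sweeps the decision threshold over the observed score range under the
#' convention that `score >= threshold` predicts AWM (the positive class
#' sits at the higher I15 mode). Candidate thresholds are the midpoints
#' between consecutive distinct sorted scores plus one sentinel above the
#' maximum and one below the minimum, so every achievable
#' (sensitivity, specificity) operating point appears exactly once and no
#' score ever equals a threshold. Rates are exact counts, no smoothing.
#'
#' @param scores numeric I15 scores, or a [score_set()] data frame (in
#'   which case `labels` is ignored).
#' @param labels character labels `"AWM"` / `"NODAL"` parallel to `scores`.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `tpr`, `fpr` (non-decreasing), and the class counts
#'   `n_pos`, `n_neg`.
#' @examples
#' rc <- build_roc(c(0.9, 0.8, 0.3, 0.2), c("AWM", "AWM", "NODAL", "NODAL"))
#' auc(rc)
#' @export
build_roc <- function(scores, labels = NULL) {
  inp <- scored_input(scores, labels)
  pos <- inp$scores[inp$labels == "AWM"]
  neg <- inp$scores[inp$labels == "NODAL"]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("ROC curve requires at least one score from each class")
  s <- sort(unique(inp$scores))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  thr <- c(max(s) + 1, rev(mids), min(s) - 1)   # decreasing
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds over %d AWM / %d NODAL scores, AUC %.4f\n",
              length(x$thresholds), x$n_pos, x$n_neg, auc(x)))
  invisible(x)
}

#' Area under a ROC curve
#'
#' Trapezoidal area over the false-positive rate. With the exact
#' threshold-sweep construction of [build_roc()] this equals the
#' Mann-Whitney U statistic normalized by `n_pos * n_neg`, ties counted
#' one half.
#'
#' @param curve a `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  n <- length(curve$fpr)
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-n]) / 2)
}

#' Cost-weighted optimal decision cutoff
#'
#' Selects the threshold optimizing the criterion over all candidate
#' thresholds of the curve: for `"weighted_corner_distance"` the minimum of
#' `sqrt(fn_cost * (1 - tpr)^2 + fp_cost * fpr^2)`, for `"product"` the
#' maximum of `tpr * (1 - fpr)`. Ties (objectives equal to within 1e-12)
#' are broken toward the larger threshold: a higher cutoff predicts fewer
#' positives and therefore never more false positives, matching the bias
#' toward avoiding nodal-as-AWM misclassifications.
#'
#' @param curve a `roc_curve` from [build_roc()].
#' @param criterion a [cutoff_criterion()].
#' @return An object of class `i15_cutoff`: list with `threshold`,
#'   `sensitivity` and `specificity` at the cutoff (proportions in
#'   `[0, 1]`), the criterion fields, and the objective value.
#' @export
optimal_cutoff <- function(curve, criterion = cutoff_criterion()) {
  stopifnot(inherits(curve, "roc_curve"), inherits(criterion, "cutoff_criterion"))
  obj <- switch(criterion$rule,
    weighted_corner_distance =
      sqrt(criterion$fn_cost * (1 - curve$tpr)^2 +
           criterion$fp_cost * curve$fpr^2),
    product = -(curve$tpr * (1 - curve$fpr)))
  best <- min(obj)
  # thresholds are stored in decreasing order: the first index among the
  # tied optima is the largest threshold
  i <- which(obj <= best + 1e-12)[1]
  structure(list(threshold = curve$thresholds[i],
                 sensitivity = curve$tpr[i],
                 specificity = 1 - curve$fpr[i],
                 rule = criterion$rule,
                 fp_cost = criterion$fp_cost,
                 fn_cost = criterion$fn_cost,
                 objective = abs(best)),
            class = "i15_cutoff")
}

#' @export
print.i15_cutoff <- function(x, ...) {
  cat(sprintf("<i15_cutoff> threshold %.4f (%s, fp_cost %g, fn_cost %g)\n",
              x$threshold, x$rule, x$fp_cost, x$fn_cost))
  cat(sprintf("  at cutoff: sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
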