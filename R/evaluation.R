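#' Labeled continuous scores for ROC analysis
#'
#' @param id character identifiers.
#' @param score numeric continuous predictions.
#' @param label `"positive"` / `"negative"` per item.
#' @return data frame of class `labeled_scores`.
#' @export
labeled_scores <- function(id, score, label) {
  stopifnot(length(id) == length(score), length(id) == length(label))
  label <- as.character(label)
  if (!all(label %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  structure(data.frame(id = as.character(id), score = as.numeric(score),
                       label = label, stringsAsFactors = FALSE),
            class = c("labeled_scores", "data.frame"))
}

#' Area under the ROC curve (tie-aware Mann-Whitney)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)` over all
#' positive/negative pairs, computed from midranks; identical to the
#' trapezoidal area under the tie-aware ROC curve.
#'
#' @param data a [labeled_scores()] object.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(data) {
  pos <- data$label == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative item")
  }
  r <- rank(data$score)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve vertices
#'
#' One vertex per candidate threshold (each unique score, plus `Inf` for the
#' call-nothing-positive corner); an item is predicted positive when its
#' score is `>=` the threshold.
#'
#' @param data a [labeled_scores()] object.
#' @return data frame: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(data) {
  pos <- data$label == "positive"
  thresholds <- c(Inf, sort(unique(data$score), decreasing = TRUE))
  do.call(rbind, lapply(thresholds, function(t) {
    called <- data$score >= t
    data.frame(threshold = t,
               sensitivity = sum(called & pos) / sum(pos),
               specificity = sum(!called & !pos) / sum(!pos))
  }))
}

#' Operating point within a specificity window
#'
#' Among ROC vertices whose specificity lies in `spec_range`, picks the one
#' maximizing sensitivity (ties broken toward higher specificity) and
#' reports the confusion lists by id. This reconstructs reporting errors "at
#' a comparable type-I error rate" across species panels.
#'
#' @param data a [labeled_scores()] object.
#' @param spec_range length-2 numeric interval for specificity
#'   (default `c(0.56, 0.75)`).
#' @return object of class `operating_point`: list with `threshold`,
#'   `sensitivity`, `specificity`, `false_positive_ids`,
#'   `false_negative_ids`.
#' @export
operating_point <- function(data, spec_range = c(0.56, 0.75)) {
  stopifnot(length(spec_range) == 2L, spec_range[1L] <= spec_range[2L])
  pts <- roc_points(data)
  inside <- pts$specificity >= spec_range[1L] & pts$specificity <= spec_range[2L]
  if (!any(inside)) {
    stop("no ROC vertex with specificity in [", spec_range[1L], ", ",
         spec_range[2L], "]; achievable specificities nearest the window: ",
         paste(sort(unique(round(pts$specificity, 4L))), collapse = ", "))
  }
  cand <- pts[inside, , drop = FALSE]
  cand <- cand[order(-cand$sensitivity, -cand$specificity), , drop = FALSE]
  t_star <- cand$threshold[1L]
  called <- data$score >= t_star
  pos <- data$label == "positive"
  structure(list(threshold = t_star,
                 sensitivity = cand$sensitivity[1L],
                 specificity = cand$specificity[1L],
                 false_positive_ids = data$id[called & !pos],
                 false_negative_ids = data$id[!called & pos]),
            class = "operating_point")
}

#' @exportS3Method print operating_point
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.4g: sens %.3f, spec %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  cat("  false positives:", paste(x$false_positive_ids, collapse = ", "), "\n")
  cat("  false negatives:", paste(x$false_negative_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Dose-response slope of predicted carcinogenicity
#'
#' Ordinary least-squares slope of the predicted statistic on administered
#' dose (rescaled to `dose_unit`), with a one-sided p-value for the
#' alternative that the slope is positive (upper-tail t on `n - 2` degrees
#' of freedom).
#'
#' @param dose numeric administered doses (>= 3 values, not all equal,
#'   strictly increasing recommended).
#' @param predicted_z numeric predicted statistic per dose.
#' @param dose_unit report the slope per this many dose units (e.g. 100 for
#'   "per 100 mg/kg"); default 1.
#' @return list: `slope` (per `dose_unit`), `p_one_sided`.
#' @export
dose_slope <- function(dose, predicted_z, dose_unit = 1) {
  stopifnot(length(dose) == length(predicted_z))
  if (length(dose) < 3L) stop("need at least 3 dose points")
  if (stats::var(dose) == 0) stop("zero dose variance")
  x <- dose / dose_unit
  fit <- stats::lm(predicted_z ~ x)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-10 * max(1, mean(predicted_z^2))) {
    # exact fit: the t statistic degenerates; the one-sided p collapses to
    # its limiting value by the sign of the slope
    p <- if (slope > 0) 0 else if (slope < 0) 1 else 0.5
  } else {
    tval <- summary(fit)$coefficients[2L, "t value"]
    p <- stats::pt(tval, df = length(dose) - 2L, lower.tail = FALSE)
  }
  list(slope = slope, p_one_sided = p)
}

#' Binary scores reproducing a known confusion outcome
#'
#' Builds a [labeled_scores()] fixture in which, at threshold 1, the set of
#' predicted positives is exactly (true positives) plus the given false
#' positives. Used to check operating-point arithmetic against published
#' confusion lists.
#'
#' @param labels named character vector (`id -> "positive"/"negative"`).
#' @param fp_ids ids falsely called positive.
#' @param fn_ids ids falsely called negative.
#' @return a [labeled_scores()] object.
#' @export
confusion_fixture_scores <- function(labels, fp_ids, fn_ids) {
  stopifnot(all(fp_ids %in% names(labels)), all(fn_ids %in% names(labels)))
  called <- (labels == "positive" & !(names(labels) %in% fn_ids)) |
    names(labels) %in% fp_ids
  labeled_scores(names(labels), as.numeric(called), unname(labels))
}
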