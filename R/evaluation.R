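#' Confusion counts for a binary evaluation
#'
#' @param y_true,y_pred Equal-length 0/1 vectors (truth, prediction).
#' @return Object of class `bb_confusion`: list with `tp`, `fp`, `tn`, `fn`.
#'   The four counts always sum to the number of evaluated windows.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))  # tp 1, fn 1, tn 1, fp 1
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stopf("y_true (%d) and y_pred (%d) lengths differ",
          length(y_true), length(y_pred))
  }
  if (length(y_true) < 1) stopf("nothing to evaluate")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  structure(list(
    tp = sum(y_true == 1L & y_pred == 1L),
    fp = sum(y_true == 0L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fn = sum(y_true == 1L & y_pred == 0L)
  ), class = "bb_confusion")
}

#' @export
print.bb_confusion <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`, defined as 0 when both are 0.
#'
#' @param p Precision in \[0, 1\].
#' @param r Recall in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
#' @examples
#' f1_score(0.99, 0.82)
f1_score <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Per-class metrics from confusion counts
#'
#' Precision and recall for both classes, per-class F1 (harmonic mean of
#' precision and recall), the macro average of F1 (unweighted mean over the
#' two classes), the support-weighted average of F1, and accuracy. A zero
#' denominator yields 0 for that metric and sets the `degenerate` flag.
#'
#' @param cm A [confusion()] object.
#' @return Object of class `bb_metrics` with fields `precision_pos`,
#'   `precision_neg`, `recall_pos`, `recall_neg`, `f1_pos`, `f1_neg`,
#'   `macro_avg_f1`, `weighted_avg_f1`, `accuracy`, `support_pos`,
#'   `support_neg`, `degenerate`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "bb_confusion"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total < 1) stopf("empty confusion table")
  support_pos <- cm$tp + cm$fn
  support_neg <- cm$tn + cm$fp
  degenerate <- any(c(cm$tp + cm$fp, cm$tn + cm$fn,
                      support_pos, support_neg) == 0)
  precision_pos <- safe_div(cm$tp, cm$tp + cm$fp)
  precision_neg <- safe_div(cm$tn, cm$tn + cm$fn)
  recall_pos <- safe_div(cm$tp, support_pos)
  recall_neg <- safe_div(cm$tn, support_neg)
  f1_pos <- f1_score(precision_pos, recall_pos)
  f1_neg <- f1_score(precision_neg, recall_neg)
  structure(list(
    precision_pos = precision_pos, precision_neg = precision_neg,
    recall_pos = recall_pos, recall_neg = recall_neg,
    f1_pos = f1_pos, f1_neg = f1_neg,
    macro_avg_f1 = (f1_pos + f1_neg) / 2,
    weighted_avg_f1 = (f1_neg * support_neg + f1_pos * support_pos) / total,
    accuracy = (cm$tp + cm$tn) / total,
    support_pos = support_pos, support_neg = support_neg,
    degenerate = degenerate
  ), class = "bb_metrics")
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (under `seed`) and deals its members to
#' the k folds round-robin, rotating the starting fold between classes so
#' fold sizes stay as equal as the totals allow (exactly equal when the
#' total divides by k).
#'
#' @param y Integer 0/1 labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffles.
#' @return Integer vector in `1..k`, one fold id per observation.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  k <- as.integer(k)
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < k)) {
    stopf("k = %d exceeds the minority-class count (%d)", k, min(counts))
  }
  folds <- integer(length(y))
  offset <- 0L
  local_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

#' Cross-validated comparison of a model roster
#'
#' Splits the windows into `k` stratified folds (one fixed assignment,
#' reused identically by every model), trains each spec on k-1 folds and
#' tests on the held-out fold, and reports the mean and standard deviation
#' of the fold accuracies plus the mean wall-clock time to train and test
#' one fold. Timing is informational only: it depends on the host and is
#' never compared.
#'
#' @param X Feature matrix (or a [build_feature_matrix()] table, in which
#'   case `y` may be omitted).
#' @param y Integer 0/1 labels.
#' @param specs List of [model_spec()]s (default: the eight-model roster).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A `data.frame` with columns `Model`, `MeanAccuracy`, `Std`,
#'   `FoldTimeSeconds` (unrounded), with attributes `fold_assignment`
#'   (integer vector) and `fold_accuracies` (k x n_models matrix).
#' @export
kfold_compare <- function(X, y = NULL, specs = default_model_specs(),
                          k = 10, seed = 1L) {
  if (is.data.frame(X) && "label" %in% names(X)) {
    xy <- feature_xy(X)
    X <- xy$X
    if (is.null(y)) y <- xy$y
  }
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- stratified_folds(y, k, seed)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  acc <- matrix(NA_real_, nrow = k, ncol = length(specs),
                dimnames = list(NULL, names(specs)))
  fold_time <- numeric(length(specs))
  for (m in seq_along(specs)) {
    t0 <- proc.time()[["elapsed"]]
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- fit_model(specs[[m]], X[!test, , drop = FALSE], y[!test])
      pred <- predict(fit, X[test, , drop = FALSE])
      acc[f, m] <- mean(pred == y[test])
    }
    fold_time[m] <- (proc.time()[["elapsed"]] - t0) / k
  }
  out <- data.frame(
    Model = names(specs),
    MeanAccuracy = colMeans(acc),
    Std = apply(acc, 2, sd),
    FoldTimeSeconds = fold_time,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fold_assignment") <- folds
  attr(out, "fold_accuracies") <- acc
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  out
}

#' Leave-one-subject-out per-participant evaluation
#'
#' For each participant, the chosen model is trained on every other
#' participant's windows and tested on that participant's own windows
#' (1,440 per person in the full study: 4 positions x 360 windows). One
#' row of per-class precision/recall/F1, macro and weighted F1 averages and
#' accuracy is emitted per person, followed by a `Mean` row holding the
#' average accuracy across persons.
#'
#' @param features A [build_feature_matrix()] table (needs the
#'   `participant` column).
#' @param spec The [model_spec()] to evaluate (default: the random forest).
#' @param seed Integer seed applied to the spec for each fit.
#' @return A `data.frame` shaped like the per-person report: `Person`,
#'   `PrecisionNoBeating`, `PrecisionHeartBeating`, `RecallNoBeating`,
#'   `RecallHeartBeating`, `F1NoBeating`, `F1HeartBeating`, `MacroAverage`,
#'   `WeightedAverage`, `Accuracy` (unrounded), with the per-person
#'   `bb_metrics` objects in attribute `metrics`.
#' @export
per_person_eval <- function(features, spec = model_spec("RF"), seed = 1L) {
  if (!"participant" %in% names(features)) {
    stopf("features table lacks a 'participant' column")
  }
  people <- unique(features$participant)
  if (length(people) < 2) stopf("need at least two participants")
  xy <- feature_xy(features)
  spec$seed <- as.integer(seed)
  rows <- list()
  mets <- list()
  for (p in people) {
    test <- features$participant == p
    if (!any(test)) stopf("participant %s has no windows", p)
    fit <- fit_model(spec, xy$X[!test, , drop = FALSE], xy$y[!test])
    pred <- predict(fit, xy$X[test, , drop = FALSE])
    mm <- metrics_from_confusion(confusion(xy$y[test], pred))
    mets[[p]] <- mm
    rows[[p]] <- data.frame(
      Person = p,
      PrecisionNoBeating = mm$precision_neg,
      PrecisionHeartBeating = mm$precision_pos,
      RecallNoBeating = mm$recall_neg,
      RecallHeartBeating = mm$recall_pos,
      F1NoBeating = mm$f1_neg,
      F1HeartBeating = mm$f1_pos,
      MacroAverage = mm$macro_avg_f1,
      WeightedAverage = mm$weighted_avg_f1,
      Accuracy = mm$accuracy,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  mean_row <- out[1, ]
  mean_row[1, ] <- NA
  mean_row$Person <- "Mean"
  mean_row$Accuracy <- mean(out$Accuracy)
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  attr(out, "metrics") <- mets
  attr(out, "protocol") <- "leave-one-subject-out"
  out
}

#' Majority-class baseline accuracy
#'
#' The accuracy of always predicting the more frequent class; the floor any
#' informative classifier must clear.
#'
#' @param y Integer 0/1 labels.
#' @return Fraction in \[0.5, 1\].
#' @export
majority_baseline <- function(y) {
  max(table(factor(as.integer(y), levels = c(0, 1)))) / length(y)
}
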