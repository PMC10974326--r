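test_that("confusion counts match hand counts and a counting loop", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unlist(cm[c("tp", "fn", "tn", "fp")]),
                   c(tp = 1L, fn = 1L, tn = 1L, fp = 1L))

  y <- c(1L, 0L, 1L)
  cm_id <- confusion(y, y)
  expect_identical(cm_id$fp + cm_id$fn, 0L)

  set.seed(41)
  yt <- sample(0:1, 10000, replace = TRUE)
  yp <- sample(0:1, 10000, replace = TRUE)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(yt)) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1L
    else if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1L
    else if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  cm2 <- confusion(yt, yp)
  expect_identical(unlist(cm2[c("tp", "fp", "tn", "fn")]),
                   c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_identical(cm2$tp + cm2$fp + cm2$tn + cm2$fn, 10000L)

  expect_error(confusion(1:3, 1:2), "differ")
})

test_that("metrics reproduce the printed per-person worked example", {
  # person 3 of the per-person report: printed precision/recall
  f1_pos <- f1_score(0.99, 0.82)
  f1_neg <- f1_score(0.91, 0.99)
  # F1+ recomputed from the 2 d.p. precision/recall; printed value 0.89
  expect_lt(abs(f1_pos - 0.89), 0.01)
  expect_identical(round((f1_pos + f1_neg) / 2, 2), 0.92)
})

test_that("perfect predictions score 1 on every metric", {
  m <- metrics_from_confusion(structure(list(tp = 50L, fp = 0L, tn = 50L,
                                             fn = 0L), class = "bb_confusion"))
  for (f in c("precision_pos", "precision_neg", "recall_pos", "recall_neg",
              "f1_pos", "f1_neg", "macro_avg_f1", "weighted_avg_f1",
              "accuracy")) {
    expect_identical(m[[f]], 1)
  }
  expect_false(m$degenerate)
})

test_that("metrics agree with a brute-force implementation on random tables", {
  set.seed(59)
  for (i in 1:1000) {
    counts <- as.integer(rmultinom(1, sample(4:400, 1), rep(0.25, 4)))
    cm <- structure(list(tp = counts[1], fp = counts[2], tn = counts[3],
                         fn = counts[4]), class = "bb_confusion")
    m <- metrics_from_confusion(cm)
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    total <- tp + fp + tn + fn
    pp <- if (tp + fp == 0) 0 else tp / (tp + fp)
    pn <- if (tn + fn == 0) 0 else tn / (tn + fn)
    rp <- if (tp + fn == 0) 0 else tp / (tp + fn)
    rn <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1p <- if (pp + rp == 0) 0 else 2 * pp * rp / (pp + rp)
    f1n <- if (pn + rn == 0) 0 else 2 * pn * rn / (pn + rn)
    expect_equal(m$precision_pos, pp)
    expect_equal(m$precision_neg, pn)
    expect_equal(m$recall_pos, rp)
    expect_equal(m$recall_neg, rn)
    expect_equal(m$f1_pos, f1p)
    expect_equal(m$f1_neg, f1n)
    expect_equal(m$macro_avg_f1, (f1p + f1n) / 2)
    expect_equal(m$weighted_avg_f1,
                 (f1n * (tn + fp) + f1p * (tp + fn)) / total)
    expect_equal(m$accuracy, (tp + tn) / total)
    # structural invariants
    expect_gte(m$macro_avg_f1, min(f1p, f1n))
    expect_lte(m$macro_avg_f1, max(f1p, f1n))
    expect_equal(m$accuracy, 1 - (fp + fn) / total)
    if (tp + fn == tn + fp) expect_equal(m$weighted_avg_f1, m$macro_avg_f1)
  }
})

test_that("stratified folds are balanced, class-complete and reproducible", {
  set.seed(61)
  y <- rep(c(0L, 1L), times = c(83, 117))
  f1 <- stratified_folds(y, 10, seed = 4)
  f2 <- stratified_folds(y, 10, seed = 4)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:10)
  expect_lte(diff(range(table(f1))), 1)
  for (k in 1:10) expect_identical(sort(unique(y[f1 == k])), c(0L, 1L))
  expect_error(stratified_folds(y, 1), "k must be")
  expect_error(stratified_folds(rep(0:1, c(195, 5)), 10), "minority")
})

test_that("a constant predictor's CV accuracy equals the majority fraction", {
  y <- rep(c(0L, 1L), times = c(120, 80))
  folds <- stratified_folds(y, 10, seed = 2)
  fold_acc <- vapply(1:10, function(f) mean(y[folds == f] == 0L), numeric(1))
  expect_equal(mean(fold_acc), majority_baseline(y))
  expect_equal(sd(fold_acc),
               sqrt(sum((fold_acc - mean(fold_acc))^2) / 9))
})

test_that("kfold_compare reuses one fold assignment and runs a minimal case", {
  toy <- separable_toy(n_per_class = 20, sd = 0.3)
  specs <- list(model_spec("LR", seed = 1), model_spec("CART", seed = 1))
  cv <- kfold_compare(toy$X, toy$y, specs, k = 4, seed = 9)
  expect_identical(nrow(cv), 2L)
  expect_identical(dim(attr(cv, "fold_accuracies")), c(4L, 2L))
  expect_identical(attr(cv, "fold_assignment"),
                   stratified_folds(toy$y, 4, seed = 9))
  expect_true(all(cv$Std >= 0))

  # minimal: k = 2 on 4 windows, 2 per class
  X4 <- matrix(rnorm(48), 4, 12, dimnames = list(NULL, feature_names()))
  cv2 <- kfold_compare(X4, c(0L, 1L, 0L, 1L),
                       list(model_spec("NB", seed = 1)), k = 2, seed = 1)
  expect_identical(nrow(cv2), 1L)
  expect_identical(table(attr(cv2, "fold_assignment")),
                   table(c(1L, 1L, 2L, 2L)))
})

test_that("per-person rows are symmetric for identical participants", {
  rec <- tiny_dataset()[[1]]$recording
  feats1 <- build_feature_matrix(list(rec))
  feats2 <- feats1
  feats1$participant <- "A"
  feats2$participant <- "B"
  both <- rbind(feats1, feats2)
  pp <- per_person_eval(both, spec = model_spec("RF"), seed = 5)
  expect_identical(nrow(pp), 3L)
  expect_identical(pp$Person, c("A", "B", "Mean"))
  expect_equal(pp$Accuracy[1], pp$Accuracy[2])
  expect_equal(pp[1, -1], pp[2, -1], ignore_attr = TRUE)
  expect_equal(pp$Accuracy[3], mean(pp$Accuracy[1:2]))
  expect_error(per_person_eval(feats1), "two participants")
})

test_that("degenerate confusion tables yield flagged zero metrics", {
  cm <- confusion(c(0L, 0L), c(1L, 1L))  # no true positives/negatives support
  m <- metrics_from_confusion(cm)
  expect_true(m$degenerate)
  expect_identical(m$precision_pos, 0)
  expect_identical(m$accuracy, 0)
  expect_gte(min(unlist(m[1:9])), 0)
  expect_lte(max(unlist(m[1:9])), 1)
})
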