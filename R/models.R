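bb_model_names <- c("LR", "LDA", "KNN", "CART", "NB", "SVM", "RF", "DL")

## Scale-sensitive learners get z-scored inputs (fitted on training rows
## only); trees, naive Bayes and LDA do not need it.
bb_standardize_default <- c(
  LR = TRUE, LDA = FALSE, KNN = TRUE, CART = FALSE,
  NB = FALSE, SVM = TRUE, RF = FALSE, DL = TRUE
)

#' Model specification
#'
#' One of the eight classifiers in the comparison roster, with its resolved
#' hyperparameters. Mandated settings: the random forest uses 100 trees; the
#' deep-learning model is a 12-input MLP with two hidden layers of nine
#' neurons (ReLU), one sigmoid output, SGD with learning rate 0.1, 100
#' epochs, batch size 10. Other defaults (KNN k = 5, radial-kernel SVM with
#' cost 1, Gini trees) are package choices where the study left them open.
#'
#' @param name One of `"LR"`, `"LDA"`, `"KNN"`, `"CART"`, `"NB"`, `"SVM"`,
#'   `"RF"`, `"DL"`.
#' @param hyperparameters Named list overriding defaults for this model.
#' @param standardize_inputs Z-score inputs using training-fold statistics;
#'   default depends on the model (TRUE for LR, KNN, SVM, DL).
#' @param seed Integer seed used by stochastic learners.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("RF")$hyperparameters$n_trees  # 100
model_spec <- function(name, hyperparameters = list(),
                       standardize_inputs = NULL, seed = 1L) {
  if (length(name) != 1 || !name %in% bb_model_names) {
    stopf("unknown model name '%s'; expected one of %s",
          paste(name, collapse = ","), paste(bb_model_names, collapse = ", "))
  }
  defaults <- switch(name,
    LR   = list(threshold = 0.5),
    LDA  = list(),
    KNN  = list(k = 5),
    CART = list(),                    # rpart defaults: Gini splits
    NB   = list(),                    # Gaussian class-conditionals
    SVM  = list(kernel = "radial", cost = 1),
    RF   = list(n_trees = 100),
    DL   = list(hidden = c(9, 9), lr = 0.1, epochs = 100, batch_size = 10,
                threshold = 0.5)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  if (name == "RF" && (is.null(hp$n_trees) || hp$n_trees < 1)) {
    stopf("RF requires a positive n_trees (mandated default 100)")
  }
  if (name == "DL" && (is.null(hp$lr) || is.null(hp$epochs) ||
                       is.null(hp$hidden) || is.null(hp$batch_size))) {
    stopf("DL spec must carry hidden, lr, epochs and batch_size")
  }
  if (is.null(standardize_inputs)) {
    standardize_inputs <- unname(bb_standardize_default[name])
  }
  structure(list(name = name, hyperparameters = hp,
                 standardize_inputs = isTRUE(standardize_inputs),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' The default eight-model comparison roster
#'
#' @param seed Integer seed shared by the specs (each learner reseeds its
#'   own fit deterministically from it).
#' @return Named list of eight [model_spec()]s: LR, LDA, KNN, CART, NB,
#'   SVM, RF, DL.
#' @export
default_model_specs <- function(seed = 1L) {
  out <- lapply(bb_model_names, model_spec, seed = seed)
  names(out) <- bb_model_names
  out
}

#' Instantiate an untrained estimator from a spec
#'
#' Mostly a validation step: the returned object describes the configured
#' estimator (e.g. tree count, layer widths) and is fitted with
#' [fit_model()].
#'
#' @param spec A [model_spec()].
#' @return An object of class `bb_estimator` with a `describe` field.
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  describe <- switch(spec$name,
    RF = sprintf("random forest, %d trees", spec$hyperparameters$n_trees),
    DL = sprintf("MLP %s", paste(c(12, spec$hyperparameters$hidden, 1),
                                 collapse = " -> ")),
    KNN = sprintf("k-nearest neighbours, k = %d", spec$hyperparameters$k),
    SVM = sprintf("SVM, %s kernel", spec$hyperparameters$kernel),
    sprintf("%s with default configuration", spec$name)
  )
  structure(list(spec = spec, describe = describe), class = "bb_estimator")
}

#' Layer widths of a configured network spec
#'
#' @param spec A `DL` [model_spec()].
#' @param n_inputs Input dimensionality (default 12).
#' @return Integer vector of layer sizes, input to output.
#' @export
dl_layer_sizes <- function(spec, n_inputs = 12) {
  stopifnot(inherits(spec, "model_spec"), spec$name == "DL")
  as.integer(c(n_inputs, spec$hyperparameters$hidden, 1))
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[!is.finite(sc) | sc == 0] <- 1   # constant feature: leave centred only
  list(center = mu, scale = sc)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Fit a classifier to features and labels
#'
#' Every model of the roster trains through this one interface. If the spec
#' asks for standardization, per-feature mean and scale are computed from
#' the training rows only and stored for prediction. Stochastic learners
#' (CART/RF tie-breaks, MLP initialization and shuffling, KNN distance-tie
#' votes) run under the spec's seed, so repeated fits are identical.
#'
#' @param spec A [model_spec()] (or a `bb_estimator` from [make_model()]).
#' @param X Numeric feature matrix (rows = windows).
#' @param y Integer 0/1 labels, one per row.
#' @return An object of class `bb_model`.
#' @export
fit_model <- function(spec, X, y) {
  if (inherits(spec, "bb_estimator")) spec <- spec$spec
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) stopf("X rows and y length differ")
  present <- sort(unique(y))
  if (!all(c(0L, 1L) %in% present)) {
    stopf("training labels contain a single class: class %d is missing",
          setdiff(c(0L, 1L), present)[1])
  }
  scaler <- if (spec$standardize_inputs) fit_scaler(X) else NULL
  Xs <- apply_scaler(X, scaler)
  hp <- spec$hyperparameters
  df <- as.data.frame(Xs)
  fit <- local_seed(spec$seed, switch(spec$name,
    LR = suppressWarnings(glm(y ~ ., data = cbind(df, y = y),
                              family = binomial())),
    LDA = MASS::lda(x = Xs, grouping = factor(y, levels = c(0, 1))),
    KNN = list(train = Xs, cl = factor(y, levels = c(0, 1)), k = hp$k),
    CART = rpart::rpart(y ~ ., data = cbind(df, y = factor(y, levels = c(0, 1))),
                        method = "class"),
    NB = e1071::naiveBayes(x = Xs, y = factor(y, levels = c(0, 1))),
    SVM = e1071::svm(x = Xs, y = factor(y, levels = c(0, 1)),
                     kernel = hp$kernel, cost = hp$cost, scale = FALSE),
    RF = randomForest::randomForest(x = Xs, y = factor(y, levels = c(0, 1)),
                                    ntree = hp$n_trees),
    DL = mlp_fit(Xs, y, hidden = hp$hidden, lr = hp$lr, epochs = hp$epochs,
                 batch_size = hp$batch_size, seed = spec$seed)
  ))
  structure(list(spec = spec, fit = fit, scaler = scaler, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "bb_model")
}

#' Predict 0/1 window labels
#'
#' Probability-based models (logistic regression, the MLP) threshold
#' P(heartbeat) at 0.5; the others emit their predicted class directly.
#'
#' @param object A fitted `bb_model`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Integer 0/1 vector, one label per row.
#' @export
predict.bb_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (nrow(X) == 0) return(integer(0))
  if (ncol(X) != object$n_features) {
    stopf("expected %d features, got %d", object$n_features, ncol(X))
  }
  colnames(X) <- object$feature_names
  Xs <- apply_scaler(X, object$scaler)
  spec <- object$spec
  hp <- spec$hyperparameters
  out <- local_seed(spec$seed + 1L, switch(spec$name,
    LR = as.integer(predict(object$fit, newdata = as.data.frame(Xs),
                            type = "response") >= hp$threshold),
    LDA = as.integer(as.character(predict(object$fit, Xs)$class)),
    KNN = as.integer(as.character(
      class::knn(object$fit$train, Xs, object$fit$cl, k = object$fit$k))),
    CART = as.integer(as.character(
      predict(object$fit, newdata = as.data.frame(Xs), type = "class"))),
    NB = as.integer(as.character(predict(object$fit, Xs))),
    SVM = as.integer(as.character(predict(object$fit, Xs))),
    RF = as.integer(as.character(predict(object$fit, Xs))),
    DL = as.integer(predict(object$fit, Xs) >= hp$threshold)
  ))
  unname(out)
}
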