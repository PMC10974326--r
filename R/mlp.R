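#' Train the heartbeat-detection multilayer perceptron
#'
#' A small fully connected network for binary classification: ReLU hidden
#' layers, a single sigmoid output unit, binary cross-entropy loss, plain
#' mini-batch stochastic gradient descent. Defaults follow the study's
#' configuration: two hidden layers of nine neurons, learning rate 0.1,
#' 100 epochs, batch size 10, 12 inputs, one output. Inputs should be
#' standardized (see [fit_model()], which does this for the `DL` spec).
#'
#' @param X Numeric matrix of predictors (rows = windows).
#' @param y Integer 0/1 labels.
#' @param hidden Integer vector of hidden-layer widths (default `c(9, 9)`).
#' @param lr SGD learning rate (default 0.1).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 10).
#' @param seed Integer seed for weight initialization and epoch shuffling.
#' @return An object of class `bb_mlp`.
#' @export
mlp_fit <- function(X, y, hidden = c(9, 9), lr = 0.1, epochs = 100,
                    batch_size = 10, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X rows and y length differ")
  fit <- local_seed(seed, {
    mlp_train_cpp(X, y, as.integer(hidden), lr, as.integer(epochs),
                  as.integer(batch_size))
  })
  structure(list(weights = fit$weights, biases = fit$biases,
                 sizes = fit$sizes, hidden = hidden),
            class = "bb_mlp")
}

#' Predict class probabilities from a trained MLP
#'
#' @param object A `bb_mlp` from [mlp_fit()].
#' @param newdata Numeric matrix with the training feature dimensionality.
#' @param ... Unused.
#' @return Numeric vector of P(heartbeat) in (0, 1).
#' @export
predict.bb_mlp <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  if (nrow(A) == 0) return(numeric(0))
  if (ncol(A) != object$sizes[1]) {
    stopf("expected %d features, got %d", object$sizes[1], ncol(A))
  }
  nl <- length(object$weights)
  for (l in seq_len(nl)) {
    Z <- A %*% object$weights[[l]]
    Z <- sweep(Z, 2, object$biases[[l]], "+")
    A <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.numeric(A)
}
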