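#' Funnel multilayer perceptron specification
#'
#' Architecture and training settings for [mlp_train()]: a feed-forward
#' network whose hidden widths halve down a funnel (512, 256, 128, 64,
#' 32 by default), ReLU activations, a softmax output over the classes,
#' L2 weight decay, and the Adam optimizer with optional early stopping
#' on a held-out validation fraction of the training data.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param l2 L2 regularization strength on the weights (default 0.001).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Mini-batch size (default 64).
#' @param early_stopping Stop when validation loss stops improving?
#' @param patience Early-stopping patience in epochs (default 20).
#' @param validation_fraction Fraction of the training rows held out for
#'   early stopping (default 0.1).
#'
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_layers = c(512, 256, 128, 64, 32),
                     l2 = 0.001, learning_rate = 0.001, epochs = 200,
                     batch_size = 64, early_stopping = TRUE, patience = 20,
                     validation_fraction = 0.1) {
  if (length(hidden_layers) < 1 || any(hidden_layers < 1)) {
    abort("`hidden_layers` must be positive widths.")
  }
  assert_scalar_number(l2, "l2", 0)
  assert_scalar_number(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  assert_scalar_number(epochs, "epochs", 1)
  assert_scalar_number(batch_size, "batch_size", 1)
  structure(
    list(
      hidden_layers = as.integer(hidden_layers), l2 = l2,
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      early_stopping = isTRUE(early_stopping), patience = as.integer(patience),
      validation_fraction = validation_fraction
    ),
    class = "mlp_spec"
  )
}

#' One-hot encode class labels
#'
#' @param y Factor of class labels.
#' @return A binary matrix, one column per class level.
#' @export
one_hot <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy plus L2 penalty on the weights (not biases).
mlp_loss <- function(probs, y_onehot, weights, l2) {
  ce <- -mean(rowSums(y_onehot * log(pmax(probs, 1e-12))))
  ce + l2 * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
}

mlp_forward <- function(weights, biases, x) {
  acts <- list(x)
  n_layers <- length(weights)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% weights[[l]] +
      matrix(biases[[l]], nrow(x), length(biases[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < n_layers) relu(z) else softmax_rows(z)
  }
  acts
}

#' Train the funnel multilayer perceptron
#'
#' Trains the network of [mlp_spec()] with mini-batch Adam on the
#' softmax cross-entropy loss with L2 weight decay. Labels are one-hot
#' encoded internally. Weights use He initialization. When early
#' stopping is enabled, a stratified validation fraction of the training
#' rows is held out and training stops once the validation loss has not
#' improved for `patience` epochs, restoring the best weights.
#' Deterministic under a fixed seed.
#'
#' @param train Feature table with a `group` label column.
#' @param spec An [mlp_spec()].
#' @param seed Integer seed for initialization, batching and the
#'   validation split.
#' @return An `ls_classifier` of family `"mlp"` whose fit carries the
#'   weights and the per-epoch loss `history`.
#' @export
mlp_train <- function(train, spec = mlp_spec(), seed = 42) {
  x <- feature_matrix(train)
  y <- droplevels(as.factor(train$group))
  y_hot <- one_hot(y)
  n_class <- ncol(y_hot)
  dims <- c(ncol(x), spec$hidden_layers, n_class)
  n_layers <- length(dims) - 1

  with_seed(derive_seed(seed, "mlp"), {
    # Validation holdout for early stopping (stratified).
    if (spec$early_stopping && spec$validation_fraction > 0) {
      val_idx <- unlist(lapply(levels(y), function(cls) {
        idx <- which(y == cls)
        sample(idx, max(1, round(spec$validation_fraction * length(idx))))
      }))
      x_val <- x[val_idx, , drop = FALSE]
      y_val <- y_hot[val_idx, , drop = FALSE]
      x_tr <- x[-val_idx, , drop = FALSE]
      y_tr <- y_hot[-val_idx, , drop = FALSE]
    } else {
      x_val <- NULL
      x_tr <- x
      y_tr <- y_hot
    }
    n <- nrow(x_tr)

    weights <- lapply(seq_len(n_layers), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1])
    })
    biases <- lapply(seq_len(n_layers), function(l) numeric(dims[l + 1]))

    # Adam state
    mW <- lapply(weights, function(w) w * 0)
    vW <- mW
    mB <- lapply(biases, function(b) b * 0)
    vB <- mB
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0

    history <- numeric(0)
    best_val <- Inf
    best_state <- NULL
    stall <- 0

    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = spec$batch_size)
      for (s in batch_starts) {
        rows <- ord[s:min(s + spec$batch_size - 1, n)]
        xb <- x_tr[rows, , drop = FALSE]
        yb <- y_tr[rows, , drop = FALSE]
        m <- nrow(xb)

        acts <- mlp_forward(weights, biases, xb)
        delta <- (acts[[n_layers + 1]] - yb) / m # softmax + CE gradient
        for (l in rev(seq_len(n_layers))) {
          gW <- crossprod(acts[[l]], delta) + 2 * spec$l2 * weights[[l]]
          gB <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(weights[[l]])) * (acts[[l]] > 0)
          }
          step_l <- step + 1
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
          vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
          corr1 <- 1 - b1^step_l
          corr2 <- 1 - b2^step_l
          weights[[l]] <- weights[[l]] -
            spec$learning_rate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          biases[[l]] <- biases[[l]] -
            spec$learning_rate * (mB[[l]] / corr1) / (sqrt(vB[[l]] / corr2) + eps)
        }
        step <- step + 1
      }

      probs_tr <- mlp_forward(weights, biases, x_tr)[[n_layers + 1]]
      loss_tr <- mlp_loss(probs_tr, y_tr, weights, spec$l2)
      if (!is.finite(loss_tr)) {
        abort(sprintf("MLP training diverged at epoch %d (non-finite loss).", epoch))
      }
      history <- c(history, loss_tr)

      if (!is.null(x_val)) {
        probs_val <- mlp_forward(weights, biases, x_val)[[n_layers + 1]]
        loss_val <- mlp_loss(probs_val, y_val, weights, spec$l2)
        if (loss_val < best_val - 1e-6) {
          best_val <- loss_val
          best_state <- list(weights = weights, biases = biases)
          stall <- 0
        } else {
          stall <- stall + 1
          if (stall >= spec$patience) break
        }
      }
    }
    if (!is.null(best_state)) {
      weights <- best_state$weights
      biases <- best_state$biases
    }

    structure(
      list(
        family = "mlp",
        params = unclass(spec),
        fit = list(weights = weights, biases = biases, history = history,
                   n_epochs = length(history)),
        levels = levels(y),
        feature_names = colnames(x)
      ),
      class = c("ls_mlp", "ls_classifier")
    )
  })
}

#' @export
predict.ls_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newx <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  newx <- newx[, object$feature_names, drop = FALSE]
  acts <- mlp_forward(object$fit$weights, object$fit$biases, newx)
  probs <- acts[[length(acts)]]
  colnames(probs) <- object$levels
  if (type == "prob") {
    return(probs)
  }
  factor(object$levels[max.col(probs)], levels = object$levels)
}
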