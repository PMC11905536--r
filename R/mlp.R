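# Single-hidden-layer perceptron trained with minibatch SGD + momentum,
# leaky-ReLU hidden activation, cross-entropy loss and early stopping on a
# held-out validation split. Implemented directly with matrix algebra so
# that the penultimate (hidden-layer) activations — which the OpenMax
# recalibration needs — are first-class outputs of the model.

leaky_relu <- function(a, slope) ifelse(a > 0, a, slope * a)

#' SoftMax probabilities from logits
#'
#' `P(k|x) = exp(z_k) / sum_j exp(z_j)`, computed with max-subtraction for
#' numerical stability, so the result is invariant to shifting all logits
#' by a constant and never overflows.
#'
#' @param z Logit vector, or a samples-by-classes matrix of logits.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(z) {
  vec <- is.null(dim(z))
  z <- rbind(z)
  if (any(!is.finite(z))) stop("softmax requires finite logits")
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) p[1, ] else p
}

#' Train the classification MLP
#'
#' Fits a single-hidden-layer network with leaky-ReLU activation by
#' minibatch stochastic gradient descent with momentum on the multinomial
#' cross-entropy. A stratified validation split drives early stopping: when
#' validation loss fails to improve for `patience` consecutive epochs,
#' training stops and the weights from the best epoch are restored. The
#' published architecture uses an 80,000-unit hidden layer; `hidden_units`
#' is fully configurable and small layers (64-256 units) are adequate at
#' panel sizes of a few hundred probes, so the default here is deliberately
#' desk-scale.
#'
#' Inputs are standardised per feature (mean 0, sd 1 estimated from the
#' training data); the standardisation is stored in the model and applied
#' automatically at prediction time.
#'
#' @param x Samples-by-features matrix (panel-restricted, batch-corrected
#'   log-scale values).
#' @param y Class label per sample; every class must be represented.
#' @param hidden_units Hidden-layer width (default 128).
#' @param leaky_slope Negative-side slope of the leaky ReLU (default 0.01).
#' @param learning_rate,momentum SGD hyper-parameters (defaults 0.01, 0.9).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Upper bound on epochs (default 200).
#' @param validation_fraction Fraction held out per class for early
#'   stopping, in (0, 1) (default 0.1).
#' @param patience Epochs without validation improvement before stopping
#'   (default 10).
#' @param seed Seed controlling initialisation, the split and shuffling;
#'   identical seeds give identical weights (single-threaded).
#' @return An object of class `mlp_model` with weights, the feature
#'   standardisation, class levels, configuration, training history and
#'   `val_idx`, the row indices of the early-stopping validation split
#'   (rows of `x` never used in gradient updates; downstream distance
#'   calibration can treat them as held-out).
#' @export
train_mlp <- function(x, y, hidden_units = 128, leaky_slope = 0.01,
                      learning_rate = 0.01, momentum = 0.9, batch_size = 32,
                      max_epochs = 200, validation_fraction = 0.1,
                      patience = 10, seed = NULL) {
  assert_matrix(x)
  y <- droplevels(factor(y))
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  K <- nlevels(y); P <- ncol(x); H <- as.integer(hidden_units)
  yi <- as.integer(y)

  with_seed(seed, {
    # stratified validation split; every class keeps >= 1 training sample
    val <- unlist(lapply(split(seq_along(yi), yi), function(ix) {
      nv <- min(length(ix) - 1L, max(1L, round(validation_fraction * length(ix))))
      sample(ix, nv)
    }), use.names = FALSE)
    tr <- setdiff(seq_along(yi), val)
    if (length(unique(yi[tr])) < K)
      stop("a class is absent from the training split; supply more samples")

    # He-style uniform initialisation
    lim1 <- sqrt(6 / P); lim2 <- sqrt(6 / H)
    W1 <- matrix(stats::runif(P * H, -lim1, lim1), P, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::runif(H * K, -lim2, lim2), H, K)
    b2 <- numeric(K)
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2

    Ytr <- matrix(0, length(tr), K); Ytr[cbind(seq_along(tr), yi[tr])] <- 1
    xtr <- xs[tr, , drop = FALSE]
    xval <- xs[val, , drop = FALSE]; yval <- yi[val]

    val_loss <- function() {
      a <- leaky_relu(xval %*% W1 + rep(b1, each = nrow(xval)), leaky_slope)
      p <- softmax(a %*% W2 + rep(b2, each = nrow(xval)))
      -mean(log(pmax(p[cbind(seq_along(yval), yval)], 1e-12)))
    }

    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0L)
    history <- numeric(0)
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(nrow(xtr))
      for (start in seq(1, nrow(xtr), by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1, nrow(xtr))]
        xb <- xtr[ix, , drop = FALSE]; yb <- Ytr[ix, , drop = FALSE]
        n <- nrow(xb)
        z1 <- xb %*% W1 + rep(b1, each = n)
        a1 <- leaky_relu(z1, leaky_slope)
        p <- softmax(a1 %*% W2 + rep(b2, each = n))
        dz2 <- (p - yb) / n
        gW2 <- crossprod(a1, dz2); gb2 <- colSums(dz2)
        da1 <- dz2 %*% t(W2)
        dz1 <- da1 * ifelse(z1 > 0, 1, leaky_slope)
        gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
        vW1 <- momentum * vW1 - learning_rate * gW1; W1 <- W1 + vW1
        vb1 <- momentum * vb1 - learning_rate * gb1; b1 <- b1 + vb1
        vW2 <- momentum * vW2 - learning_rate * gW2; W2 <- W2 + vW2
        vb2 <- momentum * vb2 - learning_rate * gb2; b2 <- b2 + vb2
      }
      vl <- val_loss()
      if (!is.finite(vl))
        stop(sprintf("validation loss became non-finite at epoch %d; ",
                     epoch),
             "try a lower learning rate or check the inputs for extreme values")
      history <- c(history, vl)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }

    model <- list(
      W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
      center = center, scale = scl, val_idx = sort(val),
      features = colnames(x), classes = levels(y),
      config = list(hidden_units = H, leaky_slope = leaky_slope,
                    learning_rate = learning_rate, momentum = momentum,
                    batch_size = batch_size, max_epochs = max_epochs,
                    validation_fraction = validation_fraction,
                    patience = patience, seed = seed),
      best_epoch = best$epoch, val_loss = best$loss, history = history
    )
    class(model) <- "mlp_model"
    model
  })
}

# Standardise newdata and check dimensions/feature names against the model.
prep_input <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(model$center))
    stop(sprintf("input has %d features; model expects %d",
                 ncol(x), length(model$center)))
  if (!is.null(colnames(x)) && !is.null(model$features) &&
      !identical(colnames(x), model$features)) {
    if (!all(model$features %in% colnames(x)))
      stop("input feature names do not match the model's panel")
    x <- x[, model$features, drop = FALSE]
  }
  sweep(sweep(x, 2, model$center), 2, model$scale, "/")
}

#' Hidden-layer activations of an MLP
#'
#' Returns the penultimate-layer (leaky-ReLU) activations for each input;
#' these are the feature vectors whose distances to per-class mean
#' activation vectors drive the OpenMax recalibration.
#'
#' @param model An `mlp_model`.
#' @param x Feature vector or samples-by-features matrix on the model's
#'   panel.
#' @return Samples-by-hidden-units activation matrix.
#' @export
penultimate_activations <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  xs <- prep_input(model, x)
  leaky_relu(xs %*% model$W1 + rep(model$b1, each = nrow(xs)),
             model$config$leaky_slope)
}

#' Class logits of an MLP
#'
#' Deterministic forward pass producing the pre-SoftMax scores `z_k`.
#'
#' @inheritParams penultimate_activations
#' @return Samples-by-classes logit matrix (colnames = class levels).
#' @export
predict_logits <- function(model, x) {
  a <- penultimate_activations(model, x)
  z <- a %*% model$W2 + rep(model$b2, each = nrow(a))
  colnames(z) <- model$classes
  z
}

#' Predict from an MLP model
#'
#' @param object An `mlp_model`.
#' @param newdata Feature matrix on the model's panel.
#' @param type `"class"` (default), `"prob"` (SoftMax probabilities) or
#'   `"logits"`.
#' @param ... Ignored.
#' @return Factor of classes, or a numeric matrix for `"prob"`/`"logits"`.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob", "logits"),
                              ...) {
  type <- match.arg(type)
  z <- predict_logits(object, newdata)
  switch(type,
         logits = z,
         prob = {p <- softmax(z); p <- rbind(p); colnames(p) <- object$classes; p},
         class = factor(object$classes[max.col(rbind(z), ties.method = "first")],
                        levels = object$classes))
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP classifier: %d features -> %d hidden (leaky ReLU) -> %d classes\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2)))
  cat(sprintf("best epoch %d, validation loss %.4f\n", x$best_epoch, x$val_loss))
  invisible(x)
}

#' Save / load an MLP model
#'
#' The model directory holds human-readable JSON metadata (configuration,
#' class levels, feature panel) next to the weight arrays stored in an R
#' serialisation container; reloading reproduces predictions bit-for-bit.
#'
#' @param model An `mlp_model`.
#' @param dir Directory to create/populate.
#' @return `save_mlp`: `dir`, invisibly. `load_mlp`: the model.
#' @export
save_mlp <- function(model, dir) {
  stopifnot(inherits(model, "mlp_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(type = "mlp_model", classes = model$classes,
               features = model$features, config = model$config,
               best_epoch = model$best_epoch, val_loss = model$val_loss)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model[c("W1", "b1", "W2", "b2", "center", "scale", "history")],
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  w <- readRDS(file.path(dir, "weights.rds"))
  model <- c(w, list(features = meta$features, classes = meta$classes,
                     config = as.list(meta$config), best_epoch = meta$best_epoch,
                     val_loss = meta$val_loss))
  class(model) <- "mlp_model"
  model
}
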