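# Pair-feature construction and the fully-connected classifier: each
# drug-target pair is the concatenation of the drug's and the target's fused
# features; a 5-layer network (input, ReLU hidden layers of 300/200/100 with
# dropout, sigmoid output) predicts the interaction probability.

#' Build a labeled pair dataset from entity features
#'
#' @param h_d,h_t Drug (`n_d x d_d`) and target (`n_t x d_t`) feature
#'   matrices.
#' @param y Optional binary interaction matrix (`n_d x n_t`) supplying
#'   labels; omit for prediction mode.
#' @param pairs Two-column integer matrix of (drug index, target index)
#'   rows; defaults to all pairs in row-major (drug-major) order.
#' @return An object of class `pair_dataset`: `pairs`, `features`
#'   (`[h_d[i, ] || h_t[j, ]]` per row), `labels` (or `NULL`).
#' @export
make_pairs <- function(h_d, h_t, y = NULL, pairs = NULL) {
  stopifnot(is.matrix(h_d), is.matrix(h_t))
  if (inherits(y, "interaction_matrix")) y <- y$y
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(target = seq_len(nrow(h_t)),
                                   drug = seq_len(nrow(h_d))))[, c(2, 1)]
  }
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("drug", "target")))
  if (nrow(pairs) > 0 &&
      (min(pairs) < 1L || max(pairs[, 1]) > nrow(h_d) ||
       max(pairs[, 2]) > nrow(h_t))) {
    stop_dtifuse("pair index out of range", "dtifuse_validation_error")
  }
  features <- cbind(h_d[pairs[, 1], , drop = FALSE],
                    h_t[pairs[, 2], , drop = FALSE])
  rownames(features) <- NULL
  labels <- if (!is.null(y)) as.numeric(y[pairs]) else NULL
  structure(list(pairs = pairs, features = features, labels = labels,
                 drug_labels = rownames(h_d), target_labels = rownames(h_t)),
            class = "pair_dataset")
}

#' Classifier configuration
#'
#' Defaults: three ReLU hidden layers of 300, 200 and 100 units, dropout 0.5
#' on every hidden layer (training only), momentum SGD (lr 0.01, momentum
#' 0.9), binary cross-entropy loss, early stopping when validation accuracy
#' has not risen for `patience` consecutive epochs (best-epoch weights are
#' restored), with a stratified `val_fraction` of the training rows held out
#' for that monitor.
#'
#' @param hidden_widths Integer vector of hidden-layer widths.
#' @param dropout_p Dropout probability in \[0, 1).
#' @param learning_rate,momentum Momentum-SGD hyperparameters.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param val_fraction Fraction of training rows held out for the
#'   early-stopping monitor.
#' @param batch_size Minibatch size.
#' @param seed RNG seed (init, shuffling, dropout, validation split).
#' @return An object of class `dnn_config`.
#' @export
dnn_config <- function(hidden_widths = c(300L, 200L, 100L), dropout_p = 0.5,
                       learning_rate = 0.01, momentum = 0.9,
                       max_epochs = 200L, patience = 10L,
                       val_fraction = 0.1, batch_size = 32L, seed = 1L) {
  stopifnot(length(hidden_widths) >= 1, all(hidden_widths >= 1),
            dropout_p >= 0, dropout_p < 1, learning_rate >= 0,
            momentum >= 0, momentum < 1, max_epochs >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1, batch_size >= 1)
  structure(list(hidden_widths = as.integer(hidden_widths),
                 dropout_p = dropout_p, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "dnn_config")
}

dnn_acts <- function(cfg) c(rep("relu", length(cfg$hidden_widths)), "sigmoid")

dnn_init_layers <- function(input_dim, cfg) {
  dims <- c(input_dim, cfg$hidden_widths, 1L)
  lapply(seq_len(length(dims) - 1L), function(l) dense_init(dims[l], dims[l + 1L]))
}

# stratified index split: returns list(train, val)
stratified_split <- function(labels, val_fraction) {
  val <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    n_val <- max(1L, round(length(idx) * val_fraction))
    sample(idx, n_val)
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Train the pair classifier
#'
#' Minimizes the sample-averaged binary cross-entropy by momentum SGD with
#' dropout on the hidden layers; early stopping monitors accuracy on an
#' internal stratified validation split and restores the best-epoch weights.
#' Input features are standardized per column (training-set mean and sd,
#' stored in the model and re-applied at prediction time). Deterministic
#' given `cfg$seed`.
#'
#' @param train A labeled [make_pairs()] dataset containing both classes.
#' @param cfg A [dnn_config()].
#' @return An object of class `dnn_model` with fields `layers`, `config`,
#'   `input_dim`, `center`/`scale` (the stored standardization),
#'   `history` (per-epoch loss and train/val accuracy) and `best_epoch`.
#' @export
train_dnn <- function(train, cfg = dnn_config()) {
  stopifnot(inherits(train, "pair_dataset"), !is.null(train$labels))
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop_dtifuse("training data must contain both classes",
                 "dtifuse_validation_error")
  }
  # Per-feature standardization, learned on the training rows and stored in
  # the model: autoencoder bottleneck activations are sigmoid outputs
  # cramped near 0.5, and rescaling them to unit variance is what lets the
  # classifier move within the early-stopping patience window.
  center <- colMeans(train$features)
  scale_ <- apply(train$features, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  x <- scale(train$features, center, scale_)
  attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  acts <- dnn_acts(cfg)
  with_seed(cfg$seed, {
    split_idx <- stratified_split(y, cfg$val_fraction)
    xt <- x[split_idx$train, , drop = FALSE]
    yt <- y[split_idx$train]
    xv <- x[split_idx$val, , drop = FALSE]
    yv <- y[split_idx$val]
    layers <- dnn_init_layers(ncol(x), cfg)
    state <- NULL
    best <- list(acc = -Inf, epoch = 0L, layers = layers)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          train_acc = numeric(), val_acc = numeric())
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(xt))
      epoch_loss <- 0
      for (idx in minibatches(nrow(xt), cfg$batch_size, ord)) {
        xb <- xt[idx, , drop = FALSE]
        yb <- yt[idx]
        fwd <- mlp_forward(layers, acts, xb, dropout_p = cfg$dropout_p,
                           training = TRUE)
        a <- fwd$a[[length(fwd$a)]][, 1]
        loss <- bce_loss(yb, a)
        if (!is.finite(loss)) {
          stop_dtifuse(sprintf("classifier loss diverged at epoch %d", epoch),
                       "dtifuse_diverged_error")
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        delta_z <- matrix((a - yb) / length(yb), ncol = 1)
        grads <- mlp_backward(layers, acts, fwd, delta_z)$grads
        upd <- sgd_update(layers, grads, state, cfg$learning_rate,
                          cfg$momentum)
        layers <- upd$layers
        state <- upd$state
      }
      model_now <- structure(list(layers = layers, config = cfg,
                                  input_dim = ncol(x),
                                  center = rep(0, ncol(x)),
                                  scale = rep(1, ncol(x))),
                             class = "dnn_model")
      train_acc <- mean(classify(predict_proba(model_now, xt)) == yt)
      val_acc <- mean(classify(predict_proba(model_now, xv)) == yv)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  loss = epoch_loss / nrow(xt),
                                  train_acc = train_acc, val_acc = val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, layers = layers)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
    structure(list(layers = best$layers, config = cfg, input_dim = ncol(x),
                   center = center, scale = scale_,
                   history = history, best_epoch = best$epoch),
              class = "dnn_model")
  })
}

#' Predict interaction probabilities
#'
#' Dropout is disabled; predictions are deterministic and do not depend on
#' the RNG state.
#'
#' @param model A [train_dnn()] model.
#' @param features Feature matrix or a `pair_dataset`.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "dnn_model"))
  if (inherits(features, "pair_dataset")) features <- features$features
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$input_dim) {
    stop_dtifuse(sprintf("feature dimension %d does not match model input %d",
                         ncol(features), model$input_dim),
                 "dtifuse_shape_error")
  }
  features <- scale(features, model$center, model$scale)
  acts <- dnn_acts(model$config)
  fwd <- mlp_forward(model$layers, acts, features)
  fwd$a[[length(fwd$a)]][, 1]
}

#' Threshold probabilities into interaction calls
#'
#' A pair is called interacting only if its probability strictly exceeds
#' 0.5.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' classify(c(0.4, 0.5, 0.6))  # 0 0 1
classify <- function(probabilities) {
  as.integer(probabilities > 0.5)
}

dnn_param_count <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}
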