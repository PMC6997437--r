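# Transfer learning for small datasets: pretrain the classifier on a large
# source dataset, freeze every layer except the output layer, reinitialize
# the output layer and finetune it on the target dataset. Pair-feature
# dimensions must match, which is enforced by using identical autoencoder
# bottleneck widths on both datasets.

#' Finetune only the output layer of a trained classifier
#'
#' Reinitializes the output layer (seeded) and trains it on `train` while
#' every hidden-layer parameter stays bitwise-unchanged. Uses the same
#' minibatch/early-stopping loop as [train_dnn()].
#'
#' @param model A pretrained `dnn_model`.
#' @param train A labeled `pair_dataset` with matching feature dimension.
#' @param cfg A [dnn_config()] for the finetuning run.
#' @return A `dnn_model` whose hidden layers equal the pretrained ones.
#' @export
finetune_output <- function(model, train, cfg = model$config) {
  stopifnot(inherits(model, "dnn_model"), inherits(train, "pair_dataset"))
  if (ncol(train$features) != model$input_dim) {
    stop_dtifuse("pair-feature dimension mismatch; align autoencoder bottleneck widths across datasets",
                 "dtifuse_shape_error")
  }
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop_dtifuse("finetuning data must contain both classes",
                 "dtifuse_validation_error")
  }
  acts <- dnn_acts(model$config)
  layers <- model$layers
  n_out <- length(layers)
  # frozen preprocessing: hidden layers expect the source standardization
  feats <- scale(train$features, model$center, model$scale)
  with_seed(cfg$seed, {
    layers[[n_out]] <- dense_init(nrow(layers[[n_out]]$W), 1L)
    split_idx <- stratified_split(y, cfg$val_fraction)
    xt <- feats[split_idx$train, , drop = FALSE]
    yt <- y[split_idx$train]
    xv <- train$features[split_idx$val, , drop = FALSE]
    yv <- y[split_idx$val]
    state <- NULL
    best <- list(acc = -Inf, epoch = 0L, layer = layers[[n_out]])
    history <- NULL
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(xt))
      for (idx in minibatches(nrow(xt), cfg$batch_size, ord)) {
        xb <- xt[idx, , drop = FALSE]
        yb <- yt[idx]
        fwd <- mlp_forward(layers, acts, xb, dropout_p = cfg$dropout_p,
                           training = TRUE)
        a <- fwd$a[[length(fwd$a)]][, 1]
        delta_z <- matrix((a - yb) / length(yb), ncol = 1)
        g <- list(W = crossprod(fwd$a[[n_out]], delta_z),
                  b = colSums(delta_z))
        upd <- sgd_update(layers[n_out], list(g), state, cfg$learning_rate,
                          cfg$momentum)
        layers[[n_out]] <- upd$layers[[1]]
        state <- upd$state
      }
      model_now <- structure(list(layers = layers, config = model$config,
                                  input_dim = model$input_dim,
                                  center = model$center, scale = model$scale),
                             class = "dnn_model")
      val_acc <- mean(classify(predict_proba(model_now, xv)) == yv)
      history <- rbind(history, data.frame(epoch = epoch, val_acc = val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = epoch, layer = layers[[n_out]])
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
    layers[[n_out]] <- best$layer
    structure(list(layers = layers, config = model$config,
                   input_dim = model$input_dim,
                   center = model$center, scale = model$scale,
                   history = history,
                   best_epoch = best$epoch, finetuned = TRUE),
              class = "dnn_model")
  })
}

#' Number of parameters trained during output-layer finetuning
#'
#' For the default 300/200/100 hidden architecture this is the output
#' layer's 100 weights plus 1 bias = 101.
#'
#' @param model A `dnn_model`.
#' @return Integer parameter count of the output layer.
#' @export
trainable_finetune_params <- function(model) {
  out <- model$layers[[length(model$layers)]]
  length(out$W) + length(out$b)
}

#' Pretrain on a source dataset, finetune on a target dataset
#'
#' Extracts features independently for both datasets (fresh autoencoders at
#' identical bottleneck widths), pretrains the classifier on all source
#' pairs (optionally SMOTE-balanced), then freezes the hidden layers and
#' finetunes a reinitialized output layer on all target pairs.
#'
#' @param source,target `dti_dataset` objects.
#' @param source_drug_cfg,source_target_cfg,target_drug_cfg,target_target_cfg
#'   [layer_config()]s; source and target bottleneck widths must match.
#' @param rwr_cfg,mda_cfg,dnn_cfg,smote_cfg Stage configurations;
#'   `smote_cfg = NULL` disables oversampling.
#' @param seed Seed fanning out to the pretraining and finetuning stages.
#' @return A list with the finetuned `model`, the `pretrained` model and
#'   both feature sets.
#' @export
pretrain_finetune <- function(source, target,
                              source_drug_cfg, source_target_cfg,
                              target_drug_cfg, target_target_cfg,
                              rwr_cfg = rwr_config(),
                              mda_cfg = mda_train_config(),
                              dnn_cfg = dnn_config(),
                              smote_cfg = smote_config(), seed = 1L) {
  if (source_drug_cfg$bottleneck != target_drug_cfg$bottleneck ||
      source_target_cfg$bottleneck != target_target_cfg$bottleneck) {
    stop_dtifuse("source and target bottleneck widths must match so pair-feature dimensions align",
                 "dtifuse_shape_error")
  }
  prep <- function(ds, dcfg, tcfg, stage) {
    mc <- mda_cfg
    mc$seed <- derive_seed(seed, paste0("features_", stage))
    feats <- extract_features(ds, dcfg, tcfg, rwr_cfg, mc)
    pairs <- make_pairs(feats$drugs, feats$targets, ds$interactions)
    if (!is.null(smote_cfg)) {
      sc <- smote_cfg
      sc$seed <- derive_seed(seed, paste0("smote_", stage))
      pairs <- smote(pairs, sc)
    }
    list(feats = feats, pairs = pairs)
  }
  src <- prep(source, source_drug_cfg, source_target_cfg, "source")
  tgt <- prep(target, target_drug_cfg, target_target_cfg, "target")
  pre_cfg <- dnn_cfg
  pre_cfg$seed <- derive_seed(seed, "pretrain")
  pretrained <- train_dnn(src$pairs, pre_cfg)
  fine_cfg <- dnn_cfg
  fine_cfg$seed <- derive_seed(seed, "finetune")
  model <- finetune_output(pretrained, tgt$pairs, fine_cfg)
  list(model = model, pretrained = pretrained,
       source_features = src$feats, target_features = tgt$feats)
}
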