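# Multimodal deep autoencoder (MDA): one encoder branch per similarity
# modality, a shared low-dimensional bottleneck (the feature layer), and a
# mirrored decoder with one output head per modality. Trained to jointly
# reconstruct all topological similarity matrices; the bottleneck activations
# are the fused entity features. Entities are the sample rows: drug i's input
# under modality j is row i of that modality's topological matrix.

#' Layer configuration for a multimodal autoencoder
#'
#' The encoder is: per-modality dense sigmoid layers of widths
#' `branch_widths` (possibly none), concatenation across modalities, then a
#' shared sigmoid bottleneck of width `bottleneck`. The decoder mirrors the
#' encoder, ending in per-modality sigmoid output heads of width
#' `input_dim`.
#'
#' @param n_modalities Number of input similarity views `n`.
#' @param input_dim Entities per modality `m` (each view contributes an
#'   `m`-dimensional input row per entity).
#' @param branch_widths Integer vector of per-modality encoder widths;
#'   `integer(0)` means the concatenated inputs feed the bottleneck
#'   directly.
#' @param bottleneck Width `d >= 1` of the shared feature layer.
#' @return An object of class `layer_config`.
#' @export
#' @examples
#' layer_config(3, 60, bottleneck = 50)                  # [n*m, 50, n*m]
#' layer_config(3, 60, branch_widths = 200, bottleneck = 100)
layer_config <- function(n_modalities, input_dim, branch_widths = integer(0),
                         bottleneck) {
  n_modalities <- as.integer(n_modalities)
  input_dim <- as.integer(input_dim)
  branch_widths <- as.integer(branch_widths)
  bottleneck <- as.integer(bottleneck)
  if (n_modalities < 1L || input_dim < 1L) {
    stop_dtifuse("need n_modalities >= 1 and input_dim >= 1",
                 "dtifuse_config_error")
  }
  if (length(bottleneck) != 1L || is.na(bottleneck) || bottleneck < 1L) {
    stop_dtifuse("bottleneck must be a positive integer", "dtifuse_config_error")
  }
  if (length(branch_widths) && any(is.na(branch_widths) | branch_widths < 1L)) {
    stop_dtifuse("branch widths must be positive integers",
                 "dtifuse_config_error")
  }
  structure(list(n_modalities = n_modalities, input_dim = input_dim,
                 branch_widths = branch_widths, bottleneck = bottleneck),
            class = "layer_config")
}

#' Parse a layer-configuration string
#'
#' Accepts the bracketed full form used to describe autoencoder
#' architectures, e.g. `"[n*m, n*100, n*75, 50, n*75, n*100, n*m]"`, where
#' `n*k` entries are per-modality widths and the single bare integer is the
#' shared bottleneck; the decoder must mirror the encoder. Symbolic entries
#' `n*m`, `n*n_d`, `n*n_t` denote the input/output layer and are resolved
#' from `input_dim`. A bare encoder-side form like `"n*100, 50"` is also
#' accepted.
#'
#' @param text Configuration string.
#' @param n_modalities,input_dim Dimensions the symbols refer to.
#' @return A [layer_config()].
#' @export
parse_layer_config <- function(text, n_modalities, input_dim) {
  toks <- strsplit(gsub("\\[|\\]|\\s", "", text), ",")[[1]]
  toks <- toks[nzchar(toks)]
  sym_io <- grepl("^n\\*(m|n_?[dt])$", toks)
  bare <- grepl("^[0-9]+$", toks)
  per_mod <- grepl("^n\\*[0-9]+$", toks)
  if (!all(sym_io | bare | per_mod)) {
    stop_dtifuse(sprintf("cannot parse layer config '%s'", text),
                 "dtifuse_config_error")
  }
  if (sum(bare) != 1L) {
    stop_dtifuse("layer config must contain exactly one bare integer (the bottleneck)",
                 "dtifuse_config_error")
  }
  toks <- toks[!sym_io]                       # drop input/output layers
  pos <- which(grepl("^[0-9]+$", toks))
  enc <- toks[seq_len(pos - 1L)]
  dec <- rev(toks[seq_along(toks) > pos])
  if (!identical(enc, dec) && length(dec) > 0) {
    stop_dtifuse("decoder side must mirror the encoder side",
                 "dtifuse_config_error")
  }
  widths <- as.integer(sub("^n\\*", "", enc))
  layer_config(n_modalities, input_dim, widths, as.integer(toks[pos]))
}

#' Training configuration for the multimodal autoencoder
#'
#' Defaults are 100 epochs, minibatches of 32 entity rows, learning rate
#' 0.001, plain SGD (momentum 0).
#'
#' @param epochs,batch_size,learning_rate,momentum,seed Training
#'   hyperparameters.
#' @return An object of class `mda_train_config`.
#' @export
mda_train_config <- function(epochs = 100L, batch_size = 32L,
                             learning_rate = 0.001, momentum = 0,
                             seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0,
            momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "mda_train_config")
}

#' Build a multimodal autoencoder with seeded initialization
#'
#' Weights get a uniform fan-scaled initialization; biases start at zero.
#' The same seed always yields bitwise-identical parameters.
#'
#' @param config A [layer_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `mda_model`.
#' @export
build_mda <- function(config, seed = 1L) {
  stopifnot(inherits(config, "layer_config"))
  n <- config$n_modalities
  m <- config$input_dim
  bw <- config$branch_widths
  with_seed(seed, {
    enc <- lapply(seq_len(n), function(j) {
      dims <- c(m, bw)
      lapply(seq_along(bw), function(l) dense_init(dims[l], dims[l + 1L]))
    })
    top_w <- if (length(bw)) bw[length(bw)] else m
    fus <- dense_init(n * top_w, config$bottleneck)
    dec <- lapply(seq_len(n), function(j) {
      dims <- c(config$bottleneck, rev(bw), m)
      lapply(seq_len(length(dims) - 1L), function(l)
        dense_init(dims[l], dims[l + 1L]))
    })
    structure(list(config = config, enc = enc, fus = fus, dec = dec,
                   rng_seed = as.integer(seed)),
              class = "mda_model")
  })
}

mda_check_input <- function(model, mats) {
  cfg <- model$config
  if (length(mats) != cfg$n_modalities) {
    stop_dtifuse(sprintf("model expects %d modalities, got %d",
                         cfg$n_modalities, length(mats)), "dtifuse_shape_error")
  }
  for (x in mats) {
    if (!is.matrix(x) || ncol(x) != cfg$input_dim) {
      stop_dtifuse("modality matrix columns do not match config input_dim",
                   "dtifuse_shape_error")
    }
  }
  invisible(mats)
}

topo_matrices <- function(topo) {
  if (inherits(topo, "topo_features")) topo$matrices else topo
}

# forward through branches + fusion; returns caches for backprop
mda_encode_cache <- function(model, mats) {
  acts <- rep("sigmoid", 64L)
  enc_fwd <- lapply(seq_along(mats), function(j) {
    if (length(model$enc[[j]]) == 0L) {
      list(a = list(mats[[j]]), masks = list())
    } else {
      mlp_forward(model$enc[[j]], acts, mats[[j]])
    }
  })
  tops <- lapply(enc_fwd, function(f) f$a[[length(f$a)]])
  concat <- do.call(cbind, tops)
  h <- sigmoid(dense_forward(model$fus, concat))
  list(enc_fwd = enc_fwd, concat = concat, h = h)
}

#' Encode entities into fused bottleneck features
#'
#' @param model An [build_mda()] model.
#' @param topo A `topo_features` object or a list of per-modality matrices
#'   whose rows are entities.
#' @return An `m x d` matrix of bottleneck activations in (0, 1); rows carry
#'   the entity labels when the input does.
#' @export
mda_encode <- function(model, topo) {
  mats <- mda_check_input(model, topo_matrices(topo))
  h <- mda_encode_cache(model, mats)$h
  rownames(h) <- rownames(mats[[1]])
  h
}

#' Decode bottleneck features back into per-modality reconstructions
#'
#' @param model An `mda_model`.
#' @param h An `m x d` feature matrix.
#' @return A list of `n` reconstruction matrices, entries in (0, 1).
#' @export
mda_decode <- function(model, h) {
  if (!is.matrix(h) || ncol(h) != model$config$bottleneck) {
    stop_dtifuse("feature matrix width does not match bottleneck",
                 "dtifuse_shape_error")
  }
  acts <- rep("sigmoid", 64L)
  lapply(model$dec, function(chain) {
    f <- mlp_forward(chain, acts, h)
    f$a[[length(f$a)]]
  })
}

# total loss: per modality, element-mean BCE; summed over modalities
mda_loss <- function(model, mats) {
  h <- mda_encode_cache(model, mats)$h
  rec <- mda_decode(model, h)
  sum(vapply(seq_along(mats), function(j) bce_loss(mats[[j]], rec[[j]]),
             numeric(1)))
}

# one forward+backward over a batch; returns grads for enc/fus/dec and loss
mda_batch_grads <- function(model, mats) {
  acts <- rep("sigmoid", 64L)
  n <- length(mats)
  b <- nrow(mats[[1]])
  m <- model$config$input_dim
  ec <- mda_encode_cache(model, mats)
  dec_fwd <- lapply(model$dec, function(chain) mlp_forward(chain, acts, ec$h))
  delta_h <- matrix(0, b, model$config$bottleneck)
  dec_grads <- vector("list", n)
  loss <- 0
  for (j in seq_len(n)) {
    out <- dec_fwd[[j]]$a[[length(dec_fwd[[j]]$a)]]
    loss <- loss + bce_loss(mats[[j]], out)
    delta_z <- (out - mats[[j]]) / (b * m)      # sigmoid + element-mean BCE
    bk <- mlp_backward(model$dec[[j]], acts, dec_fwd[[j]], delta_z,
                       input_grad = TRUE)
    dec_grads[[j]] <- bk$grads
    delta_h <- delta_h + bk$delta_input
  }
  delta_zf <- delta_h * ec$h * (1 - ec$h)
  fus_grad <- list(W = crossprod(ec$concat, delta_zf), b = colSums(delta_zf))
  delta_concat <- delta_zf %*% t(model$fus$W)
  enc_grads <- vector("list", n)
  top_w <- ncol(ec$concat) / n
  for (j in seq_len(n)) {
    if (length(model$enc[[j]]) == 0L) next
    cols <- ((j - 1L) * top_w + 1L):(j * top_w)
    top_a <- ec$enc_fwd[[j]]$a[[length(ec$enc_fwd[[j]]$a)]]
    delta_z <- delta_concat[, cols, drop = FALSE] * top_a * (1 - top_a)
    enc_grads[[j]] <- mlp_backward(model$enc[[j]], acts, ec$enc_fwd[[j]],
                                   delta_z)$grads
  }
  list(enc = enc_grads, fus = fus_grad, dec = dec_grads, loss = loss)
}

#' Train a multimodal autoencoder
#'
#' Minimizes the sum over modalities of the element-averaged binary
#' cross-entropy between each (min-max scaled) topological matrix and its
#' reconstruction, by minibatch SGD over entity rows. Deterministic given
#' the config seed (fixed shuffle stream).
#'
#' @param model An `mda_model`.
#' @param topo A `topo_features` object or list of matrices, each entity x
#'   feature, values in \[0, 1\].
#' @param cfg An [mda_train_config()].
#' @return The trained model, with an added `loss_trace` (full-data loss at
#'   the end of every epoch, preceded by the pre-training loss as element 1).
#' @export
train_mda <- function(model, topo, cfg = mda_train_config()) {
  mats <- mda_check_input(model, topo_matrices(topo))
  if (any(vapply(mats, function(x) any(x < 0 | x > 1), logical(1)))) {
    stop_dtifuse("autoencoder reconstruction targets must lie in [0, 1]; run topologize() with scale = TRUE",
                 "dtifuse_validation_error")
  }
  m <- nrow(mats[[1]])
  states <- list(enc = vector("list", length(mats)), fus = NULL,
                 dec = vector("list", length(mats)))
  trace <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(m)
      for (idx in minibatches(m, cfg$batch_size, ord)) {
        xb <- lapply(mats, function(x) x[idx, , drop = FALSE])
        g <- mda_batch_grads(model, xb)
        if (!is.finite(g$loss)) {
          stop_dtifuse(sprintf("autoencoder loss diverged at epoch %d", epoch),
                       "dtifuse_diverged_error")
        }
        upd <- sgd_update(list(model$fus), list(g$fus), states$fus,
                          cfg$learning_rate, cfg$momentum)
        model$fus <- upd$layers[[1]]
        states$fus <- upd$state
        for (j in seq_along(mats)) {
          if (length(model$enc[[j]])) {
            upd <- sgd_update(model$enc[[j]], g$enc[[j]],
                              states$enc[[j]], cfg$learning_rate, cfg$momentum)
            model$enc[[j]] <- upd$layers
            states$enc[[j]] <- upd$state
          }
          upd <- sgd_update(model$dec[[j]], g$dec[[j]],
                            states$dec[[j]], cfg$learning_rate, cfg$momentum)
          model$dec[[j]] <- upd$layers
          states$dec[[j]] <- upd$state
        }
      }
      trace[epoch] <- mda_loss(model, mats)
    }
  })
  model$loss_trace <- trace
  model$train_config <- cfg
  model
}

#' Extract fused low-dimensional drug and target features from a dataset
#'
#' Runs [topologize()] on both similarity sets, then trains one autoencoder
#' per entity kind and returns the bottleneck features. This stage is fully
#' unsupervised: the interaction matrix is never read.
#'
#' @param dataset A `dti_dataset`.
#' @param drug_cfg,target_cfg [layer_config()] objects for the two
#'   autoencoders (their `n_modalities`/`input_dim` must match the dataset).
#' @param rwr_cfg An [rwr_config()].
#' @param train_cfg An [mda_train_config()]; per-entity-kind seeds are
#'   derived from its seed.
#' @param scale Min-max scale topological matrices before training
#'   (required for the cross-entropy reconstruction loss).
#' @return A list with `drugs` (`n_d x d_d` feature matrix), `targets`
#'   (`n_t x d_t`), and the two trained models.
#' @export
extract_features <- function(dataset, drug_cfg, target_cfg,
                             rwr_cfg = rwr_config(),
                             train_cfg = mda_train_config(),
                             scale = TRUE) {
  stopifnot(inherits(dataset, "dti_dataset"))
  one <- function(sims, cfg, stage) {
    topo <- topologize(sims, rwr_cfg, scale = scale)
    tc <- train_cfg
    tc$seed <- derive_seed(train_cfg$seed, stage)
    model <- build_mda(cfg, seed = derive_seed(tc$seed, "init"))
    model <- train_mda(model, topo, tc)
    list(h = mda_encode(model, topo), model = model)
  }
  d <- one(dataset$drug_sims, drug_cfg, "mda_drug")
  t_ <- one(dataset$target_sims, target_cfg, "mda_target")
  list(drugs = d$h, targets = t_$h,
       drug_model = d$model, target_model = t_$model)
}
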