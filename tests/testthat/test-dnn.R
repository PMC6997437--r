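zero_dnn <- function(model) {
  model$layers <- lapply(model$layers, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  model$center[] <- 0
  model$scale[] <- 1
  model
}

test_that("pair construction concatenates entity features and reads labels", {
  set.seed(2)
  hd <- matrix(runif(4 * 3), 4, 3, dimnames = list(paste0("d", 1:4), NULL))
  ht <- matrix(runif(5 * 2), 5, 2, dimnames = list(paste0("t", 1:5), NULL))
  y <- matrix(0, 4, 5); y[2, 3] <- 1
  pd <- make_pairs(hd, ht, y)
  expect_equal(ncol(pd$features), 5)          # d_d + d_t
  expect_equal(nrow(pd$features), 20)
  i <- which(pd$pairs[, 1] == 2 & pd$pairs[, 2] == 3)
  expect_equal(pd$labels[i], 1)
  expect_equal(pd$features[i, ], c(hd[2, ], ht[3, ]), ignore_attr = TRUE)
  expect_equal(sum(pd$labels), 1)

  empty <- make_pairs(hd, ht, y, pairs = matrix(integer(0), 0, 2))
  expect_equal(nrow(empty$features), 0)
  expect_error(make_pairs(hd, ht, y, pairs = cbind(5, 1)),
               class = "dtifuse_validation_error")
})

test_that("classification threshold is strictly greater than one half", {
  expect_identical(classify(c(0.6, 0.5, 0.4)), c(1L, 0L, 0L))
})

test_that("the classifier fits linearly separable data", {
  pd <- blob_pairs(100, 10, gap = 2, seed = 1)
  m <- train_dnn(pd, dnn_config(max_epochs = 60, seed = 3))
  acc <- mean(classify(predict_proba(m, pd)) == pd$labels)
  expect_gte(acc, 0.99)
  expect_error(train_dnn(structure(list(features = pd$features,
                                        labels = rep(1, 200),
                                        pairs = pd$pairs),
                                   class = "pair_dataset")),
               class = "dtifuse_validation_error")
})

test_that("prediction is deterministic, bounded, and 0.5 for a zero-weight model", {
  pd <- blob_pairs(30, 6, seed = 4)
  m <- train_dnn(pd, dnn_config(max_epochs = 5, seed = 5))
  p1 <- predict_proba(m, pd)
  p2 <- predict_proba(m, pd)
  expect_identical(p1, p2)                   # invariant to dropout RNG
  expect_true(all(p1 > 0 & p1 < 1))
  x <- rbind(pd$features[1, ], pd$features[1, ])
  expect_equal(predict_proba(m, x)[1], predict_proba(m, x)[2])
  expect_true(all(predict_proba(zero_dnn(m), pd) == 0.5))
  expect_error(predict_proba(m, pd$features[, 1:3]),
               class = "dtifuse_shape_error")
})

test_that("zero learning rate leaves weights at their initialization", {
  pd <- blob_pairs(20, 4, seed = 6)
  cfg <- dnn_config(learning_rate = 0, max_epochs = 3, seed = 7)
  m <- train_dnn(pd, cfg)
  init <- dtifuse:::with_seed(7, {
    dtifuse:::stratified_split(pd$labels, cfg$val_fraction)
    dtifuse:::dnn_init_layers(4, cfg)
  })
  expect_equal(layer_params(m$layers), layer_params(init))
})

test_that("early stopping halts on a flat monitor and restores the best epoch", {
  pd <- blob_pairs(50, 8, gap = 3, seed = 8)
  cfg <- dnn_config(max_epochs = 200, patience = 10, seed = 9)
  m <- train_dnn(pd, cfg)
  h <- m$history
  # separable data saturates val accuracy quickly -> patience triggers
  expect_lt(nrow(h), cfg$max_epochs)
  expect_equal(nrow(h), m$best_epoch + cfg$patience)
  expect_equal(h$val_acc[m$best_epoch], max(h$val_acc))
  # no later epoch was restored: best epoch is the FIRST maximum
  expect_equal(m$best_epoch, which.max(h$val_acc))
})

test_that("momentum SGD matches the hand-computed velocity update", {
  # single parameter w0 = 1, gradients g1 = 0.5, g2 = 0.25, lr 0.1, mom 0.9
  # v1 = -0.05, w1 = 0.95; v2 = 0.9*(-0.05) - 0.025 = -0.07, w2 = 0.88
  layers <- list(list(W = matrix(1, 1, 1), b = 0))
  g1 <- list(list(W = matrix(0.5, 1, 1), b = 0))
  g2 <- list(list(W = matrix(0.25, 1, 1), b = 0))
  u1 <- dtifuse:::sgd_update(layers, g1, NULL, lr = 0.1, momentum = 0.9)
  expect_equal(u1$layers[[1]]$W[1, 1], 0.95)
  u2 <- dtifuse:::sgd_update(u1$layers, g2, u1$state, lr = 0.1, momentum = 0.9)
  expect_equal(u2$layers[[1]]$W[1, 1], 0.88)
})
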