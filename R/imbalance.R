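# SMOTE oversampling of the minority (positive) class in pair-feature
# space. Known interactions are rare relative to the full drug x target
# grid, so classifier training data is rebalanced by synthesizing minority
# points on segments between a minority row and one of its k nearest
# minority neighbors. Applied only to the training portion of a CV fold.

#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbors considered
#'   (default 5); must be smaller than the minority count.
#' @param target_ratio Desired minority/majority ratio after oversampling
#'   (default 1: balanced classes).
#' @param seed RNG seed.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, target_ratio = 1.0, seed = 1L) {
  stopifnot(k_neighbors >= 1, target_ratio > 0)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "smote_config")
}

#' Oversample the minority class of a pair dataset
#'
#' Appends synthetic minority rows `x_new = x_i + u * (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` drawn among the `k` nearest (Euclidean)
#' minority neighbors of `x_i`, until minority count equals
#' `target_ratio * majority count`. Original rows are unchanged; no
#' majority row is ever created or modified. Deterministic per seed.
#'
#' @param train A labeled [make_pairs()] dataset with both classes present.
#' @param cfg A [smote_config()].
#' @return A `pair_dataset` with appended synthetic rows and a logical
#'   `synthetic` field marking them.
#' @export
smote <- function(train, cfg = smote_config()) {
  stopifnot(inherits(train, "pair_dataset"), !is.null(train$labels))
  y <- train$labels
  counts <- table(y)
  if (length(counts) < 2L) {
    stop_dtifuse("both classes must be present for oversampling",
                 "dtifuse_validation_error")
  }
  minority <- as.numeric(names(counts)[which.min(counts)])
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min <= cfg$k_neighbors) {
    stop_dtifuse(sprintf(
      "minority count (%d) must exceed k_neighbors (%d); lower k_neighbors",
      n_min, cfg$k_neighbors), "dtifuse_validation_error")
  }
  n_syn <- round(cfg$target_ratio * n_maj) - n_min
  out <- train
  out$synthetic <- rep(FALSE, length(y))
  if (n_syn <= 0) return(out)
  min_idx <- which(y == minority)
  xm <- train$features[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(cfg$k_neighbors)]))
  with_seed(cfg$seed, {
    base <- rep_len(sample.int(n_min), n_syn)   # cycle a shuffled base order
    pick <- sample.int(cfg$k_neighbors, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    new_rows <- xm[base, , drop = FALSE] +
      u * (xm[nn[cbind(base, pick)], , drop = FALSE] - xm[base, , drop = FALSE])
  })
  out$features <- rbind(train$features, new_rows)
  out$labels <- c(y, rep(minority, n_syn))
  out$pairs <- rbind(train$pairs, train$pairs[min_idx[base], , drop = FALSE])
  out$synthetic <- c(rep(FALSE, length(y)), rep(TRUE, n_syn))
  out
}
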