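# Topological similarity: each similarity view is turned into a
# topology-aware matrix by accumulating random-walk-with-restart step
# distributions and applying positive pointwise mutual information. This is
# what lets downstream feature learning see the global structure of each
# similarity network rather than isolated pairwise scores.

#' Random walk with restart configuration
#'
#' @param alpha Walk-continuation weight in \[0, 1\]: each step mixes
#'   `alpha` times the walk term with `1 - alpha` times the restart (one-hot)
#'   distribution. Default 0.95: on dense weighted similarity networks a
#'   low walk weight concentrates so much accumulated mass on the start
#'   node that off-diagonal visit rates fall below their independence
#'   margins and the subsequent PPMI step clips nearly all of them to zero.
#' @param steps Total number of walk steps `T >= 1` whose distributions are
#'   accumulated. Default 10.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(alpha = 0.95, steps = 10L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_dtifuse("alpha must be a single value in [0, 1]", "dtifuse_config_error")
  }
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) {
    stop_dtifuse("steps must be an integer >= 1", "dtifuse_config_error")
  }
  structure(list(alpha = alpha, steps = steps), class = "rwr_config")
}

#' Row-normalize a similarity matrix into a transition matrix
#'
#' Divides each row by its sum so rows are probability distributions. A row
#' of all zeros (an isolated node) becomes a self-loop: probability 1 on the
#' diagonal.
#'
#' @param view A [similarity_view()] or a plain nonnegative square matrix.
#' @return A row-stochastic matrix.
#' @export
row_normalize <- function(view) {
  m <- if (inherits(view, "similarity_view")) view$values else view
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    m[zero, ] <- 0
    m[cbind(which(zero), which(zero))] <- 1
    rs[zero] <- 1
  }
  m / rs
}

#' Accumulated random-walk-with-restart features
#'
#' For each node `i`, iterates
#' `p_i(t) = alpha * p_i(t-1) %*% S + (1 - alpha) * p_i(0)` from the one-hot
#' start vector `p_i(0)`, where `S` is the row-normalized transition matrix,
#' and returns the accumulated matrix whose row `i` is
#' `sum_{t=1..T} p_i(t)`. Every intermediate `p_i(t)` is a probability
#' vector, so each row of the result sums to `T`.
#'
#' All start nodes are propagated simultaneously: the recurrence in matrix
#' form is `P(t) = alpha * P(t-1) %*% S + (1 - alpha) * I` with `P(0) = I`.
#'
#' @param view A [similarity_view()] or nonnegative square matrix.
#' @param cfg An [rwr_config()].
#' @return An `m x m` matrix of accumulated visit probabilities.
#' @export
#' @examples
#' v <- similarity_view(matrix(c(0, 1, 1, 0), 2,
#'                             dimnames = list(c("a", "b"), c("a", "b"))))
#' rwr_features(v, rwr_config(alpha = 0.5, steps = 2))  # rows sum to 2
rwr_features <- function(view, cfg = rwr_config()) {
  if (!inherits(cfg, "rwr_config")) {
    stop_dtifuse("cfg must be an rwr_config", "dtifuse_config_error")
  }
  s <- row_normalize(view)
  m <- nrow(s)
  eye <- diag(m)
  p <- eye
  acc <- matrix(0, m, m)
  for (t in seq_len(cfg$steps)) {
    p <- cfg$alpha * (p %*% s) + (1 - cfg$alpha) * eye
    acc <- acc + p
  }
  dimnames(acc) <- dimnames(s)
  acc
}

#' Positive pointwise mutual information of a co-occurrence matrix
#'
#' Treats `P` as joint co-occurrence weights and computes
#' `X[i, k] = max(0, log2( P[i, k] * sum(P) / (rowSums(P)[i] * colSums(P)[k]) ))`,
#' with entries where `P[i, k] == 0` mapped to 0 (no `-Inf` is ever
#' computed). A rank-1 `P` (statistically independent margins) yields the
#' zero matrix.
#'
#' @param p Nonnegative matrix with at least one strictly positive entry.
#' @return A nonnegative, finite matrix of the same shape.
#' @export
ppmi <- function(p) {
  stopifnot(is.matrix(p), is.numeric(p))
  if (any(p < 0) || any(!is.finite(p))) {
    stop_dtifuse("ppmi input must be nonnegative and finite",
                 "dtifuse_validation_error")
  }
  total <- sum(p)
  if (total == 0) {
    stop_dtifuse("ppmi input is all zero (degenerate)", "dtifuse_degenerate_error")
  }
  rs <- rowSums(p)
  cs <- colSums(p)
  denom <- outer(rs, cs)
  x <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  pos <- p > 0                     # pos entries imply denom > 0
  x[pos] <- pmax(0, log2(p[pos] * total / denom[pos]))
  x
}

#' Per-view topological similarity for a whole similarity set
#'
#' Applies [row_normalize()], [rwr_features()] and [ppmi()] independently to
#' every view of the set. If `scale` is `TRUE` (the default), each resulting
#' matrix is min-max scaled to \[0, 1\] so it can serve as the target of a
#' sigmoid/cross-entropy reconstruction during feature learning.
#'
#' @param sims A [similarity_set()].
#' @param cfg An [rwr_config()].
#' @param scale Logical; min-max scale each topological matrix to \[0, 1\].
#' @return An object of class `topo_features`: fields `entity_kind`,
#'   `labels`, `matrices` (named list, one per view, in view order) and
#'   `scaled`.
#' @export
topologize <- function(sims, cfg = rwr_config(), scale = TRUE) {
  stopifnot(inherits(sims, "similarity_set"))
  mats <- lapply(sims$views, function(v) {
    x <- ppmi(rwr_features(v, cfg))
    if (scale) x <- minmax_scale(x)
    x
  })
  structure(list(entity_kind = sims$entity_kind, labels = sims$labels,
                 matrices = mats, scaled = scale, rwr = cfg),
            class = "topo_features")
}
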