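# Shared fixtures and independent oracles used across the suite.

# random valid similarity view on n nodes
random_view <- function(n, name = "v", symmetric = TRUE) {
  m <- matrix(stats::runif(n * n), n, n)
  if (symmetric) m <- (m + t(m)) / 2
  diag(m) <- 1
  suppressWarnings(  # asymmetric views are intentional fixtures here
    similarity_view(m, labels = paste0("e", seq_len(n)), name = name))
}

# Independent RWR oracle: per-node iteration of the recurrence
# p(t) = alpha * p(t-1) %*% S + (1 - alpha) * p(0), accumulated over t,
# written with explicit matrix powers (closed form):
# p = (1-alpha) * sum_{t=1..T} sum_{k=0..t-1} alpha^k p0 S^k
#     + sum_{t=1..T} alpha^t p0 S^t
rwr_oracle <- function(view, alpha, steps) {
  s <- row_normalize(view)
  n <- nrow(s)
  pows <- vector("list", steps + 1L)
  pows[[1]] <- diag(n)
  for (k in seq_len(steps)) pows[[k + 1L]] <- pows[[k]] %*% s
  acc <- matrix(0, n, n)
  for (t in seq_len(steps)) {
    for (k in 0:(t - 1L)) acc <- acc + (1 - alpha) * alpha^k * pows[[k + 1L]]
    acc <- acc + alpha^t * pows[[t + 1L]]
  }
  dimnames(acc) <- dimnames(s)
  acc
}

# Brute-force AUC over all positive-negative pairs, ties counting 1/2
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep AUPR oracle: step curve from the highest
# threshold down, recall increments times precision at that threshold
aupr_oracle <- function(labels, scores) {
  n1 <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  rec_prev <- 0
  for (s in thr) {
    pred <- scores >= s
    tp <- sum(labels == 1 & pred)
    prec <- tp / sum(pred)
    rec <- tp / n1
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

# small planted-cluster dataset used by fast end-to-end-ish tests
small_synth <- function(seed = 7L) {
  generate_dataset(synth_config(n_drugs = 24L, n_targets = 18L,
                                k_drug_clusters = 2L, k_target_clusters = 2L,
                                n_drug_views = 2L, n_target_views = 2L,
                                matched_rate = 0.7, background_rate = 0.05,
                                seed = seed))
}

# linearly separable two-blob pair dataset for classifier tests
blob_pairs <- function(n_per_class = 100L, dim = 10L, gap = 2, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * dim, gap / 2), n_per_class),
             matrix(stats::rnorm(n_per_class * dim, -gap / 2), n_per_class))
  y <- rep(c(1, 0), each = n_per_class)
  structure(list(pairs = cbind(drug = seq_along(y), target = seq_along(y)),
                 features = x, labels = y),
            class = "pair_dataset")
}

# flatten all numeric parameters of a layer list for hashing/comparison
layer_params <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$W), as.numeric(l$b))))
}
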