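# Seeded generator of desk-scale datasets with the statistical structure the
# method assumes: several noisy similarity views of a shared cluster
# structure per entity kind, and interactions concentrated between matched
# drug/target clusters ("similar drugs tend to share similar targets"),
# with realistic class imbalance built in.

#' Synthetic dataset configuration
#'
#' Defaults describe the generator's reference condition: 60 drugs and 40
#' targets in 3 clusters each, 3 similarity views per entity kind, mean
#' within-cluster similarity 0.8 vs 0.2 between clusters, per-view Gaussian
#' noise (sd 0.05) and independently jittered base levels, interaction
#' probability 0.6 between matched clusters and 0.02 elsewhere (so
#' positives are rare and the oversampling path is exercised by default).
#'
#' @param n_drugs,n_targets Entity counts.
#' @param k_drug_clusters,k_target_clusters Cluster counts; interactions are
#'   planted between drug cluster `g` and target cluster `g` (clusters
#'   matched by index, recycled if counts differ).
#' @param n_drug_views,n_target_views Similarity views per entity kind.
#' @param within_sim,between_sim Mean similarity for same-/different-cluster
#'   pairs; must satisfy `within_sim > between_sim` unless equal (the null
#'   configuration used to check the generator itself).
#' @param view_noise_sd Gaussian noise sd added per view entry.
#' @param base_jitter Half-width of the uniform per-view jitter applied to
#'   both base levels, giving views complementary information.
#' @param matched_rate,background_rate Interaction probabilities for
#'   matched-cluster and all other pairs.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 60L, n_targets = 40L,
                         k_drug_clusters = 3L, k_target_clusters = 3L,
                         n_drug_views = 3L, n_target_views = 3L,
                         within_sim = 0.8, between_sim = 0.2,
                         view_noise_sd = 0.05, base_jitter = 0.05,
                         matched_rate = 0.6, background_rate = 0.02,
                         seed = 1L) {
  if (within_sim < between_sim) {
    stop_dtifuse("within_sim must be >= between_sim", "dtifuse_config_error")
  }
  probs <- c(within_sim, between_sim, matched_rate, background_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_dtifuse("similarities and rates must lie in [0, 1]",
                 "dtifuse_config_error")
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 k_drug_clusters = as.integer(k_drug_clusters),
                 k_target_clusters = as.integer(k_target_clusters),
                 n_drug_views = as.integer(n_drug_views),
                 n_target_views = as.integer(n_target_views),
                 within_sim = within_sim, between_sim = between_sim,
                 view_noise_sd = view_noise_sd, base_jitter = base_jitter,
                 matched_rate = matched_rate,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic drug-target dataset
#'
#' Entities are assigned to clusters uniformly at random. Each similarity
#' view entry is `clamp_[0,1](base + noise)` where `base` is the (per-view
#' jittered) within- or between-cluster level; views are symmetrized and
#' given a unit diagonal. Interactions are Bernoulli draws at the
#' matched-cluster rate or the background rate. Deterministic per seed.
#'
#' @param cfg A [synth_config()].
#' @return A `dti_dataset` carrying attributes `drug_clusters` and
#'   `target_clusters` (the ground-truth assignments).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    dlab <- sprintf("d%03d", seq_len(cfg$n_drugs))
    tlab <- sprintf("t%03d", seq_len(cfg$n_targets))
    dcl <- sample.int(cfg$k_drug_clusters, cfg$n_drugs, replace = TRUE)
    tcl <- sample.int(cfg$k_target_clusters, cfg$n_targets, replace = TRUE)
    make_views <- function(cl, labels, n_views, kind) {
      same <- outer(cl, cl, `==`)
      lapply(seq_len(n_views), function(v) {
        jw <- cfg$within_sim + stats::runif(1, -cfg$base_jitter, cfg$base_jitter)
        jb <- cfg$between_sim + stats::runif(1, -cfg$base_jitter, cfg$base_jitter)
        base <- ifelse(same, jw, jb)
        m <- base + matrix(stats::rnorm(length(base), 0, cfg$view_noise_sd),
                           nrow(base))
        m <- (m + t(m)) / 2
        diag(m) <- 1
        m <- pmin(pmax(m, 0), 1)
        dimnames(m) <- list(labels, labels)
        similarity_view(m, labels, name = sprintf("%s_view%d", kind, v))
      })
    }
    dviews <- make_views(dcl, dlab, cfg$n_drug_views, "drug")
    tviews <- make_views(tcl, tlab, cfg$n_target_views, "target")
    k <- max(cfg$k_drug_clusters, cfg$k_target_clusters)
    matched <- outer((dcl - 1L) %% k, (tcl - 1L) %% k, `==`)
    p <- ifelse(matched, cfg$matched_rate, cfg$background_rate)
    y <- matrix(stats::rbinom(length(p), 1, p), nrow(p),
                dimnames = list(dlab, tlab))
    ds <- assemble_dataset(similarity_set(dviews, "drug"),
                           similarity_set(tviews, "target"),
                           suppressWarnings(interaction_matrix(y)))
    attr(ds, "drug_clusters") <- dcl
    attr(ds, "target_clusters") <- tcl
    attr(ds, "interaction_prob") <- p
    ds
  })
}
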