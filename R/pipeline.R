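# End-to-end orchestration: a single YAML config drives data loading or
# synthesis, topological featurization, autoencoder feature learning,
# classifier training with optional SMOTE, cross-validated evaluation
# and/or ranking of unknown pairs. One run seed fans out to per-stage
# derived seeds; the written manifest captures every effective parameter so
# a rerun reproduces all outputs bit for bit.

check_keys <- function(cfg, allowed, section) {
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    stop_dtifuse(sprintf("unknown config key(s) in %s: %s", section,
                         paste(extra, collapse = ", ")),
                 "dtifuse_config_error")
  }
  cfg
}

resolve_layer_cfg <- function(spec, n_modalities, input_dim) {
  if (is.character(spec)) {
    parse_layer_config(spec, n_modalities, input_dim)
  } else if (is.list(spec)) {
    check_keys(spec, c("branch_widths", "bottleneck"), "layer config")
    layer_config(n_modalities, input_dim,
                 as.integer(unlist(spec$branch_widths %||% integer(0))),
                 spec$bottleneck)
  } else {
    stop_dtifuse("layer config must be a string or a mapping",
                 "dtifuse_config_error")
  }
}

#' Run the full prediction pipeline from a config file
#'
#' The config (YAML file path or an equivalent named list) has sections
#' `data` (either `synthetic:` generator parameters or `manifest:` path to
#' a dataset manifest), `rwr`, `mda` (with `drug_config` / `target_config`
#' architectures plus training hyperparameters), `dnn`, `smote`,
#' `evaluate` (`setting`, `folds`, `repeats`) and/or `rank` (`top_n`),
#' plus a top-level `seed` and optional `output_dir`. Unknown keys are
#' errors. Stages present in the config are executed in order: featurize,
#' evaluate, rank.
#'
#' Outputs written to the results directory: `manifest.yaml` (every
#' effective parameter and derived seed), `features_drugs.tsv`,
#' `features_targets.tsv`, `cv_repeats.tsv` (per-repeat rows plus a final
#' mean row), `cv_folds.tsv`, and `ranking.tsv`.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Overrides the config's `output_dir`.
#' @return Invisibly, a list with the loaded `dataset`, `features`,
#'   `cv` result (if evaluated), `ranking` (if ranked) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  check_keys(cfg, c("seed", "output_dir", "data", "rwr", "mda", "dnn",
                    "smote", "evaluate", "rank"), "top level")
  if (is.null(cfg$data)) {
    stop_dtifuse("config needs a 'data' section", "dtifuse_config_error")
  }
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$output_dir %||% stop_dtifuse(
    "no output directory given", "dtifuse_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- data ------------------------------------------------------------
  check_keys(cfg$data, c("synthetic", "manifest"), "data")
  if (!is.null(cfg$data$synthetic)) {
    sc_args <- check_keys(cfg$data$synthetic,
                          setdiff(names(formals(synth_config)), "seed"),
                          "data.synthetic")
    sc <- do.call(synth_config, c(sc_args, list(seed = derive_seed(seed, "synth"))))
    dataset <- generate_dataset(sc)
  } else {
    sc <- NULL
    dataset <- read_dataset_manifest(cfg$data$manifest)
  }
  n_d <- length(dataset$drug_sims$labels)
  n_t <- length(dataset$target_sims$labels)

  # --- stage configs ---------------------------------------------------
  rwr_args <- check_keys(cfg$rwr %||% list(), c("alpha", "steps"), "rwr")
  rcfg <- do.call(rwr_config, rwr_args)

  mda_sec <- check_keys(cfg$mda %||% list(),
                        c("drug_config", "target_config", "epochs",
                          "batch_size", "learning_rate", "momentum"), "mda")
  drug_cfg <- resolve_layer_cfg(mda_sec$drug_config %||% list(bottleneck = 50L),
                                length(dataset$drug_sims$views), n_d)
  target_cfg <- resolve_layer_cfg(mda_sec$target_config %||% list(bottleneck = 25L),
                                  length(dataset$target_sims$views), n_t)
  mda_args <- mda_sec[intersect(names(mda_sec),
                                c("epochs", "batch_size", "learning_rate",
                                  "momentum"))]
  mcfg <- do.call(mda_train_config,
                  c(mda_args, list(seed = derive_seed(seed, "mda"))))

  dnn_args <- check_keys(cfg$dnn %||% list(),
                         c("hidden_widths", "dropout_p", "learning_rate",
                           "momentum", "max_epochs", "patience",
                           "val_fraction", "batch_size"), "dnn")
  if (!is.null(dnn_args$hidden_widths)) {
    dnn_args$hidden_widths <- as.integer(unlist(dnn_args$hidden_widths))
  }
  dcfg <- do.call(dnn_config,
                  c(dnn_args, list(seed = derive_seed(seed, "dnn"))))

  smote_sec <- check_keys(cfg$smote %||% list(),
                          c("enabled", "k_neighbors", "target_ratio"), "smote")
  smote_on <- smote_sec$enabled %||% TRUE
  scfg <- if (smote_on) {
    do.call(smote_config,
            c(smote_sec[intersect(names(smote_sec),
                                  c("k_neighbors", "target_ratio"))],
              list(seed = derive_seed(seed, "smote"))))
  } else NULL

  # --- features --------------------------------------------------------
  features <- extract_features(dataset, drug_cfg, target_cfg, rcfg, mcfg)
  write_labelled_matrix(features$drugs, file.path(out_dir, "features_drugs.tsv"))
  write_labelled_matrix(features$targets, file.path(out_dir, "features_targets.tsv"))

  result <- list(dataset = dataset, features = features, out_dir = out_dir)

  # --- evaluate --------------------------------------------------------
  if (!is.null(cfg$evaluate)) {
    ev <- check_keys(cfg$evaluate, c("setting", "folds", "repeats"), "evaluate")
    plan <- make_cv_plan(dataset, ev$setting %||% "CVS1",
                         n_folds = ev$folds %||% 10L,
                         n_repeats = ev$repeats %||% 5L,
                         seed = derive_seed(seed, "cv"))
    cv <- run_cv(dataset, plan, drug_cfg, target_cfg, rcfg, mcfg, dcfg, scfg,
                 features = features)
    reps <- cv$per_repeat
    reps$repeat_i <- as.character(reps$repeat_i)
    reps <- rbind(reps, data.frame(repeat_i = "final",
                                   auc = cv$mean_auc, aupr = cv$mean_aupr))
    utils::write.table(reps, file.path(out_dir, "cv_repeats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cv$per_fold, file.path(out_dir, "cv_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$cv <- cv
    result$plan <- plan
  }

  # --- rank ------------------------------------------------------------
  if (!is.null(cfg$rank)) {
    rk <- check_keys(cfg$rank, "top_n", "rank")
    full <- make_pairs(features$drugs, features$targets, dataset$interactions)
    if (!is.null(scfg)) {
      sc2 <- scfg
      sc2$seed <- derive_seed(seed, "smote_rank")
      full <- smote(full, sc2)
    }
    rank_dcfg <- dcfg
    rank_dcfg$seed <- derive_seed(seed, "dnn_rank")
    full_model <- train_dnn(full, rank_dcfg)
    ranking <- rank_unknown(full_model, features$drugs, features$targets,
                            dataset$interactions, rk$top_n %||% 100L)
    utils::write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    result$ranking <- ranking
    result$full_model <- full_model
  }

  # --- manifest: every effective parameter and derived seed ------------
  manifest <- list(
    seed = seed,
    data = if (is.null(sc)) list(manifest = cfg$data$manifest)
           else list(synthetic = unclass(sc)),
    rwr = unclass(rcfg),
    mda = list(drug_config = unclass(drug_cfg),
               target_config = unclass(target_cfg),
               train = unclass(mcfg)),
    dnn = unclass(dcfg),
    smote = if (is.null(scfg)) list(enabled = FALSE)
            else c(list(enabled = TRUE), unclass(scfg)),
    evaluate = if (!is.null(cfg$evaluate))
      list(setting = result$plan$setting, folds = result$plan$n_folds,
           repeats = result$plan$n_repeats, seed = result$plan$seed),
    rank = cfg$rank)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(result)
}
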