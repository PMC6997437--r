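# Prediction of unknown interactions: score every y = 0 pair with a trained
# classifier and return the top-N list in descending probability order.

#' Rank unknown drug-target pairs by predicted probability
#'
#' Only pairs with `y == 0` (unknown interactions) are scored; known
#' positives never appear in the output. Ties are broken by (drug label,
#' target label) lexicographic order, so the ranking is a deterministic
#' function of the model and dataset.
#'
#' @param model A trained `dnn_model` (conventionally trained on all known
#'   data, with no fold held out).
#' @param h_d,h_t Drug and target feature matrices (rows labeled).
#' @param y Binary interaction matrix or [interaction_matrix()].
#' @param top_n Maximum number of rows to return.
#' @return A data frame with columns `rank`, `drug`, `target`,
#'   `probability`, at most `min(top_n, number of unknown pairs)` rows.
#' @export
rank_unknown <- function(model, h_d, h_t, y, top_n = 100L) {
  stopifnot(top_n >= 1)
  if (inherits(y, "interaction_matrix")) y <- y$y
  unknown <- which(y == 0, arr.ind = TRUE)
  if (nrow(unknown) == 0L) {
    warning("no unknown pairs to rank")
    return(data.frame(rank = integer(), drug = character(),
                      target = character(), probability = numeric()))
  }
  pairs <- make_pairs(h_d, h_t, pairs = unknown)
  prob <- predict_proba(model, pairs)
  dl <- rownames(h_d) %||% as.character(seq_len(nrow(h_d)))
  tl <- rownames(h_t) %||% as.character(seq_len(nrow(h_t)))
  drug <- dl[unknown[, 1]]
  target <- tl[unknown[, 2]]
  ord <- order(-prob, drug, target, method = "radix")
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(keep), drug = drug[keep],
             target = target[keep], probability = prob[keep])
}
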