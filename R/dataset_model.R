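# Core data types for DTI prediction: similarity views and sets, the binary
# interaction matrix, and the assembled dataset. Similarity matrices arrive
# precomputed (chemical fingerprints, sequence kernels, GO similarity, ...);
# this package consumes them, it does not compute them.

#' Construct a single similarity view
#'
#' A similarity view is one modality's square entity-by-entity similarity
#' matrix (e.g. Tanimoto similarity over chemical fingerprints for drugs, or
#' a Smith-Waterman score matrix for targets), with all entries in \[0, 1\].
#'
#' Matrices are not required to be symmetric nor to have a unit diagonal;
#' asymmetry only triggers a warning. Entries outside \[0, 1\] by at most
#' `1e-9` are clamped (floating-point dirt); larger violations are errors.
#'
#' @param values Numeric square matrix with entries in \[0, 1\].
#' @param labels Character vector of unique entity identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param name Modality identifier (a single string).
#' @return An object of class `similarity_view` with fields `name`, `labels`
#'   and `values`.
#' @export
#' @examples
#' v <- similarity_view(matrix(c(1, .3, .3, 1), 2,
#'                             dimnames = list(c("d1", "d2"), c("d1", "d2"))),
#'                      name = "chem")
similarity_view <- function(values, labels = rownames(values), name = "view") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_dtifuse("similarity view must be a numeric matrix", "dtifuse_format_error")
  }
  if (nrow(values) != ncol(values)) {
    stop_dtifuse(sprintf("similarity view '%s' is not square (%d x %d)",
                         name, nrow(values), ncol(values)),
                 "dtifuse_format_error")
  }
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop_dtifuse("label length does not match matrix dimension",
                 "dtifuse_validation_error")
  }
  if (anyDuplicated(labels)) {
    stop_dtifuse(sprintf("duplicate entity labels in view '%s'", name),
                 "dtifuse_validation_error")
  }
  if (any(!is.finite(values))) {
    stop_dtifuse(sprintf("non-finite entries in view '%s'", name),
                 "dtifuse_validation_error")
  }
  tol <- 1e-9
  if (any(values < -tol) || any(values > 1 + tol)) {
    stop_dtifuse(sprintf("entries of view '%s' outside [0, 1]", name),
                 "dtifuse_validation_error")
  }
  values <- pmin(pmax(values, 0), 1)   # clamp <=1e-9 overshoot
  dimnames(values) <- list(labels, labels)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    warning(sprintf("similarity view '%s' is asymmetric", name))
  }
  structure(list(name = name, labels = labels, values = values),
            class = "similarity_view")
}

#' Construct a set of similarity views for one entity kind
#'
#' @param views List of [similarity_view()] objects sharing one label
#'   ordering.
#' @param entity_kind Either `"drug"` or `"target"`.
#' @return An object of class `similarity_set`.
#' @export
similarity_set <- function(views, entity_kind = c("drug", "target")) {
  entity_kind <- match.arg(entity_kind)
  if (length(views) < 1L) {
    stop_dtifuse("a similarity set needs at least one view",
                 "dtifuse_validation_error")
  }
  stopifnot(all(vapply(views, inherits, logical(1), "similarity_view")))
  labels <- views[[1]]$labels
  for (v in views) {
    if (!identical(v$labels, labels)) {
      stop_dtifuse(sprintf("view '%s' labels disagree with view '%s'",
                           v$name, views[[1]]$name),
                   "dtifuse_assembly_error")
    }
  }
  names(views) <- vapply(views, `[[`, character(1), "name")
  structure(list(entity_kind = entity_kind, labels = labels, views = views),
            class = "similarity_set")
}

#' Construct a binary drug-target interaction matrix
#'
#' @param y Numeric matrix with entries in \{0, 1\}; rows are drugs, columns
#'   are targets.
#' @param drug_labels,target_labels Character identifiers; default to the
#'   dimnames of `y`.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(y, drug_labels = rownames(y),
                               target_labels = colnames(y)) {
  if (!is.matrix(y) || !is.numeric(y)) {
    stop_dtifuse("interactions must be a numeric matrix", "dtifuse_format_error")
  }
  if (!all(y %in% c(0, 1))) {
    stop_dtifuse("interaction entries must be 0 or 1",
                 "dtifuse_validation_error")
  }
  if (is.null(drug_labels)) drug_labels <- paste0("d", seq_len(nrow(y)))
  if (is.null(target_labels)) target_labels <- paste0("t", seq_len(ncol(y)))
  drug_labels <- as.character(drug_labels)
  target_labels <- as.character(target_labels)
  if (anyDuplicated(drug_labels) || anyDuplicated(target_labels)) {
    stop_dtifuse("duplicate labels in interaction matrix",
                 "dtifuse_validation_error")
  }
  storage.mode(y) <- "double"
  dimnames(y) <- list(drug_labels, target_labels)
  if (sum(y) == 0) warning("interaction matrix has no positive entries")
  structure(list(drug_labels = drug_labels, target_labels = target_labels,
                 y = y),
            class = "interaction_matrix")
}

#' Assemble a full dataset
#'
#' Checks label consistency between the drug similarity set, target
#' similarity set and interaction matrix (exact string equality, exact
#' order).
#'
#' @param drug_sims,target_sims [similarity_set()] objects.
#' @param interactions An [interaction_matrix()].
#' @return An object of class `dti_dataset`.
#' @export
assemble_dataset <- function(drug_sims, target_sims, interactions) {
  stopifnot(inherits(drug_sims, "similarity_set"),
            inherits(target_sims, "similarity_set"),
            inherits(interactions, "interaction_matrix"))
  if (drug_sims$entity_kind != "drug" || target_sims$entity_kind != "target") {
    stop_dtifuse("similarity sets must be of kind drug and target",
                 "dtifuse_assembly_error")
  }
  if (!identical(drug_sims$labels, interactions$drug_labels)) {
    stop_dtifuse("drug labels of similarity views and interaction rows disagree",
                 "dtifuse_assembly_error")
  }
  if (!identical(target_sims$labels, interactions$target_labels)) {
    stop_dtifuse("target labels of similarity views and interaction columns disagree",
                 "dtifuse_assembly_error")
  }
  structure(list(drug_sims = drug_sims, target_sims = target_sims,
                 interactions = interactions),
            class = "dti_dataset")
}

#' @export
print.dti_dataset <- function(x, ...) {
  y <- x$interactions$y
  cat(sprintf(paste0("<dti_dataset> %d drugs x %d targets, %d drug views, ",
                     "%d target views, %d positives (%.3f)\n"),
              nrow(y), ncol(y), length(x$drug_sims$views),
              length(x$target_sims$views), sum(y), mean(y)))
  invisible(x)
}

# --- delimited text I/O ------------------------------------------------------

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_labelled_matrix <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a similarity view from a delimited text file
#'
#' Expects a header row of column labels and a first column of row labels;
#' tab-separated by default, comma accepted (sniffed from the first line).
#'
#' @param path File path.
#' @param name Modality identifier for the view.
#' @return A [similarity_view()].
#' @export
read_similarity_view <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  m <- read_labelled_matrix(path)
  similarity_view(m, labels = rownames(m), name = name)
}

#' Write a similarity view as tab-separated text
#'
#' @param view A [similarity_view()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_view <- function(view, path) {
  write_labelled_matrix(view$values, path)
}

write_labelled_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a binary interaction matrix from a delimited text file
#'
#' @param path File path (header row = target labels, first column = drug
#'   labels, body of 0/1).
#' @return An [interaction_matrix()].
#' @export
read_interactions <- function(path) {
  m <- read_labelled_matrix(path)
  interaction_matrix(m)
}

#' Write an interaction matrix as tab-separated text
#' @param interactions An [interaction_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  write_labelled_matrix(interactions$y, path)
}

#' Read a dataset from a manifest file
#'
#' The manifest is YAML with keys `drugs` and `targets` (each a mapping of
#' modality name to file path) and `interactions` (one file path). Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A [assemble_dataset()] result.
#' @export
read_dataset_manifest <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  need <- c("drugs", "targets", "interactions")
  if (!all(need %in% names(cfg))) {
    stop_dtifuse("manifest needs keys: drugs, targets, interactions",
                 "dtifuse_format_error")
  }
  dviews <- lapply(names(cfg$drugs), function(nm)
    read_similarity_view(resolve(cfg$drugs[[nm]]), name = nm))
  tviews <- lapply(names(cfg$targets), function(nm)
    read_similarity_view(resolve(cfg$targets[[nm]]), name = nm))
  assemble_dataset(similarity_set(dviews, "drug"),
                   similarity_set(tviews, "target"),
                   read_interactions(resolve(cfg$interactions)))
}

#' Write a dataset as TSV files plus a manifest
#'
#' @param dataset A `dti_dataset`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(drugs = list(), targets = list(), interactions = "interactions.tsv")
  for (v in dataset$drug_sims$views) {
    f <- paste0("drug_", v$name, ".tsv")
    write_similarity_view(v, file.path(dir, f))
    cfg$drugs[[v$name]] <- f
  }
  for (v in dataset$target_sims$views) {
    f <- paste0("target_", v$name, ".tsv")
    write_similarity_view(v, file.path(dir, f))
    cfg$targets[[v$name]] <- f
  }
  write_interactions(dataset$interactions, file.path(dir, "interactions.tsv"))
  manifest <- file.path(dir, "dataset.yaml")
  yaml::write_yaml(cfg, manifest)
  invisible(manifest)
}
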