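test_that("similarity views validate shape, bounds and labels", {
  m <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("d1", "d2"), c("d1", "d2")))
  v <- similarity_view(m, name = "chem")
  expect_identical(v$labels, c("d1", "d2"))
  expect_equal(v$values, m)

  expect_error(similarity_view(matrix(0.5, 2, 3)), class = "dtifuse_format_error")
  bad <- m; bad[1, 2] <- 1.5
  expect_error(similarity_view(bad), class = "dtifuse_validation_error")
  dup <- m; dimnames(dup) <- list(c("d1", "d1"), c("d1", "d1"))
  expect_error(similarity_view(dup), class = "dtifuse_validation_error")

  # <=1e-9 overshoot is clamped, not rejected
  dirty <- m; dirty[1, 1] <- 1 + 1e-10; dirty[2, 1] <- 0.3 + 1e-10
  expect_equal(similarity_view(dirty)$values[1, 1], 1)
})

test_that("similarity view and interaction matrix round-trip through TSV", {
  withr_dir <- tempfile(); dir.create(withr_dir)
  set.seed(3)
  v <- random_view(5, name = "m1")
  p <- file.path(withr_dir, "v.tsv")
  write_similarity_view(v, p)
  v2 <- read_similarity_view(p, name = "m1")
  expect_identical(v2$labels, v$labels)
  expect_lt(max(abs(v2$values - v$values)), 1e-12)

  y <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2,
              dimnames = list(paste0("d", 1:3), paste0("t", 1:2)))
  im <- interaction_matrix(y)
  expect_equal(sum(im$y), 2)
  py <- file.path(withr_dir, "y.tsv")
  write_interactions(im, py)
  expect_equal(read_interactions(py)$y, im$y)

  # comma-separated input is sniffed
  pc <- file.path(withr_dir, "v.csv")
  write.table(v$values, pc, sep = ",", quote = FALSE, col.names = NA)
  expect_lt(max(abs(read_similarity_view(pc)$values - v$values)), 1e-12)
})

test_that("interaction matrices reject non-binary entries and warn when empty", {
  expect_error(interaction_matrix(matrix(c(0, 0.5), 1, 2)),
               class = "dtifuse_validation_error")
  expect_warning(interaction_matrix(matrix(0, 2, 2)), "no positive")
})

test_that("dataset assembly rejects any label-order disagreement", {
  ds <- small_synth()
  expect_s3_class(assemble_dataset(ds$drug_sims, ds$target_sims,
                                   ds$interactions), "dti_dataset")

  # permutation fuzzing: reordering labels anywhere must fail assembly
  set.seed(42)
  for (i in 1:20) {
    axis <- sample(c("drug_view", "target_view", "y_rows", "y_cols"), 1)
    perm_ds <- ds
    if (axis == "drug_view") {
      v <- perm_ds$drug_sims$views[[1]]
      perm <- sample(length(v$labels))
      if (identical(perm, seq_along(v$labels))) next
      v$labels <- v$labels[perm]
      v$values <- v$values[perm, perm]
      views <- perm_ds$drug_sims$views
      views[[1]] <- v
      expect_error(similarity_set(views, "drug"), class = "dtifuse_assembly_error")
    } else if (axis == "target_view") {
      v <- perm_ds$target_sims$views[[1]]
      perm <- sample(length(v$labels))
      if (identical(perm, seq_along(v$labels))) next
      v$labels <- v$labels[perm]
      v$values <- v$values[perm, perm]
      views <- perm_ds$target_sims$views
      views[[1]] <- v
      expect_error(similarity_set(views, "target"), class = "dtifuse_assembly_error")
    } else if (axis == "y_rows") {
      y <- perm_ds$interactions$y
      perm <- sample(nrow(y))
      if (identical(perm, seq_len(nrow(y)))) next
      im <- interaction_matrix(y[perm, ])
      expect_error(assemble_dataset(ds$drug_sims, ds$target_sims, im),
                   class = "dtifuse_assembly_error")
    } else {
      y <- perm_ds$interactions$y
      perm <- sample(ncol(y))
      if (identical(perm, seq_len(ncol(y)))) next
      im <- interaction_matrix(y[, perm])
      expect_error(assemble_dataset(ds$drug_sims, ds$target_sims, im),
                   class = "dtifuse_assembly_error")
    }
  }
})

test_that("dataset manifests round-trip through write_dataset", {
  ds <- small_synth()
  dir <- tempfile()
  manifest <- write_dataset(ds, dir)
  ds2 <- read_dataset_manifest(manifest)
  expect_identical(ds2$drug_sims$labels, ds$drug_sims$labels)
  expect_equal(ds2$interactions$y, ds$interactions$y)
  expect_lt(max(abs(ds2$drug_sims$views[[1]]$values -
                    ds$drug_sims$views[[1]]$values)), 1e-12)
})
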