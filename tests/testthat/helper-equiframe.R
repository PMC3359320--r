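# Shared fixtures: the default framework, a compact annotation constructor,
# and a random score matrix generator used by property-style tests.

fw_default <- load_framework()

ann_rows <- function(concept_id, column_id, quality, doc_id = "doc-1",
                     rater_id = "r1", evidence = "excerpt") {
  tibble::tibble(
    rater_id = rater_id, doc_id = doc_id, concept_id = concept_id,
    column_id = column_id, quality = as.integer(quality),
    evidence = evidence, sentence_index = NA_integer_
  )
}

# Random annotations over the framework grid (scored cells only), and the
# matrix built from them.
random_annotations <- function(n, seed, doc_id = "doc-1") {
  withr::with_seed(seed, {
    cols <- c(fw_default$groups$group_id, "universal")
    ann_rows(
      concept_id = sample(fw_default$concepts$concept_id, n, replace = TRUE),
      column_id = sample(cols, n, replace = TRUE),
      quality = sample(1:4, n, replace = TRUE),
      doc_id = doc_id
    )
  })
}

random_matrix <- function(seed, max_cells = 30) {
  n <- withr::with_seed(seed, sample(0:max_cells, 1))
  if (n == 0) {
    build_matrix(ann_rows(character(), character(), integer())[0, ],
                 fw_default, doc_id = "doc-1")
  } else {
    build_matrix(random_annotations(n, seed + 1), fw_default)
  }
}

# Independent brute-force recount of a matrix's three indices (oracle kept
# free of the package's index code paths).
recount_indices <- function(matrix) {
  sc <- matrix$scores
  base_cols <- setdiff(colnames(sc), "universal")
  row_best <- suppressWarnings(apply(sc, 1, max, na.rm = TRUE))
  row_best[!is.finite(row_best)] <- NA
  list(
    n_groups = sum(colSums(!is.na(sc[, base_cols, drop = FALSE])) > 0),
    n_concepts = sum(!is.na(row_best)),
    n_quality = sum(row_best >= 3, na.rm = TRUE)
  )
}
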