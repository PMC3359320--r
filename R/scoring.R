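#' Read an annotation file
#'
#' Annotations are rater judgments: one row per (concept, column) evidence
#' item with a quality score. The CSV has columns `rater_id`, `doc_id`,
#' `concept_id`, `column_id` (a `group_id` or `"universal"`), `quality`
#' (1-4, or `NA` for "concept not applicable in this document"), `evidence`
#' and optionally `sentence_index`.
#'
#' @param path Annotation CSV path.
#' @return A tibble with `quality` as integer (`NA` = not applicable).
#' @export
read_annotations <- function(path) {
  ann <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      rater_id = readr::col_character(), doc_id = readr::col_character(),
      concept_id = readr::col_character(), column_id = readr::col_character(),
      quality = readr::col_integer(), evidence = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  need <- c("rater_id", "doc_id", "concept_id", "column_id", "quality",
            "evidence")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sentence_index" %in% names(ann)) ann$sentence_index <- NA_integer_
  ann
}

validate_annotations <- function(annotations, framework) {
  bad_q <- !is.na(annotations$quality) &
    !(annotations$quality %in% 1:4)
  if (any(bad_q)) {
    stop("quality must be 1-4 or NA (not applicable); offending value(s): ",
         paste(unique(annotations$quality[bad_q]), collapse = ", "),
         call. = FALSE)
  }
  unknown_c <- setdiff(annotations$concept_id, framework$concepts$concept_id)
  if (length(unknown_c) > 0) {
    stop("unknown concept_id in annotations: ",
         paste(unknown_c, collapse = ", "), call. = FALSE)
  }
  known_cols <- matrix_columns(framework)
  unknown_g <- setdiff(annotations$column_id[!is.na(annotations$column_id)],
                       known_cols)
  if (length(unknown_g) > 0) {
    stop("unknown column_id in annotations: ",
         paste(unknown_g, collapse = ", "), call. = FALSE)
  }
  invisible(annotations)
}

#' Build a document score matrix from annotations
#'
#' Aggregates one rater's (or the consensus) annotations for one document to
#' the concept-by-(group + Universal) score matrix. Where several references
#' to a Core Concept contribute to the same cell, the top quality score is
#' recorded (max rule). A concept annotated "not applicable" (`quality = NA`)
#' is recorded in `na_concepts`; a concept carrying both a score and a
#' not-applicable annotation is a validation error (that situation is a rater
#' disagreement for the reliability tools, never silently resolved).
#'
#' @param annotations Annotation tibble (see [read_annotations()]); must
#'   reference a single document.
#' @param framework An `equiframe_framework`.
#' @param doc_id Document id, required only when `annotations` has zero rows.
#' @return An object of class `equiframe_matrix`: a list with `doc_id`,
#'   `scores` (integer matrix, concepts x columns, `NA` = unmentioned;
#'   columns are all group ids then `"universal"`), `na_concepts`
#'   (character), and `evidence` (the annotations kept verbatim for
#'   terminology extraction).
#' @examples
#' fw <- load_framework()
#' ann <- tibble::tibble(
#'   rater_id = "r1", doc_id = "d1", concept_id = "access",
#'   column_id = "disabled", quality = c(1L, 3L, 2L),
#'   evidence = "…", sentence_index = NA_integer_
#' )
#' m <- build_matrix(ann, fw)
#' m$scores["access", "disabled"] # 3
#' @export
build_matrix <- function(annotations, framework, doc_id = NULL) {
  stopifnot(inherits(framework, "equiframe_framework"))
  if (nrow(annotations) > 0) {
    doc_ids <- unique(annotations$doc_id)
    if (length(doc_ids) > 1) {
      stop("annotations reference multiple documents: ",
           paste(doc_ids, collapse = ", "), call. = FALSE)
    }
    doc_id <- doc_ids
    validate_annotations(annotations, framework)
  } else if (is.null(doc_id)) {
    stop("doc_id is required for an empty annotation set", call. = FALSE)
  }

  cols <- matrix_columns(framework)
  scores <- matrix(
    NA_integer_, nrow = nrow(framework$concepts), ncol = length(cols),
    dimnames = list(framework$concepts$concept_id, cols)
  )
  na_concepts <- character()
  if (nrow(annotations) > 0) {
    is_na_ann <- is.na(annotations$quality)
    na_concepts <- unique(annotations$concept_id[is_na_ann])
    scored_concepts <- unique(annotations$concept_id[!is_na_ann])
    mixed <- intersect(na_concepts, scored_concepts)
    if (length(mixed) > 0) {
      bad <- annotations[annotations$concept_id %in% mixed, ,
                         drop = FALSE]
      stop("concept(s) carry both a score and a not-applicable annotation: ",
           paste(mixed, collapse = ", "), " (", nrow(bad),
           " conflicting annotation rows)", call. = FALSE)
    }
    scored <- annotations[!is_na_ann, , drop = FALSE]
    if (any(is.na(scored$column_id))) {
      stop("scored annotations must name a column_id (group or 'universal')",
           call. = FALSE)
    }
    for (i in seq_len(nrow(scored))) {
      r <- scored$concept_id[i]
      cc <- scored$column_id[i]
      cur <- scores[r, cc]
      if (is.na(cur) || scored$quality[i] > cur) {
        scores[r, cc] <- scored$quality[i]
      }
    }
  }
  structure(
    list(doc_id = doc_id, scores = scores, na_concepts = na_concepts,
         evidence = annotations),
    class = "equiframe_matrix"
  )
}

#' Best quality score of a concept across all columns
#'
#' @param matrix An `equiframe_matrix`.
#' @param concept_id A concept id present in the matrix.
#' @return The maximum quality score the concept received in any group or
#'   the Universal column, or `NA` if the concept is unmentioned.
#' @export
concept_best_score <- function(matrix, concept_id) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  if (!concept_id %in% rownames(matrix$scores)) {
    stop("unknown concept_id: ", concept_id, call. = FALSE)
  }
  row <- matrix$scores[concept_id, ]
  if (all(is.na(row))) NA_integer_ else max(row, na.rm = TRUE)
}

#' @export
print.equiframe_matrix <- function(x, ...) {
  n_cells <- sum(!is.na(x$scores))
  cat("<equiframe_matrix>", x$doc_id, "\n")
  cat(sprintf("  %d x %d grid, %d scored cell(s), %d not-applicable concept(s)\n",
              nrow(x$scores), ncol(x$scores), n_cells,
              length(x$na_concepts)))
  invisible(x)
}

#' Export a score matrix as a CSV grid
#'
#' Concepts as rows, groups plus Universal as columns; empty cell =
#' unmentioned; `NA` concepts marked in an extra `not_applicable` column.
#'
#' @param matrix An `equiframe_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  grid <- as.data.frame(matrix$scores)
  out <- cbind(
    concept_id = rownames(matrix$scores),
    grid,
    not_applicable = rownames(matrix$scores) %in% matrix$na_concepts
  )
  readr::write_csv(tibble::as_tibble(out), path, na = "", progress = FALSE)
  invisible(path)
}
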