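# Reduce one rater's annotation set to per-cell outcomes on the category
# set {absent, 1, 2, 3, 4, NA}. Concept-level not-applicable markings are
# carried on a pseudo-column "<n/a>" so that NA-vs-NA agreement is counted
# once per concept rather than once per grid cell.
rater_outcomes <- function(annotations, framework) {
  m <- build_matrix(annotations, framework,
                    doc_id = if (nrow(annotations) == 0) "empty" else NULL)
  idx <- which(!is.na(m$scores), arr.ind = TRUE)
  cells <- tibble::tibble(
    concept_id = rownames(m$scores)[idx[, 1]],
    column_id = colnames(m$scores)[idx[, 2]],
    outcome = as.character(m$scores[idx])
  )
  if (length(m$na_concepts) > 0) {
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      concept_id = m$na_concepts, column_id = "<n/a>", outcome = "NA"
    ))
  }
  cells
}

#' Compare two raters' annotation sets for one document
#'
#' Reduces each rater's annotations to cell outcomes on the categories
#' \{absent, 1, 2, 3, 4, NA\} (NA = concept marked not applicable) and
#' compares them. By default the comparison universe is the union of cells
#' either rater touched; comparing the full concept-by-column grid (which
#' inflates agreement through shared absences) is available with
#' `universe = "full"`. Reports raw cell agreement, Cohen's kappa over the
#' same categories, and the discrepancy list.
#'
#' @param annots_a,annots_b Annotation tibbles for the same document, one
#'   per rater.
#' @param framework An `equiframe_framework`.
#' @param universe `"union"` (default) or `"full"`.
#' @return An object of class `equiframe_comparison`: list with `doc_id`,
#'   `rater_a`, `rater_b`, `n_compared`, `n_agreed`, `cell_agreement`,
#'   `kappa`, and `discrepancies` (tibble: `concept_id`, `column_id`,
#'   `outcome_a`, `outcome_b`).
#' @export
compare_raters <- function(annots_a, annots_b, framework,
                           universe = c("union", "full")) {
  universe <- match.arg(universe)
  stopifnot(inherits(framework, "equiframe_framework"))
  doc_a <- unique(annots_a$doc_id)
  doc_b <- unique(annots_b$doc_id)
  if (length(doc_a) > 0 && length(doc_b) > 0 &&
      !setequal(doc_a, doc_b)) {
    stop("annotation sets reference different documents: ",
         paste(doc_a, collapse = ","), " vs ", paste(doc_b, collapse = ","),
         call. = FALSE)
  }
  doc_id <- c(doc_a, doc_b)[1]
  cells_a <- rater_outcomes(annots_a, framework)
  cells_b <- rater_outcomes(annots_b, framework)

  if (universe == "union") {
    univ <- dplyr::distinct(
      dplyr::bind_rows(cells_a[c("concept_id", "column_id")],
                       cells_b[c("concept_id", "column_id")])
    )
  } else {
    univ <- expand.grid(
      concept_id = framework$concepts$concept_id,
      column_id = matrix_columns(framework),
      stringsAsFactors = FALSE
    )
    univ <- tibble::as_tibble(univ)
  }
  if (nrow(univ) == 0) {
    stop("no cells to compare: both annotation sets are empty",
         call. = FALSE)
  }
  lookup <- function(cells, concept, column) {
    hit <- cells$outcome[cells$concept_id == concept &
                           cells$column_id == column]
    if (length(hit) == 0) "absent" else hit[1]
  }
  out_a <- mapply(lookup, univ$concept_id, univ$column_id,
                  MoreArgs = list(cells = cells_a))
  out_b <- mapply(lookup, univ$concept_id, univ$column_id,
                  MoreArgs = list(cells = cells_b))
  agree <- out_a == out_b
  disc <- tibble::tibble(
    concept_id = univ$concept_id[!agree],
    column_id = univ$column_id[!agree],
    outcome_a = unname(out_a[!agree]),
    outcome_b = unname(out_b[!agree])
  )
  structure(
    list(
      doc_id = doc_id,
      rater_a = if (nrow(annots_a) > 0) annots_a$rater_id[1] else "A",
      rater_b = if (nrow(annots_b) > 0) annots_b$rater_id[1] else "B",
      n_compared = nrow(univ), n_agreed = sum(agree),
      cell_agreement = mean(agree),
      kappa = cohen_kappa(unname(out_a), unname(out_b)),
      discrepancies = disc
    ),
    class = "equiframe_comparison"
  )
}

#' Cohen's kappa for two nominal ratings
#'
#' Chance-corrected agreement over paired categorical outcomes:
#' `(p_o - p_e) / (1 - p_e)` where `p_o` is observed agreement and `p_e`
#' the agreement expected from the two raters' marginal category
#' frequencies. Returns 1 for perfect agreement (including the degenerate
#' single-category case) and `NA` when chance agreement is 1 without
#' perfect agreement.
#'
#' @param a,b Character (or factor) vectors of equal length.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- as.character(a)
  b <- as.character(b)
  po <- mean(a == b)
  if (po == 1) return(1)
  cats <- union(a, b)
  pa <- table(factor(a, levels = cats)) / length(a)
  pb <- table(factor(b, levels = cats)) / length(b)
  pe <- sum(pa * pb)
  if (1 - pe < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' @export
print.equiframe_comparison <- function(x, ...) {
  cat("<equiframe_comparison>", x$doc_id, ":", x$rater_a, "vs", x$rater_b,
      "\n")
  cat(sprintf("  agreement %.3f (%d/%d cells), kappa %s, %d discrepancies\n",
              x$cell_agreement, x$n_agreed, x$n_compared,
              format(round(x$kappa, 3)), nrow(x$discrepancies)))
  invisible(x)
}

#' Write a discrepancy report / resolutions template
#'
#' CSV with one row per discrepancy and an empty `resolution` column to be
#' filled in (a quality 1-4, `NA`, `absent`, or the rater letter `a`/`b`)
#' and fed back to [build_consensus()].
#'
#' @param comparison An `equiframe_comparison`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_discrepancy_report <- function(comparison, path) {
  out <- comparison$discrepancies
  out$resolution <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Build a consensus annotation set from two raters
#'
#' Cells on which the raters agree pass through; every discrepancy must be
#' resolved by an explicit entry in `resolutions` (there is no automatic
#' adjudication) mirroring the post-scoring discussion that produces a
#' consensus position. The result validates as a single-rater annotation
#' set with `rater_id = "consensus"`.
#'
#' @param annots_a,annots_b Annotation tibbles for one document.
#' @param framework An `equiframe_framework`.
#' @param resolutions Tibble with columns `concept_id`, `column_id`,
#'   `resolution`; `resolution` is `"1"`-`"4"` (a quality), `"NA"` (concept
#'   not applicable), `"absent"` (drop the cell), or `"a"`/`"b"` (adopt
#'   that rater's outcome). May be empty when there are no discrepancies.
#' @return A consensus annotation tibble.
#' @export
build_consensus <- function(annots_a, annots_b, framework,
                            resolutions = NULL) {
  cmp <- compare_raters(annots_a, annots_b, framework)
  disc <- cmp$discrepancies
  if (is.null(resolutions)) {
    resolutions <- tibble::tibble(concept_id = character(),
                                  column_id = character(),
                                  resolution = character())
  }
  key <- function(d) paste(d$concept_id, d$column_id, sep = "\r")
  res_map <- stats::setNames(as.character(resolutions$resolution),
                             key(resolutions))
  unresolved <- setdiff(key(disc), names(res_map))
  if (length(unresolved) > 0) {
    items <- disc[key(disc) %in% unresolved, , drop = FALSE]
    stop("unresolved discrepancies remain: ",
         paste(paste0("(", items$concept_id, ", ", items$column_id, ")"),
               collapse = ", "), call. = FALSE)
  }

  cells_a <- rater_outcomes(annots_a, framework)
  cells_b <- rater_outcomes(annots_b, framework)
  univ <- dplyr::distinct(
    dplyr::bind_rows(cells_a[c("concept_id", "column_id")],
                     cells_b[c("concept_id", "column_id")])
  )
  pick_evidence <- function(concept, column) {
    for (ann in list(annots_a, annots_b)) {
      hit <- ann[ann$concept_id == concept &
                   (is.na(ann$column_id) | ann$column_id == column), ,
                 drop = FALSE]
      if (nrow(hit) > 0) return(hit$evidence[which.max(
        ifelse(is.na(hit$quality), 0L, hit$quality)
      )])
    }
    NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(univ))) {
    concept <- univ$concept_id[i]
    column <- univ$column_id[i]
    k <- paste(concept, column, sep = "\r")
    oa <- cells_a$outcome[cells_a$concept_id == concept &
                            cells_a$column_id == column]
    ob <- cells_b$outcome[cells_b$concept_id == concept &
                            cells_b$column_id == column]
    oa <- if (length(oa) == 0) "absent" else oa[1]
    ob <- if (length(ob) == 0) "absent" else ob[1]
    final <- if (oa == ob) {
      oa
    } else {
      r <- res_map[[k]]
      switch(tolower(r), a = oa, b = ob, r)
    }
    if (final == "absent") next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      rater_id = "consensus",
      doc_id = cmp$doc_id,
      concept_id = concept,
      column_id = if (final == "NA") NA_character_ else column,
      quality = if (final == "NA") NA_integer_ else as.integer(final),
      evidence = pick_evidence(concept, column),
      sentence_index = NA_integer_
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      rater_id = character(), doc_id = character(), concept_id = character(),
      column_id = character(), quality = integer(), evidence = character(),
      sentence_index = integer()
    ))
  }
  out <- dplyr::bind_rows(rows)
  # a concept resolved to NA must not keep scored cells from other columns
  na_concepts <- unique(out$concept_id[is.na(out$quality)])
  conflict <- !is.na(out$quality) & out$concept_id %in% na_concepts
  out[!conflict, , drop = FALSE]
}
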