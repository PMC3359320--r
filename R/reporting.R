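#' Build a country benchmark table
#'
#' Collects per-policy summaries into a benchmark table: rows ordered by
#' overall ranking (High, Moderate, Low) and, within ranking, by Core
#' Concept Quality descending; High/Moderate/Low tallies computed.
#'
#' @param summaries Tibble of policy summaries (rows of
#'   [summarize_policy()], or any tibble with `vg_pct`, `cc_pct`,
#'   `cc_quality_pct` and optionally `ranking`; a missing `ranking` is
#'   derived with [overall_ranking()]).
#' @param country Country label; defaults to the summaries' `country`
#'   column when present.
#' @param sort `TRUE` (default) for the deterministic ranking sort;
#'   `FALSE` preserves input order.
#' @return An object of class `equiframe_benchmark`: list with `country`,
#'   `rows` (the ordered tibble) and `tallies` (named integer vector
#'   High/Moderate/Low summing to the row count).
#' @export
benchmark_country <- function(summaries, country = NULL, sort = TRUE) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    stop("benchmark requires at least one policy summary", call. = FALSE)
  }
  need <- c("vg_pct", "cc_pct", "cc_quality_pct")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    stop("summaries are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(country)) {
    country <- if ("country" %in% names(summaries)) {
      u <- unique(summaries$country)
      if (length(u) > 1) {
        stop("summaries span multiple countries: ",
             paste(u, collapse = ", "), call. = FALSE)
      }
      u
    } else {
      NA_character_
    }
  }
  rows <- tibble::as_tibble(summaries)
  if (!"ranking" %in% names(rows)) {
    rows$ranking <- overall_ranking(rows$vg_pct, rows$cc_pct,
                                    rows$cc_quality_pct)
  }
  rows$ranking <- factor(as.character(rows$ranking),
                         levels = c("High", "Moderate", "Low"))
  if (any(is.na(rows$ranking))) {
    stop("ranking values must be High, Moderate or Low", call. = FALSE)
  }
  if (sort) {
    rows <- rows[order(rows$ranking, -rows$cc_quality_pct), , drop = FALSE]
  }
  tallies <- table(rows$ranking)
  structure(
    list(country = country, rows = rows,
         tallies = stats::setNames(as.integer(tallies), names(tallies))),
    class = "equiframe_benchmark"
  )
}

#' @export
print.equiframe_benchmark <- function(x, ...) {
  cat("<equiframe_benchmark>", x$country, "-", nrow(x$rows), "policies\n")
  cat(sprintf("  High %d / Moderate %d / Low %d\n",
              x$tallies[["High"]], x$tallies[["Moderate"]],
              x$tallies[["Low"]]))
  invisible(x)
}

#' Export a benchmark table as CSV
#'
#' Columns mirror the published country tables: policy, Vulnerable Group
#' Coverage, Core Concept Coverage, Core Concept Quality, overall ranking.
#'
#' @param benchmark An `equiframe_benchmark`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(benchmark, path) {
  rows <- benchmark$rows
  id_col <- intersect(c("policy", "title", "doc_id"), names(rows))[1]
  out <- tibble::tibble(
    policy = rows[[id_col]],
    vg_pct = rows$vg_pct, cc_pct = rows$cc_pct,
    cc_quality_pct = rows$cc_quality_pct,
    ranking = as.character(rows$ranking)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract the terminologies used for concepts and groups
#'
#' Collects the verbatim evidence excerpts behind a set of annotations,
#' grouped per Core Concept and per column (group or Universal),
#' de-duplicated while preserving document order, with occurrence counts -
#' supporting qualitative cross-checking of the actual wording policies
#' use.
#'
#' @param annotations Annotation tibble with `evidence` excerpts.
#' @return A list of two tibbles: `concepts` (`concept_id`, `excerpt`,
#'   `n`) and `columns` (`column_id`, `excerpt`, `n`).
#' @export
extract_terminologies <- function(annotations) {
  empty <- function(id_col) {
    tibble::as_tibble(stats::setNames(
      list(character(), character(), integer()), c(id_col, "excerpt", "n")
    ))
  }
  if (nrow(annotations) == 0) {
    return(list(concepts = empty("concept_id"), columns = empty("column_id")))
  }
  dedup <- function(df, id_col) {
    df <- df[!is.na(df[[id_col]]) & !is.na(df$excerpt), , drop = FALSE]
    if (nrow(df) == 0) return(empty(id_col))
    df$.order <- seq_len(nrow(df))
    agg <- dplyr::summarise(
      dplyr::group_by(df, .data[[id_col]], .data$excerpt),
      n = dplyr::n(), .order = min(.data$.order), .groups = "drop"
    )
    agg <- agg[order(agg[[id_col]], agg$.order), , drop = FALSE]
    agg$.order <- NULL
    agg$n <- as.integer(agg$n)
    agg
  }
  list(
    concepts = dedup(
      tibble::tibble(concept_id = annotations$concept_id,
                     excerpt = annotations$evidence), "concept_id"
    ),
    columns = dedup(
      tibble::tibble(column_id = annotations$column_id,
                     excerpt = annotations$evidence), "column_id"
    )
  )
}

#' Published summary indices for 51 African health policies
#'
#' The benchmark dataset of summary indices (Vulnerable Group Coverage,
#' Core Concept Coverage, Core Concept Quality, all as printed percentages)
#' and overall rankings published for the 51 health policies analyzed with
#' the framework across Malawi (14 policies), Namibia (10), South Africa
#' (11) and Sudan (16). Shipped as a validation fixture: the ranking rule
#' and country tallies are reproducible from these rows.
#'
#' @return Tibble with columns `country`, `policy`, `vg_pct`, `cc_pct`,
#'   `cc_quality_pct`, `ranking`.
#' @export
reference_policy_indices <- function() {
  path <- system.file("extdata", "policy_indices_51.csv",
                      package = "equiframe", mustWork = TRUE)
  readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      country = readr::col_character(), policy = readr::col_character(),
      vg_pct = readr::col_double(), cc_pct = readr::col_double(),
      cc_quality_pct = readr::col_double(),
      ranking = readr::col_character()
    )
  )
}

#' Write a machine-readable run log
#'
#' Records inputs, a hash of the framework config, and the options of a
#' command-line run as JSON, sufficient to reproduce the outputs.
#'
#' @param path Output JSON path.
#' @param inputs Named list/character of input files.
#' @param framework_path Path of the framework config used.
#' @param options Named list of options in effect.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, inputs, framework_path, options = list()) {
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    framework = list(
      path = framework_path,
      md5 = unname(tools::md5sum(framework_path))
    ),
    options = options,
    package_version = as.character(utils::packageVersion("equiframe"))
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
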