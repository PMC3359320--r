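#' Detect candidate mentions of concepts, groups and universal references
#'
#' Scans every sentence of a document for the framework's key phrases.
#' Matching is exact-phrase, case-insensitive, on word boundaries; no
#' stemming. Detection proposes candidates for human raters to confirm and
#' score: it never assigns a quality level above "mentioned".
#'
#' @param document An `equiframe_document`.
#' @param framework An `equiframe_framework`.
#' @return A tibble of candidates, ordered by sentence then category
#'   (concept, group, universal), with columns `doc_id`, `sentence_index`,
#'   `category`, `target_id` (`NA` for universal), `matched_phrase`,
#'   `excerpt` (the verbatim sentence). Zero rows for an empty document.
#' @export
detect_mentions <- function(document, framework) {
  stopifnot(inherits(document, "equiframe_document"),
            inherits(framework, "equiframe_framework"))
  sentences <- document$sentences
  empty <- tibble::tibble(
    doc_id = character(), sentence_index = integer(), category = character(),
    target_id = character(), matched_phrase = character(),
    excerpt = character()
  )
  if (nrow(sentences) == 0) return(empty)

  targets <- rbind(
    data.frame(
      category = "concept",
      target_id = rep(framework$concepts$concept_id,
                      lengths(framework$concepts$key_phrases)),
      phrase = unlist(framework$concepts$key_phrases, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    data.frame(
      category = "group",
      target_id = rep(framework$groups$group_id,
                      lengths(framework$groups$key_phrases)),
      phrase = unlist(framework$groups$key_phrases, use.names = FALSE),
      stringsAsFactors = FALSE
    ),
    data.frame(
      category = "universal", target_id = NA_character_,
      phrase = framework$universal_phrases, stringsAsFactors = FALSE
    )
  )

  hits <- list()
  for (s in seq_len(nrow(sentences))) {
    sent <- sentences$text[s]
    matched <- phrase_in_text(targets$phrase, sent)
    if (!any(matched)) next
    sub <- targets[matched, , drop = FALSE]
    hits[[length(hits) + 1L]] <- tibble::tibble(
      doc_id = document$doc_id,
      sentence_index = sentences$index[s],
      category = sub$category,
      target_id = sub$target_id,
      matched_phrase = sub$phrase,
      excerpt = sent
    )
  }
  if (length(hits) == 0) return(empty)
  out <- dplyr::bind_rows(hits)
  cat_order <- c(concept = 1L, group = 2L, universal = 3L)
  out[order(out$sentence_index, cat_order[out$category], out$target_id,
            out$matched_phrase), , drop = FALSE]
}

# Vectorized over phrases: does each phrase occur in `text`, matched
# case-insensitively on word boundaries? Non-word phrase edges (e.g. a
# leading hyphen) anchor on the phrase's own first/last word character.
phrase_in_text <- function(phrases, text) {
  vapply(phrases, function(p) {
    grepl(phrase_regex(p), text, perl = TRUE, ignore.case = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

phrase_regex <- function(phrase) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase)
  # allow any run of whitespace where the phrase has a space
  esc <- gsub(" +", "\\\\s+", esc)
  paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
}

#' Pair concept mentions with group or Universal anchors
#'
#' Applies the framework's pairing rule at sentence scope (optionally
#' widened to a window of neighbouring sentences): a concept mention in a
#' sentence that also mentions a vulnerable group yields one (concept, group)
#' pair per group; a concept mention whose sentence mentions only a universal
#' phrase (e.g. "all people") is scored against the Universal column. A
#' concept mention with neither anchor defaults to Universal when
#' `universal_default = TRUE` (the framework's rule that population-wide
#' statements address everyone); otherwise it is left unpaired and reported
#' with `column_id = NA`.
#'
#' @param candidates Candidate tibble from [detect_mentions()] (one
#'   document).
#' @param window Integer; concept and group mentions within `window`
#'   sentences of each other are paired. Default 0 (same sentence).
#' @param universal_default Logical; see above. Default `TRUE`.
#' @return A tibble with columns `doc_id`, `concept_id`, `column_id`
#'   (a `group_id`, `"universal"`, or `NA` when unpaired), `sentence_index`,
#'   `evidence`.
#' @export
pair_mentions <- function(candidates, window = 0L, universal_default = TRUE) {
  cols <- c("doc_id", "concept_id", "column_id", "sentence_index", "evidence")
  empty <- tibble::as_tibble(stats::setNames(
    list(character(), character(), character(), integer(), character()), cols
  ))
  if (nrow(candidates) == 0) return(empty)
  if (length(unique(candidates$doc_id)) > 1) {
    stop("pair_mentions expects candidates from a single document",
         call. = FALSE)
  }
  concepts <- candidates[candidates$category == "concept", , drop = FALSE]
  groups <- candidates[candidates$category == "group", , drop = FALSE]
  universals <- candidates[candidates$category == "universal", , drop = FALSE]
  if (nrow(concepts) == 0) return(empty)

  out <- list()
  seen <- character() # de-duplicate (concept, column, sentence)
  for (i in seq_len(nrow(concepts))) {
    ci <- concepts[i, ]
    near_g <- groups[abs(groups$sentence_index - ci$sentence_index) <= window,
                     , drop = FALSE]
    near_u <- universals[
      abs(universals$sentence_index - ci$sentence_index) <= window, ,
      drop = FALSE
    ]
    cols_here <- unique(near_g$target_id)
    if (length(cols_here) == 0 && nrow(near_u) > 0) {
      cols_here <- "universal"
    }
    if (length(cols_here) == 0) {
      cols_here <- if (universal_default) "universal" else NA_character_
    }
    for (col in cols_here) {
      key <- paste(ci$target_id, col, ci$sentence_index, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- tibble::tibble(
        doc_id = ci$doc_id, concept_id = ci$target_id, column_id = col,
        sentence_index = ci$sentence_index, evidence = ci$excerpt
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Count universal-population references in a document
#'
#' Counts every occurrence (not sentence) of the framework's universal
#' phrases, e.g. "all people" or "everyone", across the document text.
#'
#' @param document An `equiframe_document`.
#' @param framework An `equiframe_framework`.
#' @return A single non-negative integer.
#' @export
count_universal_references <- function(document, framework) {
  stopifnot(inherits(document, "equiframe_document"),
            inherits(framework, "equiframe_framework"))
  if (!nzchar(document$text)) return(0L)
  counts <- vapply(framework$universal_phrases, function(p) {
    m <- gregexpr(phrase_regex(p), document$text, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  sum(counts)
}

#' Write a rater worksheet of detection candidates
#'
#' Exports candidates as a CSV suitable for manual confirmation and quality
#' scoring, with an empty `quality` column for the rater to fill in.
#'
#' @param candidates Tibble from [detect_mentions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_worksheet <- function(candidates, path) {
  out <- candidates
  out$quality <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
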