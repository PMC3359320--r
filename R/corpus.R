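#' Segment text into sentence units
#'
#' Deterministic, lossless rule-based sentence segmentation. A sentence
#' boundary is a `.`, `!` or `?` (plus any closing quote/bracket) followed by
#' whitespace and an upper-case letter or digit, unless the token preceding
#' the period is a known abbreviation (e.g. "e.g.", "i.e.", "etc.", "Dr.",
#' "No.", "Fig."). End of text always closes the final sentence. The spans
#' cover every non-whitespace character: concatenating the spans plus the
#' gaps between them reconstructs the input exactly.
#'
#' @param text A single character string (may be empty).
#' @return A tibble with columns `index` (1-based sentence number), `start`,
#'   `end` (0-based, half-open character offsets into `text`) and `text`
#'   (the verbatim sentence). Zero rows for empty/whitespace-only input.
#' @examples
#' segment_sentences("Services are free. Everyone may attend.")
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble::tibble(index = integer(), start = integer(),
                          end = integer(), text = character())
  if (is.na(text) || !nzchar(trimws(text))) {
    return(empty)
  }
  abbrev <- c("e.g", "i.e", "etc", "cf", "vs", "viz", "approx",
              "dr", "mr", "mrs", "ms", "prof", "st", "no", "fig", "al")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # candidate boundary: terminator (+ optional quotes/brackets) then
  # whitespace then uppercase/digit, or end of string
  is_term <- chars %in% c(".", "!", "?")
  breaks <- integer() # position of last char of each sentence (1-based)
  i <- 1L
  while (i <= n) {
    if (is_term[i]) {
      j <- i
      while (j + 1L <= n && chars[j + 1L] %in% c("\"", "'", ")", "]")) {
        j <- j + 1L
      }
      at_end <- j == n
      followed <- !at_end && grepl("[[:space:]]", chars[j + 1L])
      if (followed) {
        k <- j + 1L
        while (k <= n && grepl("[[:space:]]", chars[k])) k <- k + 1L
        followed <- k <= n && grepl("[[:upper:][:digit:]]", chars[k])
      }
      if (at_end || followed) {
        # token immediately before the terminator
        t_end <- i - 1L
        t_start <- t_end
        while (t_start >= 1L &&
               grepl("[[:alpha:].]", chars[t_start])) {
          t_start <- t_start - 1L
        }
        token <- if (t_end >= t_start + 1L) {
          tolower(paste(chars[(t_start + 1L):t_end], collapse = ""))
        } else ""
        token <- sub("\\.+$", "", token)
        if (!(chars[i] == "." && token %in% abbrev)) {
          breaks <- c(breaks, j)
        }
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(breaks) == 0 || breaks[length(breaks)] < n) {
    breaks <- c(breaks, n)
  }
  starts0 <- c(1L, breaks[-length(breaks)] + 1L)
  out <- list()
  idx <- 0L
  for (s in seq_along(breaks)) {
    a <- starts0[s]
    b <- breaks[s]
    # trim surrounding whitespace from the span (gaps reconstruct it)
    while (a <= b && grepl("[[:space:]]", chars[a])) a <- a + 1L
    while (b >= a && grepl("[[:space:]]", chars[b])) b <- b - 1L
    if (a > b) next # whitespace-only fragment
    idx <- idx + 1L
    out[[idx]] <- tibble::tibble(
      index = idx,
      start = a - 1L,         # 0-based
      end = b,                # half-open
      text = substr(text, a, b)
    )
  }
  if (idx == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Read a policy document from a plain-text file
#'
#' @param path Path to a plain-text file (UTF-8; `encoding` is a fallback).
#' @param doc_id Unique document identifier; defaults to the file name.
#' @param country,title Document metadata labels.
#' @param doc_type One of `"policy"`, `"guideline"`, `"strategic plan"`,
#'   `"programme"`, `"other"`.
#' @param encoding Encoding passed to the reader when UTF-8 fails.
#' @return An object of class `equiframe_document`; see [policy_document()].
#' @export
read_document <- function(path, doc_id = NULL, country = NA_character_,
                          title = NA_character_, doc_type = "policy",
                          encoding = "latin1") {
  if (!file.exists(path)) {
    stop("document file not found: ", path, call. = FALSE)
  }
  txt <- tryCatch(
    readr::read_file(path, locale = readr::locale(encoding = "UTF-8")),
    error = function(e) NULL
  )
  if (is.null(txt) || !validUTF8(txt)) {
    txt <- tryCatch(
      readr::read_file(path, locale = readr::locale(encoding = encoding)),
      error = function(e) {
        stop("cannot decode '", path, "' as UTF-8 or ", encoding,
             call. = FALSE)
      }
    )
  }
  policy_document(
    text = txt,
    doc_id = doc_id %||% basename(path),
    country = country, title = title, doc_type = doc_type
  )
}

#' Construct a policy document from text
#'
#' Builds the in-memory document object, including sentence segmentation via
#' [segment_sentences()]. An empty text yields a document with zero
#' sentences, not an error.
#'
#' @param text Full document text.
#' @param doc_id Unique identifier.
#' @param country,title Metadata labels.
#' @param doc_type One of `"policy"`, `"guideline"`, `"strategic plan"`,
#'   `"programme"`, `"other"`.
#' @return An object of class `equiframe_document`: a list with the metadata
#'   fields, `text`, and the `sentences` tibble.
#' @export
policy_document <- function(text, doc_id, country = NA_character_,
                            title = NA_character_, doc_type = "policy") {
  doc_type <- match.arg(doc_type,
                        c("policy", "guideline", "strategic plan",
                          "programme", "other"))
  stopifnot(is.character(doc_id), length(doc_id) == 1, nzchar(doc_id))
  structure(
    list(
      doc_id = doc_id, country = country, title = title,
      doc_type = doc_type, text = text,
      sentences = segment_sentences(text)
    ),
    class = "equiframe_document"
  )
}

#' @export
print.equiframe_document <- function(x, ...) {
  cat("<equiframe_document>", x$doc_id, "\n")
  cat(sprintf("  country: %s | type: %s | %d sentences, %d characters\n",
              x$country, x$doc_type, nrow(x$sentences), nchar(x$text)))
  invisible(x)
}

#' Read a corpus of policy documents from a manifest
#'
#' The manifest is a CSV with columns `doc_id`, `country`, `title`,
#' `doc_type`, `path` (paths relative to the manifest's directory or
#' absolute).
#'
#' @param manifest_path Path to the manifest CSV.
#' @return An object of class `equiframe_corpus`: a list with `documents`
#'   (named list of `equiframe_document`) and `manifest` (the tibble read).
#' @export
read_corpus <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("doc_id", "country", "title", "doc_type", "path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0) {
    stop("corpus manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man$doc_id)) {
    stop("duplicate doc_id in corpus manifest: ",
         paste(unique(man$doc_id[duplicated(man$doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  docs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_document(p, doc_id = man$doc_id[i], country = man$country[i],
                  title = man$title[i], doc_type = man$doc_type[i])
  })
  names(docs) <- man$doc_id
  structure(list(documents = docs, manifest = man),
            class = "equiframe_corpus")
}

#' @export
print.equiframe_corpus <- function(x, ...) {
  cat("<equiframe_corpus>", length(x$documents), "documents\n")
  invisible(x)
}
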