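#' Load a framework definition
#'
#' Reads a framework configuration (YAML) defining the Core Concepts of human
#' rights, the Vulnerable Groups, and the phrases treated as references to the
#' total population ("Universal"). The shipped default defines the canonical
#' 21 concepts and 12 base groups.
#'
#' Key phrases are stored lowercase; all matching downstream is
#' case-insensitive on word boundaries. Concept/group ordering is preserved
#' from the configuration file. Groups flagged `country_specific: true` are
#' additive extras: they are scored like base groups but never enter the
#' base-12 Vulnerable Group Coverage denominator.
#'
#' @param path Path to a YAML framework config with top-level keys
#'   `concepts`, `vulnerable_groups` and `universal_phrases`. `NULL` (default)
#'   loads the framework shipped with the package.
#' @param strict Logical; if `TRUE`, deviations from the canonical
#'   cardinalities (21 concepts, 12 base groups) are errors instead of
#'   warnings.
#' @return An object of class `equiframe_framework`: a list with tibbles
#'   `concepts` (`concept_id`, `name`, `definition`, `key_questions`,
#'   `key_phrases`), `groups` (`group_id`, `name`, `definition`,
#'   `key_phrases`, `country_specific`) and a character vector
#'   `universal_phrases`.
#' @examples
#' fw <- load_framework()
#' nrow(fw$concepts) # 21
#' sum(!fw$groups$country_specific) # 12
#' @export
load_framework <- function(path = NULL, strict = FALSE) {
  if (is.null(path)) {
    path <- default_framework_path()
  }
  if (!file.exists(path)) {
    stop("framework config not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (key in c("concepts", "vulnerable_groups", "universal_phrases")) {
    if (is.null(raw[[key]])) {
      stop("framework config is missing top-level key '", key, "'",
           call. = FALSE)
    }
  }
  concepts <- tibble::tibble(
    concept_id = vapply(raw$concepts, function(x) req_field(x, "concept_id"),
                        character(1)),
    name = vapply(raw$concepts, function(x) req_field(x, "name"), character(1)),
    definition = vapply(raw$concepts,
                        function(x) trimws(x$definition %||% ""), character(1)),
    key_questions = lapply(raw$concepts,
                           function(x) as.character(unlist(x$key_questions))),
    key_phrases = lapply(raw$concepts, function(x) {
      tolower(trimws(as.character(unlist(x$key_phrases))))
    })
  )
  groups <- tibble::tibble(
    group_id = vapply(raw$vulnerable_groups,
                      function(x) req_field(x, "group_id"), character(1)),
    name = vapply(raw$vulnerable_groups, function(x) req_field(x, "name"),
                  character(1)),
    definition = vapply(raw$vulnerable_groups,
                        function(x) trimws(x$definition %||% ""), character(1)),
    key_phrases = lapply(raw$vulnerable_groups, function(x) {
      tolower(trimws(as.character(unlist(x$key_phrases))))
    }),
    country_specific = vapply(raw$vulnerable_groups,
                              function(x) isTRUE(x$country_specific),
                              logical(1))
  )
  fw <- structure(
    list(
      concepts = concepts,
      groups = groups,
      universal_phrases = tolower(trimws(as.character(
        unlist(raw$universal_phrases)
      ))),
      source = path
    ),
    class = "equiframe_framework"
  )
  validate_framework(fw, strict = strict)
  fw
}

#' Path to the default framework configuration shipped with the package
#' @return File path of the default YAML config.
#' @export
default_framework_path <- function() {
  system.file("extdata", "equiframe_default.yaml", package = "equiframe",
              mustWork = TRUE)
}

req_field <- function(x, field) {
  val <- x[[field]]
  if (is.null(val) || !nzchar(trimws(as.character(val)))) {
    stop("framework entry is missing required field '", field, "'",
         call. = FALSE)
  }
  trimws(as.character(val))
}

validate_framework <- function(fw, strict = FALSE) {
  dup_c <- fw$concepts$concept_id[duplicated(fw$concepts$concept_id)]
  if (length(dup_c) > 0) {
    stop("duplicate concept_id in framework: ",
         paste(unique(dup_c), collapse = ", "), call. = FALSE)
  }
  dup_g <- fw$groups$group_id[duplicated(fw$groups$group_id)]
  if (length(dup_g) > 0) {
    stop("duplicate group_id in framework: ",
         paste(unique(dup_g), collapse = ", "), call. = FALSE)
  }
  if ("universal" %in% fw$groups$group_id) {
    stop("group_id 'universal' is reserved for the Universal column",
         call. = FALSE)
  }
  no_phrase <- fw$concepts$concept_id[
    lengths(fw$concepts$key_phrases) == 0
  ]
  if (length(no_phrase) > 0) {
    stop("concepts without key phrases cannot be used for detection: ",
         paste(no_phrase, collapse = ", "), call. = FALSE)
  }
  n_base <- sum(!fw$groups$country_specific)
  counts_ok <- nrow(fw$concepts) == 21L && n_base == 12L
  if (!counts_ok) {
    msg <- sprintf(
      "framework has %d concepts and %d base groups (canonical: 21 and 12)",
      nrow(fw$concepts), n_base
    )
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  need <- c("all people", "everyone")
  missing_u <- setdiff(need, fw$universal_phrases)
  if (length(missing_u) > 0) {
    warning("universal_phrases is missing canonical phrase(s): ",
            paste(missing_u, collapse = ", "), call. = FALSE)
  }
  conflicts <- phrase_conflicts(fw)
  hard <- conflicts[conflicts$kind == "group-universal", , drop = FALSE]
  if (nrow(hard) > 0) {
    stop("phrase(s) assigned to both a vulnerable group and the universal ",
         "category: ", paste(unique(hard$phrase), collapse = ", "),
         call. = FALSE)
  }
  invisible(fw)
}

#' Report phrases assigned to more than one lexicon category
#'
#' Scans every key phrase in the framework for multiple assignments. A phrase
#' shared by two Core Concepts is permitted but flagged (`concept-concept`
#' ambiguity); a phrase serving both as a group phrase and a universal phrase
#' (or two different groups) is a configuration defect, because group coverage
#' denominators must be unambiguous.
#'
#' @param framework An `equiframe_framework`.
#' @return A tibble with columns `phrase`, `kind` (one of `concept-concept`,
#'   `group-group`, `group-universal`) and `owners` (ids involved, `;`
#'   separated). Zero rows for the default framework.
#' @export
phrase_conflicts <- function(framework) {
  stopifnot(inherits(framework, "equiframe_framework"))
  owners <- rbind(
    data.frame(
      phrase = unlist(framework$concepts$key_phrases, use.names = FALSE),
      owner = rep(framework$concepts$concept_id,
                  lengths(framework$concepts$key_phrases)),
      side = "concept", stringsAsFactors = FALSE
    ),
    data.frame(
      phrase = unlist(framework$groups$key_phrases, use.names = FALSE),
      owner = rep(framework$groups$group_id,
                  lengths(framework$groups$key_phrases)),
      side = "group", stringsAsFactors = FALSE
    ),
    data.frame(
      phrase = framework$universal_phrases,
      owner = rep("universal", length(framework$universal_phrases)),
      side = "universal", stringsAsFactors = FALSE
    )
  )
  out <- list()
  for (ph in unique(owners$phrase[duplicated(owners$phrase)])) {
    sub <- unique(owners[owners$phrase == ph, c("owner", "side")])
    if (nrow(sub) < 2) next # same phrase repeated within one owner
    sides <- sub$side
    kind <- if (all(sides == "concept")) {
      "concept-concept"
    } else if (all(sides == "group")) {
      "group-group"
    } else if (all(sides %in% c("group", "universal"))) {
      "group-universal"
    } else {
      # concept/group or concept/universal overlap: concepts live on a
      # different axis, so this is concept-side ambiguity only
      "concept-concept"
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      phrase = ph, kind = kind,
      owners = paste(sub$owner, collapse = ";")
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(phrase = character(), kind = character(),
                          owners = character()))
  }
  dplyr::bind_rows(out)
}

#' Serialize a framework back to YAML
#'
#' Writes a loaded framework to a YAML file that [load_framework()] reads
#' back to an identical framework (round-trip property).
#'
#' @param framework An `equiframe_framework`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_framework <- function(framework, path) {
  stopifnot(inherits(framework, "equiframe_framework"))
  cfg <- list(
    concepts = lapply(seq_len(nrow(framework$concepts)), function(i) {
      row <- framework$concepts[i, ]
      list(
        concept_id = row$concept_id, name = row$name,
        definition = row$definition,
        key_questions = as.list(row$key_questions[[1]]),
        key_phrases = as.list(row$key_phrases[[1]])
      )
    }),
    vulnerable_groups = lapply(seq_len(nrow(framework$groups)), function(i) {
      row <- framework$groups[i, ]
      list(
        group_id = row$group_id, name = row$name,
        definition = row$definition,
        key_phrases = as.list(row$key_phrases[[1]]),
        country_specific = row$country_specific
      )
    }),
    universal_phrases = as.list(framework$universal_phrases)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.equiframe_framework <- function(x, ...) {
  n_extra <- sum(x$groups$country_specific)
  cat("<equiframe_framework>\n")
  cat(sprintf("  %d Core Concepts, %d base Vulnerable Groups%s\n",
              nrow(x$concepts), sum(!x$groups$country_specific),
              if (n_extra > 0) {
                sprintf(" (+%d country-specific)", n_extra)
              } else ""))
  cat(sprintf("  %d universal phrases: %s, ...\n",
              length(x$universal_phrases),
              paste(utils::head(x$universal_phrases, 2), collapse = ", ")))
  invisible(x)
}

# Column ids of a document score matrix: all groups (base then extras keep
# config order) plus the distinguished Universal column, always last.
matrix_columns <- function(framework) {
  c(framework$groups$group_id, "universal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
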