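# Sentence templates encoding the four quality levels. Automated detection
# only ever proposes that a concept is *mentioned*; the planted quality is
# carried by the ground-truth annotations, mirroring the human-judgment
# boundary of the method. Template vocabulary is deliberately disjoint from
# every default key phrase so distractor-free precision is exact.
quality_templates <- c(
  "The document refers to %s in relation to %s.",
  "The importance of %s for %s is described and explained in detail.",
  "The ministry shall implement specific actions to advance %s for %s.",
  "An intention to monitor %s for %s is stated, with annual reporting of progress."
)

universal_extra_template <- "These provisions apply to %s."

distractor_sentences <- c(
  "The committee convened quarterly to review the budget.",
  "Annexes list the administrative procedures in detail.",
  "The ministry collaborated with regional offices on logistics.",
  "Printing and distribution of the document was completed in the second quarter.",
  "A glossary of administrative terms appears at the end.",
  "Departmental reporting lines are described in the organogram.",
  "Procurement follows the standard tendering procedure.",
  "The secretariat maintains the master schedule."
)

#' Create a synthetic-document generation plan
#'
#' A plan fixes everything a synthetic policy document will contain: which
#' (concept, column) cells are planted, at what quality and how many times;
#' how many extra universal-population sentences and how many distractor
#' sentences (drawn from a key-phrase-free vocabulary) to interleave. The
#' plan is its own oracle: the summary indices the full pipeline should
#' recover are computable from the plan alone.
#'
#' @param planted_cells Tibble with columns `concept_id`, `column_id`
#'   (a group id or `"universal"`), `quality` (1-4) and `n_mentions`
#'   (>= 1). May have zero rows.
#' @param n_universal_extra Count of additional universal-phrase sentences
#'   carrying no concept.
#' @param n_distractors Count of distractor sentences.
#' @param seed Integer seed; same plan + seed gives a byte-identical
#'   document.
#' @return An object of class `equiframe_plan`.
#' @export
generation_plan <- function(planted_cells = NULL, n_universal_extra = 0L,
                            n_distractors = 0L, seed = 1L) {
  if (is.null(planted_cells) || nrow(planted_cells) == 0) {
    planted_cells <- tibble::tibble(
      concept_id = character(), column_id = character(),
      quality = integer(), n_mentions = integer()
    )
  }
  stopifnot(
    all(c("concept_id", "column_id", "quality", "n_mentions") %in%
          names(planted_cells)),
    all(planted_cells$quality %in% 1:4),
    all(planted_cells$n_mentions >= 1),
    n_universal_extra >= 0, n_distractors >= 0
  )
  structure(
    list(planted_cells = tibble::as_tibble(planted_cells),
         n_universal_extra = as.integer(n_universal_extra),
         n_distractors = as.integer(n_distractors),
         seed = as.integer(seed)),
    class = "equiframe_plan"
  )
}

#' @export
print.equiframe_plan <- function(x, ...) {
  cat("<equiframe_plan>", nrow(x$planted_cells), "planted cell(s),",
      x$n_universal_extra, "universal extra(s),",
      x$n_distractors, "distractor(s), seed", x$seed, "\n")
  invisible(x)
}

plan_expected_summary <- function(plan, framework, doc_id,
                                  vg_denominator = 12,
                                  cc_denominator = 21) {
  cells <- plan$planted_cells
  base_groups <- framework$groups$group_id[!framework$groups$country_specific]
  n_concepts <- length(unique(cells$concept_id))
  n_groups <- length(unique(intersect(cells$column_id, base_groups)))
  best <- tapply(cells$quality, cells$concept_id, max)
  n_quality <- sum(best >= 3)
  vg <- 100 * n_groups / vg_denominator
  cc <- 100 * n_concepts / cc_denominator
  qu <- 100 * n_quality / cc_denominator
  n_met <- sum(c(vg, cc, qu) >= 50)
  tibble::tibble(
    doc_id = doc_id,
    vg_pct = round_half_up(vg, 1), cc_pct = round_half_up(cc, 1),
    cc_quality_pct = round_half_up(qu, 1),
    ranking = factor(if (n_met == 3) "High" else if (n_met == 2) "Moderate"
                     else "Low",
                     levels = c("High", "Moderate", "Low")),
    n_groups = n_groups, n_concepts = n_concepts, n_quality = n_quality
  )
}

#' Generate a synthetic policy document with ground truth
#'
#' Renders every planted cell of the plan into `n_mentions` sentences using
#' the quality-level template (mention / explanation / action / monitoring
#' phrasing), each containing exactly one concept key phrase and one group
#' or universal key phrase; adds the requested universal-only and
#' distractor sentences; shuffles deterministically under the plan's seed.
#'
#' @param plan An `equiframe_plan`.
#' @param framework An `equiframe_framework`.
#' @param doc_id,country Document metadata.
#' @return A list: `document` (`equiframe_document`), `annotations` (the
#'   ground-truth annotation tibble, `rater_id = "truth"`, one row per
#'   planted sentence at the planted quality), `expected` (the one-row
#'   summary the pipeline should recover, computed analytically from the
#'   plan), and `plan`.
#' @export
generate_document <- function(plan, framework, doc_id = "synthetic-1",
                              country = "Synthetica") {
  stopifnot(inherits(plan, "equiframe_plan"),
            inherits(framework, "equiframe_framework"))
  cells <- plan$planted_cells
  unknown_c <- setdiff(cells$concept_id, framework$concepts$concept_id)
  unknown_g <- setdiff(cells$column_id, matrix_columns(framework))
  if (length(unknown_c) > 0 || length(unknown_g) > 0) {
    stop("plan references unknown framework ids: ",
         paste(c(unknown_c, unknown_g), collapse = ", "), call. = FALSE)
  }
  concept_phrases <- stats::setNames(framework$concepts$key_phrases,
                                     framework$concepts$concept_id)
  group_phrases <- stats::setNames(framework$groups$key_phrases,
                                   framework$groups$group_id)

  withr::with_seed(plan$seed, {
    sent <- character()
    truth <- list()
    for (i in seq_len(nrow(cells))) {
      for (rep_i in seq_len(cells$n_mentions[i])) {
        cp <- sample(concept_phrases[[cells$concept_id[i]]], 1)
        anchor <- if (cells$column_id[i] == "universal") {
          sample(framework$universal_phrases, 1)
        } else {
          sample(group_phrases[[cells$column_id[i]]], 1)
        }
        s <- sprintf(quality_templates[cells$quality[i]], cp, anchor)
        sent <- c(sent, s)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          rater_id = "truth", doc_id = doc_id,
          concept_id = cells$concept_id[i], column_id = cells$column_id[i],
          quality = as.integer(cells$quality[i]), evidence = s,
          sentence_index = NA_integer_
        )
      }
    }
    if (plan$n_universal_extra > 0) {
      sent <- c(sent, sprintf(
        universal_extra_template,
        sample(framework$universal_phrases, plan$n_universal_extra,
               replace = TRUE)
      ))
    }
    if (plan$n_distractors > 0) {
      sent <- c(sent, sample(distractor_sentences, plan$n_distractors,
                             replace = TRUE))
    }
    ord <- if (length(sent) > 1) sample(length(sent)) else seq_along(sent)
    sent <- sent[ord]
    annotations <- if (length(truth) > 0) {
      ann <- dplyr::bind_rows(truth)
      # truth rows were built in planting order; recover shuffled position
      ann$sentence_index <- vapply(
        seq_len(nrow(ann)), function(k) which(ord == k), integer(1)
      )
      ann
    } else {
      tibble::tibble(
        rater_id = character(), doc_id = character(),
        concept_id = character(), column_id = character(),
        quality = integer(), evidence = character(),
        sentence_index = integer()
      )
    }
  })
  text <- paste(sent, collapse = " ")
  doc <- policy_document(text, doc_id = doc_id, country = country,
                         title = paste("Synthetic policy", doc_id),
                         doc_type = "policy")
  list(
    document = doc,
    annotations = annotations,
    expected = plan_expected_summary(plan, framework, doc_id),
    plan = plan
  )
}

#' Draw a random generation plan
#'
#' Samples a plan with up to `max_cells` planted (concept, column) cells,
#' random qualities 1-4, 1-2 mentions per cell, and a few universal-extra
#' and distractor sentences. Used for property-style end-to-end testing.
#'
#' @param framework An `equiframe_framework`.
#' @param seed Integer seed (also stored in the plan).
#' @param max_cells Maximum number of planted cells.
#' @return An `equiframe_plan`.
#' @export
random_plan <- function(framework, seed, max_cells = 12L) {
  withr::with_seed(seed, {
    n_cells <- sample(0:max_cells, 1)
    cols <- matrix_columns(framework)
    cells <- if (n_cells > 0) {
      pool <- expand.grid(
        concept_id = framework$concepts$concept_id, column_id = cols,
        stringsAsFactors = FALSE
      )
      pick <- pool[sample(nrow(pool), n_cells), , drop = FALSE]
      tibble::tibble(
        concept_id = pick$concept_id, column_id = pick$column_id,
        quality = sample(1:4, n_cells, replace = TRUE),
        n_mentions = sample(1:2, n_cells, replace = TRUE)
      )
    } else NULL
    generation_plan(cells,
                    n_universal_extra = sample(0:3, 1),
                    n_distractors = sample(0:5, 1),
                    seed = seed)
  })
}

# Build a plan whose analytic summary achieves the requested overall
# ranking, by choosing how many groups/concepts/quality-level concepts to
# plant around the 50% criterion.
plan_for_ranking <- function(ranking, framework, seed) {
  counts <- switch(
    ranking,
    High = c(g = 7L, c = 14L, q = 12L),
    Moderate = c(g = 1L, c = 14L, q = 12L),
    Low = c(g = 1L, c = 8L, q = 2L)
  )
  base_groups <- framework$groups$group_id[!framework$groups$country_specific]
  concepts <- framework$concepts$concept_id[seq_len(counts["c"])]
  columns <- c(base_groups[seq_len(counts["g"])],
               rep("universal", counts["c"] - counts["g"]))
  generation_plan(
    tibble::tibble(
      concept_id = concepts,
      column_id = columns,
      quality = c(rep(3L, counts["q"]), rep(1L, counts["c"] - counts["q"])),
      n_mentions = 1L
    ),
    n_universal_extra = 1L, n_distractors = 3L, seed = seed
  )
}

#' Generate a synthetic country corpus with ground truth
#'
#' Generates `n_documents` synthetic policies for one country, either from
#' random plans or following a requested High/Moderate/Low ranking profile
#' (to emulate a country's benchmark table).
#'
#' @param n_documents Number of documents (>= 1).
#' @param framework An `equiframe_framework`.
#' @param seed Integer master seed; per-document seeds are derived from it.
#' @param country Country label.
#' @param rank_profile Optional named integer vector
#'   `c(High = ..., Moderate = ..., Low = ...)` summing to `n_documents`.
#' @return A list: `documents` (named list of `equiframe_document`),
#'   `annotations` (named list of ground-truth tibbles), `expected`
#'   (tibble of per-document expected summaries with a `country` column),
#'   `plans`.
#' @export
generate_country_corpus <- function(n_documents, framework, seed = 1L,
                                    country = "Synthetica",
                                    rank_profile = NULL) {
  stopifnot(n_documents >= 1)
  rankings <- NULL
  if (!is.null(rank_profile)) {
    if (sum(rank_profile) != n_documents) {
      stop("rank_profile must sum to n_documents", call. = FALSE)
    }
    rankings <- rep(names(rank_profile), rank_profile)
  }
  seeds <- seed * 1000L + seq_len(n_documents)
  out <- vector("list", n_documents)
  for (i in seq_len(n_documents)) {
    plan <- if (is.null(rankings)) {
      random_plan(framework, seeds[i])
    } else {
      plan_for_ranking(rankings[i], framework, seeds[i])
    }
    out[[i]] <- generate_document(
      plan, framework, doc_id = sprintf("%s-%03d", country, i),
      country = country
    )
  }
  expected <- dplyr::bind_rows(lapply(out, `[[`, "expected"))
  expected$country <- country
  list(
    documents = stats::setNames(lapply(out, `[[`, "document"),
                                expected$doc_id),
    annotations = stats::setNames(lapply(out, `[[`, "annotations"),
                                  expected$doc_id),
    expected = expected,
    plans = lapply(out, `[[`, "plan")
  )
}

#' Run the full pipeline on one synthetic document
#'
#' Convenience wrapper used in validation: detect candidate mentions, pair
#' them, confirm each detected pair at the planted quality from the ground
#' truth (standing in for the human rater), build the score matrix, and
#' summarize. With truthful confirmation the result should equal the plan's
#' expected summary exactly.
#'
#' @param generated Result of [generate_document()].
#' @param framework An `equiframe_framework`.
#' @return One-row summary tibble from [summarize_policy()].
#' @export
recover_summary <- function(generated, framework) {
  doc <- generated$document
  truth <- generated$annotations
  cand <- detect_mentions(doc, framework)
  pairs <- pair_mentions(cand)
  if (nrow(pairs) == 0) {
    return(summarize_policy(
      build_matrix(truth[0, ], framework, doc_id = doc$doc_id), framework
    ))
  }
  # rater confirmation: keep pairs that correspond to a planted cell and
  # adopt the planted quality; spurious pairs would be rejected (quality 0)
  key <- paste(pairs$concept_id, pairs$column_id, pairs$sentence_index)
  tkey <- paste(truth$concept_id, truth$column_id, truth$sentence_index)
  quality <- truth$quality[match(key, tkey)]
  confirmed <- tibble::tibble(
    rater_id = "rater-1", doc_id = pairs$doc_id,
    concept_id = pairs$concept_id, column_id = pairs$column_id,
    quality = quality, evidence = pairs$evidence,
    sentence_index = pairs$sentence_index
  )
  confirmed <- confirmed[!is.na(confirmed$quality), , drop = FALSE]
  summarize_policy(
    build_matrix(confirmed, framework, doc_id = doc$doc_id), framework
  )
}
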