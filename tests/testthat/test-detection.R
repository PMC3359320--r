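# Exhaustive oracle: scan every (sentence, phrase) combination with a plain
# lowercase regex search, independent of detect_mentions' internals.
brute_force_candidates <- function(doc, fw) {
  phrases <- rbind(
    data.frame(category = "concept",
               target_id = rep(fw$concepts$concept_id,
                               lengths(fw$concepts$key_phrases)),
               phrase = unlist(fw$concepts$key_phrases)),
    data.frame(category = "group",
               target_id = rep(fw$groups$group_id,
                               lengths(fw$groups$key_phrases)),
               phrase = unlist(fw$groups$key_phrases)),
    data.frame(category = "universal", target_id = NA_character_,
               phrase = fw$universal_phrases)
  )
  hits <- list()
  for (i in seq_len(nrow(doc$sentences))) {
    low <- tolower(doc$sentences$text[i])
    for (j in seq_len(nrow(phrases))) {
      pat <- paste0("(^|[^a-z0-9])",
                    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrases$phrase[j]),
                    "($|[^a-z0-9])")
      if (grepl(pat, low)) {
        hits[[length(hits) + 1L]] <- cbind(sentence_index = i, phrases[j, ])
      }
    }
  }
  do.call(rbind, hits)
}

test_that("detection finds universal, concept and group phrases", {
  doc <- policy_document("Services shall be available to all people.", "d1")
  cand <- detect_mentions(doc, fw_default)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$category, "universal")
  expect_equal(cand$matched_phrase, "all people")

  empty <- policy_document("", "d0")
  expect_equal(nrow(detect_mentions(empty, fw_default)), 0L)

  # matching is case-insensitive, word-bounded, no stemming
  doc2 <- policy_document(
    "EVERYONE is served. Accessing records is unrelated. The youthful spirit endures.",
    "d2"
  )
  cand2 <- detect_mentions(doc2, fw_default)
  expect_equal(cand2$matched_phrase, "everyone")
})

test_that("planted phrases are detected exactly, matching the scan oracle", {
  for (seed in c(2, 11, 23)) {
    g <- generate_document(random_plan(fw_default, seed), fw_default)
    cand <- detect_mentions(g$document, fw_default)
    oracle <- brute_force_candidates(g$document, fw_default)
    if (is.null(oracle)) {
      expect_equal(nrow(cand), 0L)
    } else {
      expect_equal(
        sort(paste(cand$sentence_index, cand$category, cand$target_id,
                   cand$matched_phrase)),
        sort(paste(oracle$sentence_index, oracle$category, oracle$target_id,
                   oracle$phrase))
      )
    }
    # determinism
    expect_identical(cand, detect_mentions(g$document, fw_default))
  }
})

test_that("adding sentences never removes previously detected candidates", {
  g <- generate_document(random_plan(fw_default, 5), fw_default)
  base <- detect_mentions(g$document, fw_default)
  extended <- policy_document(
    paste(g$document$text,
          "The ministry shall implement specific actions to advance access for youth."),
    g$document$doc_id
  )
  cand2 <- detect_mentions(extended, fw_default)
  key <- function(df) paste(df$sentence_index, df$category, df$target_id,
                            df$matched_phrase)
  expect_true(all(key(base) %in% key(cand2)))
  expect_gt(nrow(cand2), nrow(base))
})

test_that("pairing applies the same-sentence rule with Universal fallback", {
  doc <- policy_document(paste(
    "The policy upholds non-discrimination for disabled persons.",
    "Participation is promoted for everyone.",
    "Autonomy and privacy are respected for the aged.",
    "Entitlement is described."
  ), "d1")
  cand <- detect_mentions(doc, fw_default)
  pairs <- pair_mentions(cand)

  pick <- function(concept) pairs$column_id[pairs$concept_id == concept]
  expect_equal(pick("non_discrimination"), "disabled")
  expect_equal(pick("participation"), "universal")  # explicit universal
  # two concepts, one group in one sentence -> cross product (2 pairs)
  expect_equal(pick("autonomy"), "aged")
  expect_equal(pick("privacy"), "aged")
  # no anchor at all: Universal by default, unpaired when disabled
  expect_equal(pick("entitlement"), "universal")
  pairs_strict <- pair_mentions(cand, universal_default = FALSE)
  expect_true(is.na(
    pairs_strict$column_id[pairs_strict$concept_id == "entitlement"]
  ))
})

test_that("a wider pairing window links concepts to neighbouring anchors", {
  doc <- policy_document(paste(
    "Capacity building is a priority.",
    "Refugees deserve attention."
  ), "d1")
  cand <- detect_mentions(doc, fw_default)
  same_sentence <- pair_mentions(cand, universal_default = FALSE)
  expect_true(is.na(same_sentence$column_id[1]))
  windowed <- pair_mentions(cand, window = 1L, universal_default = FALSE)
  expect_equal(windowed$column_id, "displaced_populations")
})

test_that("universal references are counted per occurrence", {
  doc <- policy_document(
    paste(rep("This applies to all people.", 5), collapse = " "), "d1"
  )
  expect_equal(count_universal_references(doc, fw_default), 5L)
  expect_equal(
    count_universal_references(policy_document("", "d0"), fw_default), 0L
  )
  # generator ground truth: planted universal anchors + universal extras
  plan <- generation_plan(
    tibble::tibble(concept_id = "access", column_id = "universal",
                   quality = 1L, n_mentions = 4L),
    n_universal_extra = 19L, n_distractors = 2L, seed = 9
  )
  g <- generate_document(plan, fw_default)
  expect_equal(count_universal_references(g$document, fw_default), 23L)
})
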