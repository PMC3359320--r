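# Build a matrix with exactly n_groups base groups, n_concepts concepts and
# n_quality concepts at level >= 3 (direct construction, no detection).
matrix_from_counts <- function(n_groups, n_concepts, n_quality) {
  stopifnot(n_concepts >= n_groups, n_quality <= n_concepts)
  concepts <- fw_default$concepts$concept_id[seq_len(n_concepts)]
  base_groups <- fw_default$groups$group_id
  cols <- c(base_groups[seq_len(n_groups)],
            rep("universal", max(0, n_concepts - n_groups)))
  qual <- c(rep(3L, n_quality), rep(1L, n_concepts - n_quality))
  build_matrix(ann_rows(concepts, cols[seq_len(n_concepts)], qual),
               fw_default)
}

test_that("coverage and quality percentages match the printed arithmetic", {
  m <- matrix_from_counts(1, 14, 12)
  expect_equal(core_concept_coverage(m, digits = 1), 66.7)
  expect_equal(vulnerable_group_coverage(m, fw_default, digits = 1), 8.3)
  expect_equal(core_concept_quality(m, digits = 1), 57.1)

  expect_equal(core_concept_coverage(matrix_from_counts(1, 21, 0)), 100)
  expect_equal(core_concept_coverage(matrix_from_counts(1, 8, 0),
                                     digits = 0), 38)
  expect_equal(
    vulnerable_group_coverage(matrix_from_counts(11, 11, 0), fw_default,
                              digits = 0), 92
  )
  # all concepts at exactly 2: mentioned but below the quality threshold
  m2 <- build_matrix(
    ann_rows(fw_default$concepts$concept_id, "universal", 2), fw_default
  )
  expect_equal(core_concept_coverage(m2), 100)
  expect_equal(core_concept_quality(m2), 0)

  expect_error(core_concept_coverage(m, denominator = 0), "denominator")
  expect_error(vulnerable_group_coverage(m, denominator = -1), "denominator")
})

test_that("half-up rounding matches printed display values", {
  expect_equal(round_half_up(100 / 12, 1), 8.3)   # not ceiling's 8.4
  expect_equal(round_half_up(8.35, 1), 8.4)       # not banker's 8.3... (8.3)
  expect_equal(round_half_up(1400 / 21, 1), 66.7)
  expect_equal(round_half_up(800 / 21, 0), 38)
  expect_equal(round_half_up(1100 / 12, 0), 92)
  expect_equal(round_half_up(-2.5, 0), -3)
})

test_that("the Universal column counts for concepts but never for groups", {
  ann <- rbind(ann_rows("access", "universal", 3),
               ann_rows("privacy", "universal", 1))
  m <- build_matrix(ann, fw_default)
  expect_equal(vulnerable_group_coverage(m, fw_default), 0)
  expect_equal(core_concept_coverage(m, digits = 1),
               round_half_up(200 / 21, 1))
})

test_that("country-specific extras are excluded from the base-12 coverage", {
  cfg <- yaml::read_yaml(default_framework_path())
  cfg$vulnerable_groups[[13]] <- list(
    group_id = "extra_group", name = "Extra group", definition = "x",
    key_phrases = list("extra group"), country_specific = TRUE
  )
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  fw13 <- load_framework(tmp)
  ann <- rbind(ann_rows("access", "extra_group", 3),
               ann_rows("privacy", "youth", 1))
  m <- build_matrix(ann, fw13)
  expect_equal(vulnerable_group_coverage(m, fw13, digits = 1), 8.3)
  expect_equal(dim(m$scores), c(21L, 14L))
})

test_that("overall ranking counts indices at or above the 50% criterion", {
  expect_equal(as.character(overall_ranking(8.3, 66.7, 57.1)), "Moderate")
  expect_equal(as.character(overall_ranking(83, 90, 62)), "High")
  expect_equal(as.character(overall_ranking(25, 24, 24)), "Low")
  expect_equal(as.character(overall_ranking(50, 50, 50)), "High")
  expect_equal(as.character(overall_ranking(50, 50, 49.9)), "Moderate")
  expect_error(overall_ranking(-1, 50, 50), "0, 100")
  expect_error(overall_ranking(10, 101, 50), "0, 100")
  # ranking is monotone in each index
  ranks <- c(Low = 1, Moderate = 2, High = 3)
  withr::with_seed(42, {
    for (i in 1:50) {
      v <- runif(3, 0, 100)
      bump <- pmin(v + c(runif(1, 0, 100 - v[1]), 0, 0), 100)
      expect_true(
        ranks[as.character(overall_ranking(bump[1], v[2], v[3]))] >=
          ranks[as.character(overall_ranking(v[1], v[2], v[3]))]
      )
    }
  })
})

test_that("summarize_policy ranks on full precision and rounds for display", {
  s <- summarize_policy(matrix_from_counts(1, 14, 12), fw_default)
  expect_equal(
    unlist(s[c("vg_pct", "cc_pct", "cc_quality_pct")], use.names = FALSE),
    c(8.3, 66.7, 57.1)
  )
  expect_equal(as.character(s$ranking), "Moderate")
  expect_equal(s[c("n_groups", "n_concepts", "n_quality")],
               tibble::tibble(n_groups = 1L, n_concepts = 14L,
                              n_quality = 12L))

  s0 <- summarize_policy(build_matrix(ann_rows(character(), character(),
                                               integer())[0, ], fw_default,
                                      doc_id = "d0"), fw_default)
  expect_equal(unlist(s0[c("vg_pct", "cc_pct", "cc_quality_pct")],
                      use.names = FALSE), c(0, 0, 0))
  expect_equal(as.character(s0$ranking), "Low")
})

test_that("200 random matrices agree with an independent recount oracle", {
  for (seed in 1:200) {
    m <- random_matrix(seed)
    s <- summarize_policy(m, fw_default)
    o <- recount_indices(m)
    expect_equal(s$n_groups, o$n_groups)
    expect_equal(s$n_concepts, o$n_concepts)
    expect_equal(s$n_quality, o$n_quality)
    expect_equal(s$vg_full, 100 * o$n_groups / 12)
    expect_equal(s$cc_full, 100 * o$n_concepts / 21)
    expect_equal(s$cc_quality_full, 100 * o$n_quality / 21)
    # structural invariant: quality never exceeds coverage
    expect_true(s$cc_quality_full <= s$cc_full)
  }
})

test_that("excluding not-applicable concepts shrinks the denominator", {
  ann <- rbind(ann_rows("access", "youth", 3),
               ann_rows("liberty", NA_character_, NA_integer_))
  m <- build_matrix(ann, fw_default)
  expect_equal(core_concept_coverage(m), 100 / 21)
  expect_equal(core_concept_coverage(m, denominator = NULL), 100 / 20)
  s <- summarize_policy(m, fw_default, cc_denominator = NULL)
  expect_equal(s$cc_denominator, 20)
})

test_that("percentages are invariant to annotation order and rater labels", {
  ann <- random_annotations(30, 19)
  s1 <- summarize_policy(build_matrix(ann, fw_default), fw_default)
  relabeled <- withr::with_seed(1, ann[sample(nrow(ann)), ])
  relabeled$rater_id <- "someone-else"
  s2 <- summarize_policy(build_matrix(relabeled, fw_default), fw_default)
  expect_equal(s1[-1], s2[-1])
})
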