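test_that("identical annotation sets agree perfectly", {
  ann <- random_annotations(20, 3, doc_id = "d1")
  ann_b <- ann
  ann_b$rater_id <- "r2"
  cmp <- compare_raters(ann, ann_b, fw_default)
  expect_equal(cmp$cell_agreement, 1)
  expect_equal(cmp$kappa, 1)
  expect_equal(nrow(cmp$discrepancies), 0L)
})

test_that("disjoint annotation sets agree on nothing over the union", {
  a <- ann_rows("access", "youth", 3, rater_id = "r1")
  b <- ann_rows("privacy", "aged", 2, rater_id = "r2")
  cmp <- compare_raters(a, b, fw_default)
  expect_equal(cmp$n_compared, 2L)
  expect_equal(cmp$cell_agreement, 0)
  expect_equal(nrow(cmp$discrepancies), 2L)
  expect_true(all(c("absent") %in%
                    c(cmp$discrepancies$outcome_a,
                      cmp$discrepancies$outcome_b)))
})

test_that("perturbing k of n cells gives agreement (n - k) / n", {
  withr::with_seed(11, {
    n <- 12
    cells <- expand.grid(
      concept_id = fw_default$concepts$concept_id[1:4],
      column_id = c("youth", "aged", "universal"),
      stringsAsFactors = FALSE
    )
    a <- ann_rows(cells$concept_id, cells$column_id,
                  sample(1:4, n, replace = TRUE))
    for (k in c(0, 3, 7)) {
      b <- a
      b$rater_id <- "r2"
      if (k > 0) {
        flip <- sample(n, k)
        b$quality[flip] <- ((b$quality[flip]) %% 4L) + 1L # always different
      }
      cmp <- compare_raters(a, b, fw_default)
      expect_equal(cmp$n_compared, n)
      expect_equal(cmp$cell_agreement, (n - k) / n)
      expect_equal(nrow(cmp$discrepancies), k)
    }
  })
})

test_that("comparison statistics are symmetric in the two raters", {
  a <- random_annotations(15, 5)
  b <- random_annotations(12, 6)
  b$rater_id <- "r2"
  ab <- compare_raters(a, b, fw_default)
  ba <- compare_raters(b, a, fw_default)
  expect_equal(ab$cell_agreement, ba$cell_agreement)
  expect_equal(ab$kappa, ba$kappa)
  expect_equal(ab$n_compared, ba$n_compared)
})

test_that("kappa matches the closed form on a hand-computed 2x2 fixture", {
  # 20 paired judgments over categories {1, 3}:
  #        b=1  b=3
  #  a=1    9    1   -> po = (9 + 6)/20 = 0.75
  #  a=3    4    6      pe = 0.5*0.65 + 0.5*0.35 = 0.5
  a <- c(rep("1", 10), rep("3", 10))
  b <- c(rep("1", 9), "3", rep("1", 4), rep("3", 6))
  expect_equal(cohen_kappa(a, b), (0.75 - 0.5) / (1 - 0.5))
  # degenerate: one category, full agreement
  expect_equal(cohen_kappa(c("1", "1"), c("1", "1")), 1)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(8, {
    a <- sample(c("absent", "1", "2", "3", "4", "NA"), 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.6, a,
                sample(c("absent", "1", "2", "3", "4", "NA"), 60,
                       replace = TRUE))
    cats <- sort(union(a, b))
    tab <- table(factor(a, cats), factor(b, cats))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa)
  })
})

test_that("mismatched documents are rejected", {
  a <- ann_rows("access", "youth", 1, doc_id = "d1")
  b <- ann_rows("access", "youth", 1, doc_id = "d2", rater_id = "r2")
  expect_error(compare_raters(a, b, fw_default), "different documents")
})

test_that("consensus passes agreement through and applies resolutions", {
  a <- rbind(ann_rows("access", "youth", 3),
             ann_rows("privacy", "universal", 2))
  b <- a
  b$rater_id <- "r2"
  cons <- build_consensus(a, b, fw_default)
  expect_equal(unique(cons$rater_id), "consensus")
  expect_equal(nrow(cons), 2L)
  expect_setequal(cons$quality, c(3L, 2L))
  # consensus of identical sets scores like either input
  m_cons <- build_matrix(cons, fw_default)
  m_a <- build_matrix(a, fw_default)
  expect_equal(m_cons$scores, m_a$scores)

  # one discrepancy resolved to rater A's score
  b2 <- rbind(ann_rows("access", "youth", 1, rater_id = "r2"),
              ann_rows("privacy", "universal", 2, rater_id = "r2"))
  expect_error(build_consensus(a, b2, fw_default), "unresolved")
  res <- tibble::tibble(concept_id = "access", column_id = "youth",
                        resolution = "a")
  cons2 <- build_consensus(a, b2, fw_default, res)
  expect_equal(cons2$quality[cons2$concept_id == "access"], 3L)
})

test_that("a scripted discrepancy set resolves cell-by-cell as scripted", {
  cells <- expand.grid(
    concept_id = c("access", "privacy", "liberty"),
    column_id = c("youth", "universal"),
    stringsAsFactors = FALSE
  )
  a <- ann_rows(cells$concept_id, cells$column_id, rep(3L, 6))
  b <- ann_rows(cells$concept_id, cells$column_id, rep(1L, 6),
                rater_id = "r2")
  script <- tibble::tibble(
    concept_id = cells$concept_id, column_id = cells$column_id,
    resolution = c("a", "b", "2", "4", "absent", "b")
  )
  cons <- build_consensus(a, b, fw_default, script)
  got <- stats::setNames(
    cons$quality,
    paste(cons$concept_id, cons$column_id)
  )
  expect_equal(unname(got[paste(cells$concept_id[1], cells$column_id[1])]), 3L)
  expect_equal(unname(got[paste(cells$concept_id[2], cells$column_id[2])]), 1L)
  expect_equal(unname(got[paste(cells$concept_id[3], cells$column_id[3])]), 2L)
  expect_equal(unname(got[paste(cells$concept_id[4], cells$column_id[4])]), 4L)
  expect_false(paste(cells$concept_id[5], cells$column_id[5]) %in% names(got))
  expect_equal(unname(got[paste(cells$concept_id[6], cells$column_id[6])]), 1L)
})
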