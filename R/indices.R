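#' Round half away from zero
#'
#' Percentage displays in framework reports use arithmetic ("half-up")
#' rounding, not banker's rounding: 8.35 at one decimal is 8.4 and
#' 1/12 = 8.333 is 8.3.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # the 1e-8 nudge keeps decimal halves (e.g. 8.35) on the up side despite
  # binary representation error
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

check_denominator <- function(denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1 ||
      is.na(denominator) || denominator <= 0) {
    stop("denominator must be a single positive number", call. = FALSE)
  }
  invisible(denominator)
}

concept_row_best <- function(matrix) {
  apply(matrix$scores, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE)
  })
}

#' Core Concept Coverage
#'
#' Percentage of Core Concepts mentioned at least once in the document
#' (in any vulnerable-group column or the Universal column), out of the
#' framework's 21 concepts.
#'
#' @param matrix An `equiframe_matrix`.
#' @param denominator Number of concepts the percentage is taken over;
#'   default 21. Set to `NULL` to exclude not-applicable concepts from the
#'   default denominator.
#' @param digits Display precision passed to [round_half_up()]; use
#'   `Inf` for the full-precision value.
#' @return Percentage in \[0, 100\].
#' @export
core_concept_coverage <- function(matrix, denominator = 21, digits = Inf) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  if (is.null(denominator)) {
    denominator <- nrow(matrix$scores) - length(matrix$na_concepts)
  }
  check_denominator(denominator)
  n <- sum(!is.na(concept_row_best(matrix)))
  pct <- 100 * n / denominator
  if (is.finite(digits)) round_half_up(pct, digits) else pct
}

#' Vulnerable Group Coverage
#'
#' Percentage of the 12 base Vulnerable Groups mentioned at least once in
#' the document. The Universal column never counts toward group coverage,
#' and country-specific extra groups are excluded from both numerator and
#' denominator (report them separately).
#'
#' @param matrix An `equiframe_matrix`.
#' @param framework The `equiframe_framework` the matrix was scored against
#'   (identifies base vs country-specific groups). `NULL` treats every
#'   non-Universal column as a base group.
#' @param denominator Number of base groups; default 12.
#' @param digits Display precision; `Inf` for the full-precision value.
#' @return Percentage in \[0, 100\].
#' @export
vulnerable_group_coverage <- function(matrix, framework = NULL,
                                      denominator = 12, digits = Inf) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  check_denominator(denominator)
  cols <- colnames(matrix$scores)
  base_cols <- setdiff(cols, "universal")
  if (!is.null(framework)) {
    base_cols <- framework$groups$group_id[!framework$groups$country_specific]
    base_cols <- intersect(cols, base_cols)
  }
  sub <- matrix$scores[, base_cols, drop = FALSE]
  n <- sum(apply(sub, 2, function(cc) any(!is.na(cc))))
  pct <- 100 * n / denominator
  if (is.finite(digits)) round_half_up(pct, digits) else pct
}

#' Core Concept Quality
#'
#' Percentage of Core Concepts whose best score in the document is 3 or 4 -
#' that is, concepts for which a specific policy action or an intention to
#' monitor is stated - out of the framework's 21 concepts.
#'
#' @inheritParams core_concept_coverage
#' @return Percentage in \[0, 100\].
#' @export
core_concept_quality <- function(matrix, denominator = 21, digits = Inf) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  if (is.null(denominator)) {
    denominator <- nrow(matrix$scores) - length(matrix$na_concepts)
  }
  check_denominator(denominator)
  best <- concept_row_best(matrix)
  n <- sum(!is.na(best) & best >= 3)
  pct <- 100 * n / denominator
  if (is.finite(digits)) round_half_up(pct, digits) else pct
}

#' Overall Summary Ranking
#'
#' Classifies a policy as High, Moderate or Low from its three summary
#' indices: High if all three are at or above the threshold (default 50%),
#' Moderate if exactly two are, Low otherwise.
#'
#' @param vg_pct,cc_pct,quality_pct The three indices, each in \[0, 100\].
#'   Vectorized: the three vectors are recycled to a common length.
#' @param threshold Criterion percentage, default 50.
#' @return Factor with levels `High`, `Moderate`, `Low`.
#' @examples
#' overall_ranking(8.3, 66.7, 57.1) # Moderate
#' @export
overall_ranking <- function(vg_pct, cc_pct, quality_pct, threshold = 50) {
  vals <- cbind(vg_pct, cc_pct, quality_pct)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 100)) {
    stop("indices must be percentages in [0, 100]", call. = FALSE)
  }
  n_met <- rowSums(vals >= threshold)
  factor(
    ifelse(n_met == 3, "High", ifelse(n_met == 2, "Moderate", "Low")),
    levels = c("High", "Moderate", "Low")
  )
}

#' Summarize a policy document
#'
#' Computes all four summary indices from a score matrix. The three
#' percentages are computed and the ranking applied on full-precision
#' values; rounded display values are reported at `digits` precision.
#'
#' @param matrix An `equiframe_matrix`.
#' @param framework Optional `equiframe_framework` (base-group
#'   identification, see [vulnerable_group_coverage()]).
#' @param cc_denominator,vg_denominator Index denominators (defaults 21 and
#'   12). Pass `cc_denominator = NULL` to exclude not-applicable concepts.
#' @param digits Display precision for the reported percentages (default 1).
#' @param threshold Ranking criterion, default 50.
#' @return A one-row tibble (a policy summary): `doc_id`, the rounded
#'   `vg_pct`, `cc_pct`, `cc_quality_pct`, `ranking`, the full-precision
#'   `*_full` values, the raw counts (`n_groups`, `n_concepts`,
#'   `n_quality`), and the denominators used.
#' @export
summarize_policy <- function(matrix, framework = NULL, cc_denominator = 21,
                             vg_denominator = 12, digits = 1,
                             threshold = 50) {
  stopifnot(inherits(matrix, "equiframe_matrix"))
  vg_full <- vulnerable_group_coverage(matrix, framework,
                                       denominator = vg_denominator)
  cc_full <- core_concept_coverage(matrix, denominator = cc_denominator)
  qu_full <- core_concept_quality(matrix, denominator = cc_denominator)
  best <- concept_row_best(matrix)
  cols <- colnames(matrix$scores)
  base_cols <- setdiff(cols, "universal")
  if (!is.null(framework)) {
    base_cols <- intersect(
      cols, framework$groups$group_id[!framework$groups$country_specific]
    )
  }
  tibble::tibble(
    doc_id = matrix$doc_id,
    vg_pct = round_half_up(vg_full, digits),
    cc_pct = round_half_up(cc_full, digits),
    cc_quality_pct = round_half_up(qu_full, digits),
    ranking = overall_ranking(vg_full, cc_full, qu_full,
                              threshold = threshold),
    vg_full = vg_full, cc_full = cc_full, cc_quality_full = qu_full,
    n_groups = sum(apply(matrix$scores[, base_cols, drop = FALSE], 2,
                         function(x) any(!is.na(x)))),
    n_concepts = sum(!is.na(best)),
    n_quality = sum(!is.na(best) & best >= 3),
    vg_denominator = if (is.null(vg_denominator)) NA_real_ else vg_denominator,
    cc_denominator = if (is.null(cc_denominator)) {
      nrow(matrix$scores) - length(matrix$na_concepts)
    } else cc_denominator
  )
}
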