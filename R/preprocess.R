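# Preprocessing: missing-value filtering, the virtual-control differential
# transform, and the nonstringent Mann-Whitney feature screen.

#' Drop probes with missing values
#'
#' Restricts the matrix to probes measured in every sample; probe order and
#' the sample set are preserved.
#'
#' @param x Expression tibble.
#' @return Expression tibble containing only complete probes.
#' @export
drop_incomplete_probes <- function(x) {
  x <- check_expression(x)
  keep <- stats::complete.cases(x[-1L])
  if (!any(keep)) {
    abort("every probe has at least one missing value; nothing left to analyse")
  }
  x[keep, ]
}

#' Virtual control profile
#'
#' The per-probe arithmetic mean across all samples. Dividing each profile
#' by this cohort-wide reference turns absolute intensities into deviations
#' from the cohort norm. All values must be complete and strictly positive.
#'
#' @param x Expression tibble (complete, positive).
#' @return Tibble with columns `probe_id`, `control`.
#' @export
virtual_control <- function(x) {
  m <- expr_values(x)
  assert_positive(m)
  tibble(probe_id = rownames(m), control = unname(rowMeans(m)))
}

#' Differential transform against a control profile
#'
#' Divides each sample's profile probe-wise by the control profile
#' (defaulting to [virtual_control()] of `x` itself, recomputed over all
#' samples present — including any newly added test sample). Row means of
#' the result against the cohort's own virtual control are exactly 1.
#'
#' @param x Expression tibble (complete, positive).
#' @param control Tibble (`probe_id`, `control`) or `NULL` for the cohort's
#'   own virtual control.
#' @return Tibble of the same shape as `x` holding ratios.
#' @export
differential_transform <- function(x, control = NULL) {
  m <- expr_values(x)
  assert_positive(m)
  if (is.null(control)) control <- virtual_control(x)
  if (!setequal(control$probe_id, rownames(m)) ||
      nrow(control) != nrow(m)) {
    abort("control profile probes do not match the expression matrix")
  }
  ctrl <- control$control[match(rownames(m), control$probe_id)]
  if (any(!is.finite(ctrl)) || any(ctrl <= 0)) {
    abort("control profile must be finite and strictly positive")
  }
  ratios <- m / ctrl
  tibble(probe_id = rownames(m), !!!as.data.frame(ratios))
}

#' Mann-Whitney U test for one probe
#'
#' Rank-sum comparison of two groups of values. The reported statistic is
#' the U count for `group_a` (number of (a, b) pairs with a > b, ties
#' counted half). The p-value is two-sided: the exact distribution when both
#' groups have at most 12 observations and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections. Because the
#' test is rank-based, it gives identical results on raw and on
#' differential values (division by a positive per-probe constant preserves
#' within-probe ordering).
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact `"auto"` (exact iff both sizes <= 12 and no ties),
#'   `"exact"` (exact whenever there are no ties), or `"approx"`.
#' @return One-row tibble with columns `statistic`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3, 4), c(5, 6, 7, 8))  # U = 0, p = 2/70
mann_whitney_u <- function(group_a, group_b,
                           exact = c("auto", "exact", "approx")) {
  exact <- match.arg(exact)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- switch(exact,
    auto   = !ties && length(group_a) <= 12L && length(group_b) <= 12L,
    exact  = !ties,
    approx = FALSE)
  w <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE))
  tibble(statistic = unname(w$statistic), p_value = w$p.value,
         method = if (use_exact) "exact" else "normal_approx")
}

#' Mann-Whitney feature preselection
#'
#' Screens every probe for a control-vs-affected difference with a
#' nonstringent two-sided Mann-Whitney test and flags those at or below
#' `alpha`. Unknown-labelled samples are excluded from the test. This step
#' counters the diluting effect of the many control probes on dense arrays;
#' no multiple-testing correction is applied, deliberately.
#'
#' @param x Expression or differential tibble.
#' @param labels Label tibble; must yield two non-empty known groups.
#' @param alpha Significance level in (0, 1); default 0.1.
#' @param inclusive If `TRUE` (default) a probe with p exactly `alpha` is
#'   selected (p <= alpha); if `FALSE` the threshold is strict.
#' @param exact Passed to [mann_whitney_u()].
#' @return Tibble with columns `probe_id`, `statistic`, `p_value`,
#'   `selected` covering every probe.
#' @export
select_features <- function(x, labels, alpha = 0.1, inclusive = TRUE,
                            exact = c("auto", "exact", "approx")) {
  exact <- match.arg(exact)
  if (!(alpha > 0 && alpha < 1)) {
    abort("alpha must lie strictly between 0 and 1")
  }
  m <- expr_values(x)
  ph <- phenotype_of(colnames(m), labels)
  idx_a <- which(ph == "control")
  idx_b <- which(ph == "affected")
  if (length(idx_a) == 0L || length(idx_b) == 0L) {
    abort("feature selection needs samples in both the control and affected groups")
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    mann_whitney_u(m[i, idx_a], m[i, idx_b], exact = exact)
  })
  res <- dplyr::bind_rows(res)
  tibble(probe_id = rownames(m),
         statistic = res$statistic,
         p_value = res$p_value,
         selected = if (inclusive) res$p_value <= alpha else res$p_value < alpha)
}

#' Write a feature-selection report to TSV
#'
#' @param features Tibble from [select_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

assert_positive <- function(m) {
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(paste0("non-positive or missing intensity at probe ",
                 rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]],
                 "; filter missing values first and supply linear-scale data"))
  }
  invisible(m)
}
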