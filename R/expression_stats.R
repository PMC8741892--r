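#' Nonparametric two-group and k-group comparisons
#'
#' `wilcoxon_rank_sum()` compares two groups of expression values with the
#' Wilcoxon rank sum test: exact enumeration when the combined sample size
#' is at most 20 and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections. `kruskal_wallis()` tests equality of
#' several group distributions (tie-corrected H, chi-square reference with
#' groups - 1 degrees of freedom).
#'
#' @param x,y Numeric value vectors, both nonempty.
#' @param groups A list of at least 2 nonempty numeric vectors.
#' @return A one-row tibble: `statistic` and `p.value` (plus `df` for
#'   `kruskal_wallis()`, and `method` describing the variant used).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p.value # 1/3, exact
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be nonempty.")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !has_ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 method = if (exact) "exact" else "normal approximation")
}

#' @rdname wilcoxon_rank_sum
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(lengths(groups) == 0)) {
    abort("`groups` must be a list of at least 2 nonempty value vectors.")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(values, g)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p.value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities (margins fixed) of every table no more probable than the
#' observed one.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return A one-row tibble with `p.value`.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value # 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    abort("`table` must be 2x2.")
  }
  if (any(!is.finite(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8)) {
    abort("`table` entries must be nonnegative integers.")
  }
  ht <- fisher.test(round(table))
  tibble::tibble(p.value = ht$p.value)
}

#' Cross-tabulate molecular subtype against dichotomized expression
#'
#' Builds the 2x2 contingency table of luminal A / luminal B subtype against
#' low / high biomarker expression (high = strictly above the cutoff, as in
#' [dichotomize()]), ready for [fisher_exact_2x2()].
#'
#' @param annotation A data frame with `sample_id` and `subtype` columns
#'   (subtypes `"luminalA"` / `"luminalB"`; other subtypes are dropped).
#' @param values Biomarker values named by sample id, or aligned with
#'   `annotation` rows.
#' @param cutoff Dichotomization cutoff.
#' @return A 2x2 integer matrix (rows: subtype; columns: low, high).
#' @export
subtype_by_expression_table <- function(annotation, values, cutoff) {
  if (!all(c("sample_id", "subtype") %in% names(annotation))) {
    abort("`annotation` must have `sample_id` and `subtype` columns.")
  }
  keep <- annotation$subtype %in% c("luminalA", "luminalB")
  ann <- annotation[keep, ]
  if (!is.null(names(values))) {
    missing <- setdiff(ann$sample_id, names(values))
    if (length(missing) > 0) {
      abort(paste0("no biomarker value for sample `", missing[1], "`."))
    }
    v <- values[ann$sample_id]
  } else {
    if (length(values) != nrow(annotation)) {
      abort("unnamed `values` must align with `annotation` rows.")
    }
    v <- values[keep]
  }
  if (any(!is.finite(v))) {
    bad <- ann$sample_id[which(!is.finite(v))[1]]
    abort(paste0("missing biomarker value for sample `", bad, "`."))
  }
  high <- dichotomize(v, cutoff)
  tab <- table(factor(ann$subtype, levels = c("luminalA", "luminalB")),
               factor(ifelse(high == 1, "high", "low"),
                      levels = c("low", "high")))
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = list(subtype = c("luminalA", "luminalB"),
                                expression = c("low", "high")))
  out
}

#' Classify patients into biomarker-by-outcome groups
#'
#' Reproduces the four-group outcome classification: the latest observed
#' event time within the high-expression group defines a "cure horizon";
#' every event is group 1 (high) or 3 (low); subjects censored strictly
#' after the horizon are "cured" — group 2 (high) or 4 (low); subjects
#' censored at or before the horizon are ambiguous (they could still have a
#' later onset) and are excluded.
#'
#' @inheritParams neg_log_likelihood
#' @param high A 0/1 vector (or column name in `data`) flagging
#'   high-expression patients.
#' @return `data` with two added columns: `outcome_group` (factor with
#'   levels `"1"`, `"2"`, `"3"`, `"4"`, `"excluded"`) and the attribute-free
#'   column `cure_horizon_years` (the recomputed horizon, identical in all
#'   rows).
#' @export
define_outcome_groups <- function(data, high) {
  validate_survival(data)
  if (is.character(high) && length(high) == 1) {
    if (!high %in% names(data)) abort(paste0("column `", high, "` not found."))
    high <- data[[high]]
  }
  if (length(high) != nrow(data) || !all(high %in% c(0, 1))) {
    abort("`high` must be a 0/1 indicator, one per record.")
  }
  high_events <- data$event == 1 & high == 1
  if (!any(high_events)) {
    abort("no events in the high group: the cure horizon is undefined.")
  }
  horizon <- max(data$time_years[high_events])
  grp <- dplyr::case_when(
    data$event == 1 & high == 1 ~ "1",
    data$event == 1 & high == 0 ~ "3",
    data$time_years > horizon & high == 1 ~ "2",
    data$time_years > horizon & high == 0 ~ "4",
    .default = "excluded"
  )
  out <- tibble::as_tibble(data)
  out$outcome_group <- factor(grp, levels = c("1", "2", "3", "4", "excluded"))
  out$cure_horizon_years <- horizon
  out
}

#' Compare a marker gene between two outcome groups
#'
#' Wilcoxon rank sum comparison of marker expression between two of the
#' four outcome groups (default: group 1, high-expression patients with an
#' event, versus group 3, low-expression patients with an event).
#'
#' @param values Marker expression values, one per record.
#' @param labels Outcome-group labels as produced by
#'   [define_outcome_groups()] (`outcome_group` column or compatible
#'   vector).
#' @param group_a,group_b Labels of the two groups to compare.
#' @return A one-row tibble from [wilcoxon_rank_sum()].
#' @export
compare_marker <- function(values, labels, group_a = "1", group_b = "3") {
  labels <- as.character(labels)
  if (length(values) != length(labels)) {
    abort("`values` and `labels` must be aligned.")
  }
  x <- values[labels == as.character(group_a)]
  y <- values[labels == as.character(group_b)]
  if (length(x) == 0 || length(y) == 0) {
    abort("a comparison group is empty after exclusions.")
  }
  wilcoxon_rank_sum(x, y)
}
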