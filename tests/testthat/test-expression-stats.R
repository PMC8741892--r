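test_that("small-sample Wilcoxon p is the exact enumeration value", {
  out <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(out$p.value, 1 / 3) # 2 of the 6 assignments are as extreme
  expect_equal(out$method, "exact")
})

test_that("identical groups are not distinguishable", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$p.value, 1)
})

test_that("the large-sample Wilcoxon branch matches a hand-coded oracle", {
  withr::local_seed(19)
  for (rep in 1:5) {
    x <- round(stats::rnorm(30, 0, 1), 1) # rounding induces ties
    y <- round(stats::rnorm(30, 0.3, 1), 1)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                 wilcoxon_normal_oracle(x, y), tolerance = 1e-6)
  }
})

test_that("Wilcoxon is invariant to sample order", {
  withr::local_seed(29)
  x <- stats::rnorm(15); y <- stats::rnorm(12)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               wilcoxon_rank_sum(sample(x), sample(y))$p.value)
})

test_that("two-group Kruskal-Wallis approximates the Wilcoxon normal test", {
  withr::local_seed(39)
  x <- stats::rnorm(50); y <- stats::rnorm(50, 0.2)
  kw <- kruskal_wallis(list(x, y))
  expect_equal(kw$df, 1)
  expect_equal(kw$p.value, wilcoxon_normal_oracle(x, y), tolerance = 0.01)
})

test_that("Kruskal-Wallis matches the tie-corrected closed form", {
  withr::local_seed(49)
  groups <- list(round(stats::rnorm(20), 1), round(stats::rnorm(15, 0.5), 1),
                 round(stats::rnorm(25, -0.2), 1))
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  out <- kruskal_wallis(groups)
  expect_equal(out$statistic, h, tolerance = 1e-8)
  expect_equal(out$p.value, stats::pchisq(h, 2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("Fisher's exact test matches its enumeration values", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
  withr::local_seed(59)
  for (rep in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p.value, fisher_enum_oracle(tab),
                 tolerance = 1e-7)
  }
})

test_that("subtype-by-expression tables conserve and classify samples", {
  ann <- tibble::tibble(sample_id = paste0("S", 1:4),
                        subtype = c("luminalA", "luminalA", "luminalB", "luminalB"))
  v <- stats::setNames(c(1, 2, 3, 4), ann$sample_id)
  tab <- subtype_by_expression_table(ann, v, cutoff = 2.5)
  expect_equal(sum(tab), 4)
  expect_equal(unname(tab), matrix(c(2, 0, 0, 2), 2)) # A all low, B all high
  expect_error(subtype_by_expression_table(ann, v[-2], 2.5), "S2")
})

test_that("subtype-shifted panels are detected by Fisher's test", {
  hits <- 0
  for (r in 1:100) {
    panel <- generate_expression_panel(c(luminalA = 29, luminalB = 30),
                                       shift = 1.0, seed = r)
    v <- panel$matrix["BRCA1", ]
    cut <- unname(decile_cutoffs(v)[["50%"]])
    tab <- subtype_by_expression_table(panel$annotation, v, cut)
    if (fisher_exact_2x2(tab)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("outcome groups follow the recomputed cure-horizon rule", {
  d <- tibble::tibble(
    time_years = c(2.0, 5.77, 6.0, 5.77, 4.0, 9.0, 3.0),
    event = c(1L, 1L, 0L, 0L, 0L, 0L, 1L),
    high = c(1L, 1L, 1L, 1L, 1L, 0L, 0L)
  )
  out <- define_outcome_groups(d, "high")
  expect_equal(out$cure_horizon_years[1], 5.77) # latest high-group event
  expect_equal(as.character(out$outcome_group),
               c("1", "1", "2", "excluded", "excluded", "4", "3"))
  # conservation: groups plus exclusions partition the cohort
  expect_equal(sum(table(out$outcome_group)), nrow(d))
  # every event is in group 1 or 3
  expect_true(all(as.character(out$outcome_group[d$event == 1]) %in% c("1", "3")))
})

test_that("a fully observed cohort has no exclusions", {
  withr::local_seed(69)
  d <- tibble::tibble(time_years = stats::rlnorm(20, 1, 0.5),
                      event = rep(1L, 20),
                      high = rep(c(0L, 1L), 10))
  out <- define_outcome_groups(d, "high")
  expect_true(all(as.character(out$outcome_group) %in% c("1", "3")))
  expect_error(define_outcome_groups(dplyr::mutate(d, event = 0L), "high"),
               "no events in the high group")
})

test_that("marker comparisons separate shifted groups and stay calibrated", {
  expect_equal(compare_marker(c(1, 2, 3, 1, 2, 3),
                              c("1", "1", "1", "3", "3", "3"))$p.value, 1)
  expect_error(compare_marker(1:4, c("1", "1", "2", "2")), "empty")
  withr::local_seed(79)
  hits <- 0
  for (r in 1:100) {
    vals <- c(stats::rnorm(30, 1), stats::rnorm(30, 0))
    labs <- rep(c("1", "3"), each = 30)
    if (compare_marker(vals, labs)$p.value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 80)
  # permuted labels give uniform p-values
  vals <- c(stats::rnorm(30, 1), stats::rnorm(30, 0))
  p <- vapply(1:200, function(i) {
    compare_marker(vals, sample(rep(c("1", "3"), each = 30)))$p.value
  }, numeric(1))
  ks <- max(abs(seq_along(p) / length(p) - sort(p)))
  expect_lt(ks, 0.1)
})
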