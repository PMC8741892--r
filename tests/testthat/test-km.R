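test_that("the product-limit estimate matches hand computation", {
  km <- km_overall(tiny_cohort())
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3, 1))
})

test_that("without censoring the curve is one minus the empirical CDF", {
  withr::local_seed(13)
  t <- stats::rlnorm(40, 1, 0.5)
  d <- tibble::tibble(time_years = t, event = 1L)
  km <- km_overall(d)
  expect_equal(km$survival,
               vapply(km$time, function(x) mean(t > x), numeric(1)))
})

test_that("the estimator agrees with the reference product-limit implementation", {
  co <- generate_cohort(preset_config(n = 200, seed = 13))
  km <- km_overall(co$records)
  sf <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                          data = co$records)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv, tolerance = 1e-10)
  expect_equal(km$n_risk, ref$n.risk, tolerance = 1e-10)
  # grouped curves too
  kmg <- km_overall(co$records, group = "high")
  for (g in 0:1) {
    sub <- co$records[co$records$high == g, ]
    sfg <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = sub)
    kg <- kmg[kmg$group == g, ]
    refg <- summary(sfg, times = kg$time)
    expect_equal(kg$survival, refg$surv, tolerance = 1e-10)
  }
})

test_that("susceptibility weights follow their closed form", {
  # pi = 0.5 and S(c | D = 1) = 0.5 at c = 1 under mu = 0, sigma = 1
  st <- fit_stub(cure_design(), estimates = c(0, 0, 0), std_errors = rep(1, 3))
  d <- tibble::tibble(time_years = c(1, 1, 1e6), event = c(1L, 0L, 0L))
  w <- susceptibility_weights(d, st)
  expect_equal(w[1], 1)                    # events are surely susceptible
  expect_equal(w[2], 1 / 3)                # 0.25 / 0.75
  expect_lt(w[3], 1e-6)                    # long event-free follow-up -> cured
})

test_that("unit weights reproduce the overall curve exactly", {
  co <- generate_cohort(preset_config(n = 150, seed = 23))
  k1 <- km_overall(co$records)
  k2 <- km_conditional(co$records, rep(1, 150))
  expect_equal(k2$survival, k1$survival, tolerance = 1e-12)
  expect_equal(k2$n_risk, k1$n_risk, tolerance = 1e-12)
})

test_that("an events-only cohort is insensitive to the fit behind the weights", {
  withr::local_seed(33)
  d <- tibble::tibble(time_years = stats::rlnorm(30, 1, 0.5),
                      event = rep(1L, 30))
  st <- fit_stub(cure_design(), estimates = c(-2, 3, 0.5), std_errors = rep(1, 3))
  w <- susceptibility_weights(d, st)
  expect_true(all(w == 1))
  expect_equal(km_conditional(d, w)$survival, km_overall(d)$survival)
})

test_that("weighted conditional KM medians track the generative location", {
  cfg <- cohort_config(n = 5000, gamma = c("(Intercept)" = 2.249), seed = 2)
  co <- generate_cohort(cfg)
  fit <- cure_fit(co$records, cure_design(), n_restarts = 0)
  w <- susceptibility_weights(co$records, fit)
  kc <- km_conditional(co$records, w)
  med <- kc$time[which(kc$survival <= 0.5)[1]]
  expect_lt(abs(med - exp(2.249)) / exp(2.249), 0.10)
})

test_that("weight and degenerate-input contracts are enforced", {
  d <- tiny_cohort()
  expect_error(km_conditional(d, c(1, 1)), "one entry per record")
  expect_error(km_conditional(d, c(2, 1, 1)), "0, 1")
  expect_error(km_conditional(d, c(0, 0, 0)), "all weights are zero")
  expect_error(km_overall(d, group = factor(rep("a", 3), levels = c("a", "b"))),
               "empty")
})

test_that("curve tables expose step breakpoints and survive CSV round trips", {
  one <- tibble::tibble(time_years = 1, event = 1L)
  tab <- curve_table(km_overall(one))
  expect_equal(nrow(tab), 2) # origin plus the single step
  expect_equal(tab$survival, c(1, 0))

  two <- tibble::tibble(time_years = c(1, 10), event = c(1L, 1L))
  lt <- curve_table(km_overall(two), log_time = TRUE)
  expect_equal(lt$time_years, c(0, log(10)))

  # censoring after the last event extends the final flat segment
  ext <- tibble::tibble(time_years = c(1, 5), event = c(1L, 0L))
  tab2 <- curve_table(km_overall(ext))
  expect_equal(tail(tab2$time_years, 1), 5)
  expect_equal(tail(tab2$survival, 1), 0.5)

  km <- km_overall(generate_cohort(preset_config(n = 80, seed = 43))$records)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(km, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(curve_table(km)))
})

test_that("the overall KM tail approaches the cured fraction under late censoring", {
  # long follow-up window so censoring bites after most susceptible events
  cfg <- cohort_config(n = 5000, gamma = c("(Intercept)" = 2.249),
                       horizon = 60, seed = 3)
  co <- generate_cohort(cfg)
  km <- km_overall(co$records)
  expect_lt(abs(min(km$survival) - 0.672), 0.05)
})
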