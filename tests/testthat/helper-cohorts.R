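# Shared fixtures, all built in code.

# A tiny hand-checkable cohort: event at 1, censored at 2, event at 3.
tiny_cohort <- function() {
  tibble::tibble(time_years = c(1, 2, 3), event = c(1L, 0L, 1L))
}

# Default generative preset: logistic intercept -0.715 (cured fraction
# 0.672), location 2.249 with high effect -1.022, scale -0.545, 15-year
# window.
preset_config <- function(n, seed, ...) {
  cohort_config(n = n, seed = seed, ...)
}

# Same preset without any covariate effect (null biomarker).
null_config <- function(n, seed, ...) {
  cohort_config(n = n, gamma = c("(Intercept)" = 2.249), seed = seed, ...)
}

# Minimal cure_fit stub for exercising Wald/CI/LRT arithmetic on published
# coefficient tables without refitting.
fit_stub <- function(design, estimates, std_errors, loglik = 0,
                     data = tiny_cohort()) {
  k <- length(estimates)
  nm <- curemix:::param_names(design)
  stopifnot(length(nm) == k)
  structure(list(
    params = curemix:::unpack_params(estimates, design),
    design = design,
    coefficients = stats::setNames(estimates, nm),
    loglik = loglik, aic = 2 * k - 2 * loglik, df = k,
    vcov = diag(std_errors^2, k),
    std_errors = stats::setNames(std_errors, nm),
    vcov_available = TRUE, converged = TRUE,
    n = nrow(data), n_events = sum(data$event),
    data = tibble::as_tibble(data)
  ), class = "cure_fit")
}

# Independent normal-approximation Wilcoxon p with tie and continuity
# corrections (oracle for the large-sample branch).
wilcoxon_normal_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
  v <- m * n / 12 * ((m + n + 1) - tie_term)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# Exhaustive Fisher two-sided p by the probability-mass rule.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
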