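#' Model quantities at given covariate values
#'
#' `cure_probability()` returns the lifetime event-free probability
#' `Pr(D = 0 | Z) = 1 / (1 + exp(beta'Z))`, the cured fraction implied by the
#' logistic susceptibility part. `overall_survival()` returns the mixture
#' survival `Pr(T > t | Z) = Pr(D = 1 | Z) S(t | D = 1, Z) + Pr(D = 0 | Z)`,
#' which starts at 1 and plateaus at the cured fraction. `median_event_time()`
#' returns the median event time of susceptible subjects, `exp(gamma'Z)` —
#' the log-logistic median.
#'
#' @param newdata A data frame of covariate values (one row per profile), or
#'   `NULL` for an intercept-only design.
#' @param beta Logistic-part coefficients, intercept first.
#' @param design A [cure_design()]. Defaults to intercept-only.
#' @param t Time in years, `>= 0`. Vectorised (recycled against rows of
#'   `newdata`).
#' @param params A [cure_params()] object.
#'
#' @return A numeric vector.
#' @examples
#' cure_probability(beta = -0.715) # 0.672: the cured fraction
#' median_event_time(cure_params(-0.715, c(2.249, -1.022), -0.545),
#'                   newdata = data.frame(high = 1),
#'                   design = cure_design(location = "high")) # 3.41 years
#' @export
cure_probability <- function(newdata = NULL, beta, design = cure_design()) {
  eta <- linear_predictor(newdata, beta, design$logistic, "logistic")
  plogis(-eta)
}

#' @rdname cure_probability
#' @export
overall_survival <- function(t, newdata = NULL, params, design = cure_design()) {
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and >= 0.")
  }
  check_params_design(params, design)
  eta <- linear_predictor(newdata, params$beta, design$logistic, "logistic")
  mu <- linear_predictor(newdata, params$gamma, design$location, "location")
  sigma <- exp(linear_predictor(newdata, params$alpha, design$scale, "scale"))
  pi_d <- plogis(eta)
  s_cond <- ifelse(t == 0, 1, plogis((log(pmax(t, .Machine$double.xmin)) - mu) / sigma,
                                     lower.tail = FALSE))
  pi_d * s_cond + (1 - pi_d)
}

#' @rdname cure_probability
#' @export
median_event_time <- function(params, newdata = NULL, design = cure_design()) {
  check_params_design(params, design)
  mu <- linear_predictor(newdata, params$gamma, design$location, "location")
  exp(mu)
}

# eta = coef' [1, Z] for one part; newdata may be NULL when the part is
# intercept-only.
linear_predictor <- function(newdata, coefs, terms, part) {
  if (length(coefs) != 1L + length(terms)) {
    abort(paste0("coefficient length ", length(coefs), " does not match the ",
                 part, " part (intercept + ", length(terms), " terms)."))
  }
  if (length(terms) == 0) {
    n <- if (is.null(newdata)) 1L else max(1L, nrow(newdata))
    return(rep(coefs[1], n))
  }
  if (is.null(newdata)) {
    abort(paste0("`newdata` is required: the ", part, " part uses covariate(s) ",
                 paste(terms, collapse = ", "), "."))
  }
  missing <- setdiff(terms, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("covariate `", missing[1], "` missing from `newdata`."))
  }
  X <- part_matrix(newdata, terms)
  drop(X %*% coefs)
}

#' Negative log-likelihood of the mixture cure model
#'
#' For an observed event at time `t` the contribution is
#' `Pr(D = 1 | Z) f(t | Z)`; for a right-censored time it is
#' `Pr(D = 1 | Z) S(t | Z) + Pr(D = 0 | Z)` — a censored subject either has
#' a later event or is cured. Computation is done on the log scale
#' (log-sum-exp for the censored mixture) so the result stays finite for
#' linear predictors up to at least +/- 50.
#'
#' @param data A data frame with `time_years` (> 0), `event` (0/1) and any
#'   covariate columns named by `design`.
#' @param params A [cure_params()] object.
#' @param design A [cure_design()].
#'
#' @return The negative log-likelihood (a finite scalar).
#' @examples
#' d <- data.frame(time_years = 1, event = 1)
#' neg_log_likelihood(d, cure_params(0, 0, 0), cure_design()) # log(8)
#' @export
neg_log_likelihood <- function(data, params, design) {
  check_params_design(params, design)
  validate_survival(data, design_terms(design))
  -sum(record_log_contributions(data, params, design))
}

# Per-record log-likelihood contributions, vectorised.
record_log_contributions <- function(data, params, design) {
  t <- data$time_years
  event <- data$event == 1
  eta <- linear_predictor(data, params$beta, design$logistic, "logistic")
  mu <- linear_predictor(data, params$gamma, design$location, "location")
  log_sigma <- linear_predictor(data, params$alpha, design$scale, "scale")
  sigma <- exp(log_sigma)
  w <- (log(t) - mu) / sigma

  log_pi <- plogis(eta, log.p = TRUE)        # log Pr(D = 1)
  log_cure <- plogis(-eta, log.p = TRUE)     # log Pr(D = 0)
  out <- numeric(length(t))
  if (any(event)) {
    out[event] <- log_pi[event] + dlogis(w[event], log = TRUE) -
      log_sigma[event] - log(t[event])
  }
  if (any(!event)) {
    log_s <- plogis(w[!event], lower.tail = FALSE, log.p = TRUE)
    out[!event] <- log_sum_exp2(log_pi[!event] + log_s, log_cure[!event])
  }
  out
}
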