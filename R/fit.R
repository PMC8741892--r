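#' Kaplan-Meier-based starting values for the mixture cure model
#'
#' The cured fraction is weakly informed by early follow-up, so starting
#' values come from the nonparametric side: the tail of the overall
#' Kaplan-Meier curve proxies the cured fraction (logistic intercept =
#' logit of one minus the tail), the KM-implied conditional median event
#' time gives the location intercept on the log scale, and the spread of
#' log event times gives the scale intercept by logistic quantile matching
#' (the logistic IQR is `2 sigma log 3`). Covariate coefficients start at 0.
#'
#' @inheritParams neg_log_likelihood
#' @return A [cure_params()] object dimensioned to `design`.
#' @export
initial_values <- function(data, design = cure_design()) {
  validate_survival(data, design_terms(design))
  if (sum(data$event) < 1) {
    abort("cannot initialize susceptible-time distribution: no events in `data`.")
  }
  km <- km_overall(data)
  s_tail <- km$survival[nrow(km)]
  c_hat <- min(max(s_tail, 1e-3), 1 - 1e-3)
  beta0 <- qlogis(1 - c_hat)

  # Conditional survival of susceptibles implied by the overall KM:
  # S_cond = (S - c) / (1 - c); its median is the first event time where
  # S drops to or below c + 0.5 (1 - c).
  target <- s_tail + 0.5 * (1 - s_tail)
  idx <- which(km$survival <= target + 1e-12)
  med <- km$time[if (length(idx) > 0) idx[1] else nrow(km)]
  gamma0 <- log(med)

  log_te <- log(data$time_years[data$event == 1])
  iqr <- diff(quantile(log_te, c(0.25, 0.75), names = FALSE, type = 7))
  sigma0 <- iqr / (2 * log(3))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 0.25
  alpha0 <- log(sigma0)

  cure_params(beta = c(beta0, rep(0, length(design$logistic))),
              gamma = c(gamma0, rep(0, length(design$location))),
              alpha = c(alpha0, rep(0, length(design$scale))))
}

#' Fit the logistic-AFT mixture cure model by maximum likelihood
#'
#' Jointly estimates the logistic (susceptibility), AFT location, and scale
#' coefficients by quasi-Newton (BFGS) minimisation of the negative
#' log-likelihood on the unconstrained parameterisation (the scale is
#' modelled through its log). By default the optimiser is started from the
#' Kaplan-Meier-based [initial_values()] plus `n_restarts` jittered
#' restarts, keeping the best maximised likelihood, because mixture
#' likelihoods can be multimodal. Standard errors come from the inverse of
#' a central-difference observed information matrix.
#'
#' @inheritParams neg_log_likelihood
#' @param init Optional [cure_params()] starting values (defaults to
#'   [initial_values()]).
#' @param n_restarts Number of jittered restarts in addition to the base
#'   start.
#' @param jitter_sd Standard deviation of the Gaussian jitter applied to the
#'   starting vector for restarts.
#' @param seed Optional integer; restart jitters are drawn from sub-streams
#'   derived from it, leaving the caller's RNG state untouched.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param maxit Maximum BFGS iterations per start.
#' @param compute_vcov If `FALSE`, skip the Hessian (no standard errors);
#'   useful inside large simulations that only need the likelihood.
#'
#' @return An object of class `cure_fit` with elements `params`, `design`,
#'   `coefficients`, `loglik`, `aic`, `vcov`, `std_errors`, `converged`,
#'   `n`, `n_events`, and the data used. Supports [tidy()], [glance()],
#'   [predict()][predict.cure_fit] and [autoplot()].
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200, seed = 7))
#' fit <- cure_fit(cohort$records, cure_design(location = "high"), seed = 1)
#' glance(fit)
#' @export
cure_fit <- function(data, design = cure_design(), init = NULL,
                     n_restarts = 3, jitter_sd = 0.25, seed = NULL,
                     reltol = 1e-8, maxit = 500, compute_vcov = TRUE) {
  validate_survival(data, design_terms(design))
  n_events <- sum(data$event)
  if (n_events < 2) {
    abort("at least 2 events are required to fit the mixture cure model.")
  }
  warn_sparse_groups(data, design)

  init <- init %||% initial_values(data, design)
  check_params_design(init, design)
  theta0 <- pack_params(init)
  nll <- function(theta) {
    val <- -sum(record_log_contributions(data, unpack_params(theta, design), design))
    if (!is.finite(val)) .Machine$double.xmax / 2 else val
  }
  v0 <- -sum(record_log_contributions(data, init, design))
  if (!is.finite(v0)) {
    abort(paste0("likelihood is not finite at the starting values (nll = ",
                 format(v0), "); supply `init` closer to the data."))
  }

  starts <- list(theta0)
  if (n_restarts > 0) {
    jit <- with_stream(seed, "fit-restarts",
                       matrix(rnorm(n_restarts * length(theta0), sd = jitter_sd),
                              nrow = n_restarts))
    for (k in seq_len(n_restarts)) starts[[k + 1]] <- theta0 + jit[k, ]
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, nll, method = "BFGS",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    abort("optimisation failed from every starting point.")
  }

  theta_hat <- best$par
  loglik <- -best$value
  k <- design_df(design)
  nm <- param_names(design)
  names(theta_hat) <- nm

  vcov <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  se <- setNames(rep(NA_real_, k), nm)
  vcov_ok <- FALSE
  if (compute_vcov) {
    H <- central_hessian(nll, theta_hat)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) >= 0)) {
      dimnames(vc) <- list(nm, nm)
      vcov <- vc
      se <- sqrt(diag(vc))
      vcov_ok <- TRUE
    } else {
      warn("observed information is singular or not positive definite; standard errors unavailable.")
    }
  }

  structure(list(
    params = unpack_params(theta_hat, design),
    design = design,
    coefficients = theta_hat,
    loglik = loglik,
    aic = 2 * k - 2 * loglik,
    df = k,
    vcov = vcov,
    std_errors = se,
    vcov_available = vcov_ok,
    converged = best$convergence == 0,
    n = nrow(data),
    n_events = as.integer(n_events),
    data = tibble::as_tibble(data),
    optim = best[c("convergence", "counts")]
  ), class = "cure_fit")
}

# Observed information by central differences with per-coordinate step
# h_i = 1e-5 * (1 + |theta_i|); symmetrised.
central_hessian <- function(f, theta) {
  p <- length(theta)
  h <- 1e-5 * (1 + abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i < p) {
      for (j in seq((i + 1), p)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

# Cure fractions and late-time tails are weakly identified when a
# covariate-defined group holds very few events.
warn_sparse_groups <- function(data, design, min_events = 5) {
  for (cv in design_terms(design)) {
    v <- data[[cv]]
    if (all(v %in% c(0, 1))) {
      ev <- tapply(data$event, v, sum)
      if (any(ev < min_events)) {
        warn(paste0("fewer than ", min_events, " events in a group defined by `",
                    cv, "`; cure fraction and tail are weakly identified."))
      }
    }
  }
  invisible(NULL)
}

#' @export
print.cure_fit <- function(x, ...) {
  cat("Logistic-AFT mixture cure model fit\n")
  cat("  ", design_label(x$design), "\n", sep = "")
  cat(sprintf("  n = %d (%d events); logLik = %.4f; AIC = %.4f; converged: %s\n",
              x$n, x$n_events, x$loglik, x$aic, x$converged))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a mixture cure model fit
#'
#' @param x A `cure_fit` object.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `part`, `term`,
#'   `estimate`, `std.error`, `statistic` (Wald z), `p.value`, `conf.low`,
#'   `conf.high`.
#' @exportS3Method generics::tidy
tidy.cure_fit <- function(x, conf.level = 0.95, ...) {
  out <- param_table_skeleton(x$design)
  out$estimate <- unname(x$coefficients)
  out$std.error <- unname(x$std_errors)
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * pnorm(abs(out$statistic), lower.tail = FALSE)
  zq <- z_quantile(conf.level)
  out$conf.low <- out$estimate - zq * out$std.error
  out$conf.high <- out$estimate + zq * out$std.error
  out
}

#' Glance at a mixture cure model fit
#'
#' @param x A `cure_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `df`, `n`, `n_events`,
#'   `converged`.
#' @exportS3Method generics::glance
glance.cure_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, df = x$df, n = x$n,
                 n_events = x$n_events, converged = x$converged)
}

#' Predict from a mixture cure model fit
#'
#' @param object A `cure_fit`.
#' @param newdata Data frame of covariate profiles (`NULL` for
#'   intercept-only designs).
#' @param times Evaluation times in years (for survival types).
#' @param type `"overall"` (mixture survival), `"conditional"` (survival of
#'   susceptibles), `"cure"` (lifetime event-free probability) or
#'   `"median"` (median event time of susceptibles, years).
#' @param ... Unused.
#' @return A tibble; survival types have one row per profile x time.
#' @export
predict.cure_fit <- function(object, newdata = NULL, times = NULL,
                             type = c("overall", "conditional", "cure", "median"),
                             ...) {
  type <- match.arg(type)
  design <- object$design
  params <- object$params
  n_prof <- if (is.null(newdata)) 1L else nrow(newdata)
  profile <- seq_len(n_prof)
  if (type == "cure") {
    return(tibble::tibble(profile = profile,
                          cure = cure_probability(newdata, params$beta, design)))
  }
  if (type == "median") {
    return(tibble::tibble(profile = profile,
                          median_years = median_event_time(params, newdata, design)))
  }
  if (is.null(times)) abort("`times` is required for survival predictions.")
  mu <- linear_predictor(newdata, params$gamma, design$location, "location")
  sigma <- exp(linear_predictor(newdata, params$alpha, design$scale, "scale"))
  pi_d <- plogis(linear_predictor(newdata, params$beta, design$logistic, "logistic"))
  grid <- tidyr::expand_grid(profile = profile, time_years = times)
  s_cond <- ifelse(grid$time_years == 0, 1,
                   plogis((log(pmax(grid$time_years, .Machine$double.xmin)) -
                             mu[grid$profile]) / sigma[grid$profile],
                          lower.tail = FALSE))
  grid$survival <- if (type == "conditional") s_cond else {
    pi_d[grid$profile] * s_cond + (1 - pi_d[grid$profile])
  }
  grid
}

#' Plot fitted overall and conditional survival curves
#'
#' @param object A `cure_fit`.
#' @param newdata Covariate profiles to display (default: distinct covariate
#'   rows of the fitting data, or the single intercept-only profile).
#' @param times Time grid in years (default: 200 points spanning follow-up).
#' @param ... Unused.
#' @return A ggplot with one panel per curve type.
#' @exportS3Method ggplot2::autoplot
autoplot.cure_fit <- function(object, newdata = NULL, times = NULL, ...) {
  terms <- design_terms(object$design)
  if (is.null(newdata)) {
    newdata <- if (length(terms) == 0) NULL else
      dplyr::distinct(object$data[, terms, drop = FALSE])
  }
  if (is.null(times)) {
    times <- seq(0, max(object$data$time_years), length.out = 200)
  }
  ov <- predict(object, newdata, times, type = "overall")
  co <- predict(object, newdata, times, type = "conditional")
  df <- dplyr::bind_rows(
    dplyr::mutate(ov, curve = "overall"),
    dplyr::mutate(co, curve = "conditional")
  )
  if (!is.null(newdata)) {
    labs <- apply(newdata, 1, function(r) paste(names(newdata), r, sep = "=", collapse = ","))
    df$group <- factor(labs[df$profile], levels = unique(labs))
  } else {
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_years, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "Years since surgery", y = "Event-free probability",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}
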