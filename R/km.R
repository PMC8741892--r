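#' Kaplan-Meier overall and weighted conditional survival curves
#'
#' `km_overall()` is the standard product-limit estimator of the overall
#' event-free curve (unit weights; censored subjects leave the risk set at
#' their censoring time; at tied times events precede censorings).
#' `km_conditional()` is the probability-weighted product-limit estimator of
#' the conditional event-free curve of the susceptible subpopulation: each
#' subject contributes a (possibly fractional) mass to the risk set —
#' observed events contribute fully, censored subjects contribute their
#' posterior probability of being susceptible, from
#' [susceptibility_weights()]. With all weights equal to 1 the two
#' estimators coincide.
#'
#' @inheritParams neg_log_likelihood
#' @param group Optional name of a grouping column in `data` (or a vector of
#'   labels, one per record); one curve is estimated per group.
#' @param weights Nonnegative weights in `[0, 1]`, one per record.
#'
#' @return A tibble of class `km_curve` with columns `group` (if grouped),
#'   `time`, `n_risk` (weighted risk mass), `n_event` (weighted event
#'   mass), `survival`, plus a `meta` attribute holding per-group starting
#'   mass and last follow-up time.
#' @examples
#' d <- data.frame(time_years = c(1, 2, 3), event = c(1, 0, 1))
#' km_overall(d)$survival # 2/3 then 0
#' @export
km_overall <- function(data, group = NULL) {
  validate_survival(data)
  labels <- resolve_group(data, group)
  km_build(data$time_years, data$event, rep(1, nrow(data)), labels)
}

#' @rdname km_overall
#' @export
km_conditional <- function(data, weights, group = NULL) {
  validate_survival(data)
  if (length(weights) != nrow(data)) {
    abort("`weights` must have one entry per record.")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
    abort("`weights` must lie in [0, 1].")
  }
  if (sum(weights) <= 0) {
    abort("all weights are zero; the conditional curve is undefined.")
  }
  labels <- resolve_group(data, group)
  km_build(data$time_years, data$event, weights, labels)
}

resolve_group <- function(data, group) {
  if (is.null(group)) return(NULL)
  if (is.character(group) && length(group) == 1 && group %in% names(data)) {
    return(data[[group]])
  }
  if (length(group) != nrow(data)) {
    abort("`group` must be a column name or one label per record.")
  }
  group
}

km_build <- function(time, event, weights, labels) {
  if (is.null(labels)) {
    out <- km_curve_one(time, event, weights)
    meta <- tibble::tibble(group = "all", n_start = sum(weights),
                           t_max = max(time))
  } else {
    labs <- if (is.factor(labels)) levels(labels) else unique(labels)
    pieces <- purrr::map(labs, function(g) {
      sel <- labels == g
      if (!any(sel)) abort(paste0("group `", g, "` is empty."))
      dplyr::mutate(km_curve_one(time[sel], event[sel], weights[sel]),
                    group = g, .before = 1)
    })
    out <- dplyr::bind_rows(pieces)
    meta <- tibble::tibble(
      group = as.character(labs),
      n_start = vapply(labs, function(g) sum(weights[labels == g]), numeric(1)),
      t_max = vapply(labs, function(g) max(time[labels == g]), numeric(1))
    )
  }
  attr(out, "meta") <- meta
  class(out) <- c("km_curve", class(out))
  out
}

# Weighted product-limit on one sample. Risk mass at an event time t_j is
# the total weight of subjects with follow-up >= t_j, so tied censorings
# remain at risk (events before censorings at ties).
km_curve_one <- function(time, event, weights) {
  ev_times <- sort(unique(time[event == 1 & weights > 0]))
  if (length(ev_times) == 0) {
    abort("no events: the product-limit curve has no steps.")
  }
  d <- vapply(ev_times, function(tj) sum(weights[event == 1 & time == tj]),
              numeric(1))
  y <- vapply(ev_times, function(tj) sum(weights[time >= tj]), numeric(1))
  keep <- y > 0
  surv <- cumprod(1 - d[keep] / y[keep])
  tibble::tibble(time = ev_times[keep], n_risk = y[keep], n_event = d[keep],
                 survival = surv)
}

#' Posterior susceptibility weights from a fitted mixture cure model
#'
#' Subjects observed with the event are susceptible with certainty (weight
#' 1). A subject censored at `c` is susceptible with posterior probability
#' `pi(Z) S(c | D = 1, Z) / (pi(Z) S(c | D = 1, Z) + 1 - pi(Z))` — the
#' probability of later onset given event-free follow-up to `c`. These are
#' the one-pass weights from the final fit used by [km_conditional()].
#'
#' @inheritParams neg_log_likelihood
#' @param fit A converged [cure_fit()] on compatible covariates.
#' @return A numeric vector of weights in `[0, 1]`, one per record.
#' @export
susceptibility_weights <- function(data, fit) {
  validate_survival(data, design_terms(fit$design))
  if (!isTRUE(fit$converged)) {
    warn("fit did not converge; susceptibility weights may be unreliable.")
  }
  params <- fit$params
  design <- fit$design
  eta <- linear_predictor(data, params$beta, design$logistic, "logistic")
  mu <- linear_predictor(data, params$gamma, design$location, "location")
  sigma <- exp(linear_predictor(data, params$alpha, design$scale, "scale"))
  log_pi <- plogis(eta, log.p = TRUE)
  log_cure <- plogis(-eta, log.p = TRUE)
  log_s <- plogis((log(data$time_years) - mu) / sigma,
                  lower.tail = FALSE, log.p = TRUE)
  num <- log_pi + log_s
  w <- exp(num - log_sum_exp2(num, log_cure))
  ifelse(data$event == 1, 1, w)
}

#' Step-function breakpoints of a Kaplan-Meier curve
#'
#' Flattens a `km_curve` into plottable `(time, survival)` breakpoints: an
#' origin row at `(0, 1)`, one row per step, and a closing row extending the
#' final flat segment to the last follow-up time. With `log_time = TRUE` the
#' exported abscissa is `log(time)` and the origin row is omitted (the
#' origin has no finite log abscissa); only the abscissa is transformed.
#'
#' @param curve A `km_curve` from [km_overall()] or [km_conditional()].
#' @param log_time Export `log(time)` as the abscissa.
#' @return A tibble with columns `group`, `time_years`, `survival`.
#' @export
curve_table <- function(curve, log_time = FALSE) {
  meta <- attr(curve, "meta")
  if (is.null(meta)) abort("`curve` must be a km_curve object.")
  has_group <- "group" %in% names(curve)
  rows_for <- function(g) {
    steps <- if (has_group) curve[curve$group == g, ] else curve
    m <- meta[meta$group == as.character(g), ]
    tm <- c(steps$time)
    sv <- c(steps$survival)
    if (m$t_max > max(tm)) {
      tm <- c(tm, m$t_max)
      sv <- c(sv, sv[length(sv)])
    }
    if (!log_time) {
      tm <- c(0, tm)
      sv <- c(1, sv)
    } else {
      tm <- log(tm)
    }
    tibble::tibble(group = as.character(g), time_years = tm, survival = sv)
  }
  groups <- if (has_group) unique(curve$group) else "all"
  dplyr::bind_rows(purrr::map(groups, rows_for))
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curve`.
#' @param log_time Display time on a logarithmic axis.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, log_time = FALSE, ...) {
  tab <- curve_table(object, log_time = FALSE)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time_years,
                                         y = .data$survival,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since surgery", y = "Event-free probability",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}
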