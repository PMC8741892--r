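# Wald and likelihood-ratio inference for fitted mixture cure models.

# Fixed 97.5% normal quantile so reported 95% intervals are bit-stable.
Z_975 <- 1.959964

z_quantile <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).")
  }
  if (abs(level - 0.95) < 1e-12) Z_975 else qnorm((1 + level) / 2)
}

locate_term <- function(fit, part, term) {
  part <- match.arg(part, c("logistic", "location", "scale"))
  skel <- param_table_skeleton(fit$design)
  idx <- which(skel$part == part & skel$term == term)
  if (length(idx) != 1) {
    abort(paste0("term `", term, "` not found in the ", part, " part of the fitted design."))
  }
  idx
}

#' Wald test for one coefficient of a mixture cure model fit
#'
#' @param fit A [cure_fit()] object.
#' @param part `"logistic"`, `"location"` or `"scale"`.
#' @param term Covariate name (or `"(Intercept)"`).
#' @return A one-row tibble: `part`, `term`, `estimate`, `std.error`,
#'   `statistic` (z = estimate / SE), `p.value` (two-sided normal).
#' @export
wald_test <- function(fit, part, term) {
  idx <- locate_term(fit, part, term)
  se <- unname(fit$std_errors[idx])
  if (!is.finite(se)) {
    abort("standard error unavailable (singular observed information).")
  }
  est <- unname(fit$coefficients[idx])
  z <- est / se
  tibble::tibble(part = part, term = term, estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = 2 * pnorm(abs(unname(z)), lower.tail = FALSE))
}

#' Wald confidence interval for one coefficient
#'
#' @inheritParams wald_test
#' @param level Confidence level in (0, 1); at 0.95 the quantile is fixed to
#'   1.959964.
#' @return A one-row tibble: `part`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `level`.
#' @export
confidence_interval <- function(fit, part, term, level = 0.95) {
  idx <- locate_term(fit, part, term)
  se <- unname(fit$std_errors[idx])
  if (!is.finite(se)) {
    abort("standard error unavailable (singular observed information).")
  }
  zq <- z_quantile(level)
  est <- unname(fit$coefficients[idx])
  tibble::tibble(part = part, term = term, estimate = est,
                 conf.low = est - zq * se, conf.high = est + zq * se,
                 level = level)
}

#' Likelihood ratio test between nested mixture cure model fits
#'
#' The statistic `2 (logLik_full - logLik_null)` is referred to a chi-square
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts. Both fits must be on identical records and the null
#' design must be nested in the full design part by part.
#'
#' @param fit_full,fit_null `cure_fit` objects on the same records.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_null) {
  if (!design_nested(fit_null$design, fit_full$design)) {
    abort("the null design is not nested in the full design.")
  }
  same_records <- fit_full$n == fit_null$n &&
    isTRUE(all.equal(sort(fit_full$data$time_years), sort(fit_null$data$time_years))) &&
    fit_full$n_events == fit_null$n_events
  if (!same_records) {
    abort("fits were not computed on the same records.")
  }
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  # optimizer slack can leave a tiny negative value for equal designs
  stat <- max(stat, 0)
  df <- fit_full$df - fit_null$df
  p <- if (df == 0) {
    if (stat <= 1e-6) 1 else NA_real_
  } else {
    pchisq(stat, df = df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = df, p.value = p)
}

#' Select where a covariate belongs by minimum AIC
#'
#' Fits every candidate design on the same records and returns the fit with
#' the smallest AIC (`2k - 2 logLik`). Ties break deterministically toward
#' fewer parameters, then candidate order. Candidates whose fit fails are
#' recorded and excluded.
#'
#' @inheritParams cure_fit
#' @param designs A list of [cure_design()] objects (at least 2), e.g.
#'   [candidate_designs()].
#' @param ... Passed on to [cure_fit()].
#' @return An object of class `cure_model_selection`: a list with `best`
#'   (the winning `cure_fit`), `table` (tibble ranked by AIC: `candidate`,
#'   `design`, `k`, `loglik`, `aic`, `converged`, `failed`), and `fits`.
#' @export
select_model <- function(data, designs, ...) {
  if (!is.list(designs) || length(designs) < 2) {
    abort("`designs` must be a list of at least 2 candidate designs.")
  }
  fits <- purrr::map(designs, function(d) {
    tryCatch(cure_fit(data, d, ...), error = function(e) e)
  })
  tab <- purrr::imap_dfr(fits, function(f, i) {
    failed <- inherits(f, "error")
    tibble::tibble(
      candidate = i,
      design = design_label(designs[[i]]),
      k = design_df(designs[[i]]),
      loglik = if (failed) NA_real_ else f$loglik,
      aic = if (failed) NA_real_ else f$aic,
      converged = if (failed) NA else f$converged,
      failed = failed,
      message = if (failed) conditionMessage(f) else NA_character_
    )
  })
  ok <- which(!tab$failed)
  if (length(ok) == 0) {
    abort("every candidate design failed to fit.")
  }
  ord <- ok[order(tab$aic[ok], tab$k[ok], tab$candidate[ok])]
  best_idx <- ord[1]
  ranked <- dplyr::bind_rows(tab[ord, ], tab[tab$failed, ])
  structure(list(best = fits[[best_idx]], best_candidate = best_idx,
                 table = ranked, fits = fits),
            class = "cure_model_selection")
}

#' @export
print.cure_model_selection <- function(x, ...) {
  cat("Model selection by minimum AIC over", nrow(x$table), "candidates\n")
  cat("Best:", design_label(x$best$design), "\n")
  print(x$table[, c("candidate", "design", "k", "loglik", "aic", "failed")], ...)
  invisible(x)
}
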