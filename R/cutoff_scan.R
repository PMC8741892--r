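#' Decile cutoffs of a continuous biomarker
#'
#' Empirical quantiles at 10%, ..., 90% using the linear-interpolation
#' ("type 7") convention.
#'
#' @param values Numeric biomarker values (at least 10 finite values).
#' @return A named numeric vector of 9 nondecreasing cutoffs.
#' @examples
#' decile_cutoffs(1:10)[["50%"]] # 5.5
#' @export
decile_cutoffs <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10) {
    abort("at least 10 finite biomarker values are required for decile cutoffs.")
  }
  quantile(values, probs = seq(0.1, 0.9, by = 0.1), type = 7)
}

#' Dichotomize a biomarker at a cutoff
#'
#' High means strictly greater than the cutoff; ties go to the low group
#' (so an 8th-decile cutoff leaves about 20% of samples high).
#'
#' @param values Numeric biomarker values.
#' @param cutoff A single finite cutoff.
#' @return An integer vector of 0/1 indicators (1 = high).
#' @examples
#' dichotomize(c(1, 2, 3), 2) # 0 0 1
#' @export
dichotomize <- function(values, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    abort("`cutoff` must be a single finite number.")
  }
  as.integer(values > cutoff)
}

#' Scan decile cutoffs of a biomarker for the best-fitting mixture model
#'
#' For each requested decile of the biomarker distribution the cohort is
#' dichotomized (high = above the cutoff), the group indicator is offered
#' to each covariate-bearing placement across the three regression parts,
#' and the minimum-AIC placement is retained together with its likelihood
#' ratio test against the covariate-free null (fitted once and shared by
#' all deciles, since it does not depend on the cutoff). The selected
#' cutoff is the decile whose retained fit attains the minimal AIC;
#' Bonferroni-adjusted LRT p-values across the scanned deciles are
#' reported alongside.
#'
#' @inheritParams cure_fit
#' @param biomarker Name of the biomarker column in `data`, or a numeric
#'   vector aligned with its rows.
#' @param deciles Integer deciles to scan, a subset of `1:9`.
#' @param designs Candidate design list for [select_model()]; defaults to
#'   [candidate_designs()] on `covariate_name`. Must include covariate-bearing
#'   designs; the covariate-free null is fitted separately.
#' @param covariate_name Column name under which the high indicator is
#'   attached (default `"high"`).
#' @param min_events Minimum events required in each group for a cutoff to
#'   be fitted; cutoffs below this are marked failed.
#' @param ... Passed to [cure_fit()] / [select_model()].
#'
#' @return An object of class `cutoff_scan`: a list with `per_decile`
#'   (tibble: `decile`, `cutoff`, `n_high`, `design`, `loglik`, `aic`,
#'   `lrt_statistic`, `lrt_df`, `lrt_p`, `lrt_p_bonferroni`, `failed`,
#'   `selected`), `selected_decile`, `null_fit`, `fits` and `metadata`
#'   (quantile type, tie rule, adjustment, weighting policy).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 250, seed = 3))
#' sc <- cutoff_scan(cohort$records, "expr", deciles = c(5, 8),
#'                   designs = candidate_designs("high")[c(1, 3)],
#'                   n_restarts = 0, seed = 1)
#' sc$per_decile
#' @export
cutoff_scan <- function(data, biomarker, deciles = 1:9, designs = NULL,
                        covariate_name = "high", min_events = 2, seed = NULL,
                        ...) {
  validate_survival(data)
  values <- if (is.character(biomarker) && length(biomarker) == 1) {
    if (!biomarker %in% names(data)) {
      abort(paste0("biomarker column `", biomarker, "` not found in `data`."))
    }
    data[[biomarker]]
  } else {
    if (length(biomarker) != nrow(data)) {
      abort("`biomarker` must be a column name or one value per record.")
    }
    as.numeric(biomarker)
  }
  if (!all(deciles %in% 1:9)) abort("`deciles` must be a subset of 1:9.")
  deciles <- sort(unique(as.integer(deciles)))

  designs <- designs %||% candidate_designs(covariate_name)
  covariate_bearing <- purrr::keep(designs, function(d) length(design_terms(d)) > 0)
  if (length(covariate_bearing) == 0) {
    abort("`designs` must contain at least one covariate-bearing candidate.")
  }

  cutoffs <- decile_cutoffs(values)
  null_fit <- cure_fit(data, cure_design(), seed = seed, ...)

  rows <- list()
  fits <- list()
  for (dec in deciles) {
    cutoff <- unname(cutoffs[[paste0(dec * 10, "%")]])
    high <- dichotomize(values, cutoff)
    n_events_by <- tapply(data$event, high, sum)
    ok <- length(n_events_by) == 2 && all(n_events_by >= min_events)
    row <- tibble::tibble(decile = dec, cutoff = cutoff,
                          n_high = sum(high),
                          design = NA_character_, loglik = NA_real_,
                          aic = NA_real_, lrt_statistic = NA_real_,
                          lrt_df = NA_integer_, lrt_p = NA_real_,
                          failed = TRUE)
    if (ok) {
      data2 <- data
      data2[[covariate_name]] <- high
      best <- tryCatch(
        suppressWarnings(
          if (length(covariate_bearing) == 1) {
            cure_fit(data2, covariate_bearing[[1]], seed = seed, ...)
          } else {
            select_model(data2, covariate_bearing, seed = seed, ...)$best
          }
        ),
        error = function(e) NULL
      )
      if (!is.null(best)) {
        lrt <- likelihood_ratio_test(best, null_fit)
        row$design <- design_label(best$design)
        row$loglik <- best$loglik
        row$aic <- best$aic
        row$lrt_statistic <- lrt$statistic
        row$lrt_df <- as.integer(lrt$df)
        row$lrt_p <- lrt$p.value
        row$failed <- FALSE
        fits[[as.character(dec)]] <- best
      }
    }
    rows[[as.character(dec)]] <- row
  }
  per_decile <- dplyr::bind_rows(rows)
  if (all(per_decile$failed)) {
    abort("every cutoff failed (too few events in a group at each decile).")
  }
  m <- sum(!per_decile$failed)
  per_decile$lrt_p_bonferroni <- pmin(per_decile$lrt_p * m, 1)
  ok_idx <- which(!per_decile$failed)
  sel_idx <- ok_idx[which.min(per_decile$aic[ok_idx])]
  per_decile$selected <- seq_len(nrow(per_decile)) == sel_idx

  structure(list(
    per_decile = per_decile,
    selected_decile = per_decile$decile[sel_idx],
    selected_fit = fits[[as.character(per_decile$decile[sel_idx])]],
    null_fit = null_fit,
    fits = fits,
    metadata = list(
      quantile_type = 7L,
      tie_rule = "ties at the cutoff go to the low group",
      adjustment = "bonferroni",
      null_model = "single covariate-free fit shared across deciles",
      conditional_weights = "one-pass from the final fit"
    )
  ), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("Decile cutoff scan (min-AIC selection; Bonferroni-adjusted LRT p)\n")
  cat("Selected decile:", x$selected_decile, "\n")
  print(x$per_decile, ...)
  invisible(x)
}

#' Plot AIC and LRT p-value trends across scanned deciles
#'
#' @param object A `cutoff_scan`.
#' @param ... Unused.
#' @return A ggplot with AIC and -log10 LRT p by decile.
#' @exportS3Method ggplot2::autoplot
autoplot.cutoff_scan <- function(object, ...) {
  df <- object$per_decile[!object$per_decile$failed, ]
  long <- dplyr::bind_rows(
    tibble::tibble(decile = df$decile, value = df$aic, panel = "AIC"),
    tibble::tibble(decile = df$decile, value = -log10(df$lrt_p),
                   panel = "-log10 LRT p")
  )
  sel <- object$selected_decile
  ggplot2::ggplot(long, ggplot2::aes(x = .data$decile, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "Biomarker decile cutoff", y = NULL)
}
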