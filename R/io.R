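#' Read and write the survival CSV dialect
#'
#' The on-disk format has header `id,time_years,event,<covariate...>`.
#' Reading validates every row (positive finite follow-up time, 0/1 event,
#' no missing values in any column) and errors cite the offending data row.
#'
#' @param path File path.
#' @param data A survival data frame (first columns `id`, `time_years`,
#'   `event`).
#' @return `read_survival_csv()` returns a validated tibble;
#'   `write_survival_csv()` returns `path` invisibly.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "time_years", "event")
  if (!identical(names(data)[1:3], required)) {
    abort("survival CSV must start with columns `id,time_years,event`.")
  }
  for (col in names(data)) {
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0) {
      abort(paste0("missing value in column `", col, "` at row ", bad[1], "."))
    }
  }
  validate_survival(data, setdiff(names(data), c("id", "time_years", "event")))
  data
}

#' @rdname read_survival_csv
#' @export
write_survival_csv <- function(data, path) {
  validate_survival(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic cohort with its latent-truth sidecar
#'
#' Writes the records as a survival CSV and the generative truths (true
#' coefficients, per-group cure probabilities and medians, seed) as a JSON
#' sidecar named `<stem>.truth.json` beside it.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_survival_csv(cohort$records, path)
  truth_path <- sub("\\.csv$", "", path)
  truth_path <- paste0(truth_path, ".truth.json")
  cfg <- cohort$config
  payload <- list(
    seed = cfg$seed, n = cfg$n,
    beta = as.list(cfg$beta), gamma = as.list(cfg$gamma),
    alpha = as.list(cfg$alpha),
    true_cutoff_decile = cfg$true_cutoff_decile,
    horizon_years = cfg$horizon,
    truth = cohort$truth
  )
  jsonlite::write_json(payload, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, truth = truth_path))
}

#' Read and write gene-by-sample expression TSV
#'
#' First column `gene_id`, remaining columns one per sample. Duplicate gene
#' or sample labels and ragged rows are rejected.
#'
#' @param path File path.
#' @param matrix A numeric matrix with gene rownames and sample colnames.
#' @return `read_expression_tsv()` returns a numeric matrix with gene
#'   rownames; `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(readr::problems(data)) > 0) {
    abort(paste0("malformed expression TSV (ragged or unparseable rows): ", path))
  }
  if (names(data)[1] != "gene_id") {
    abort("expression TSV must have `gene_id` as its first column.")
  }
  if (anyDuplicated(data$gene_id)) {
    abort(paste0("duplicate gene id: ",
                 data$gene_id[duplicated(data$gene_id)][1]))
  }
  if (anyDuplicated(names(data))) {
    abort("duplicate sample ids in the header.")
  }
  m <- as.matrix(data[, -1])
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("expression values must all be finite numbers.")
  }
  rownames(m) <- data$gene_id
  m
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write fit and scan reports
#'
#' `write_fit_report()` writes a coefficient table CSV laid out like a
#' published mixture-model table (columns `part`, `term`, `estimate`,
#' `ci_low`, `ci_high`, `wald_p`, formatted to 3 decimals) plus a JSON
#' summary at full precision (`loglik`, `aic`, `n`, `n_events`,
#' `converged`, optional `lrt_p`). `write_scan_report()` writes the
#' per-decile scan table plus a JSON metadata sidecar recording the
#' reproducibility conventions (quantile type, tie rule, adjustment).
#' Outputs are deterministic given identical inputs.
#'
#' @param fit A `cure_fit`.
#' @param path Output CSV path (the JSON summary is written beside it with
#'   extension `.json`).
#' @param lrt_p Optional likelihood-ratio p-value to include in the JSON
#'   summary.
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, path, lrt_p = NULL) {
  td <- tidy(fit)
  out <- tibble::tibble(
    part = td$part, term = td$term,
    estimate = sprintf("%.3f", td$estimate),
    ci_low = sprintf("%.3f", td$conf.low),
    ci_high = sprintf("%.3f", td$conf.high),
    wald_p = sprintf("%.3f", td$p.value)
  )
  readr::write_csv(out, path, progress = FALSE)
  json_path <- paste0(sub("\\.csv$", "", path), ".json")
  payload <- list(loglik = fit$loglik, aic = fit$aic, n = fit$n,
                  n_events = fit$n_events, converged = fit$converged,
                  design = design_label(fit$design))
  if (!is.null(lrt_p)) payload$lrt_p <- lrt_p
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}

#' @rdname write_fit_report
#' @param scan A `cutoff_scan`.
#' @export
write_scan_report <- function(scan, path) {
  stopifnot(inherits(scan, "cutoff_scan"))
  readr::write_csv(scan$per_decile, path, progress = FALSE)
  json_path <- paste0(sub("\\.csv$", "", path), ".json")
  payload <- c(list(selected_decile = scan$selected_decile), scan$metadata)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}

#' Export a Kaplan-Meier curve as CSV breakpoints
#'
#' Columns `group,time_years,survival`; with `log_time = TRUE` the abscissa
#' column holds `log(time)` (export-only transform, see [curve_table()]).
#'
#' @param curve A `km_curve`.
#' @param path Output CSV path.
#' @param log_time Export a logarithmic abscissa.
#' @return Invisibly, `path`.
#' @export
write_curve_csv <- function(curve, path, log_time = FALSE) {
  readr::write_csv(curve_table(curve, log_time = log_time), path,
                   progress = FALSE)
  invisible(path)
}
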