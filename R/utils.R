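# Internal helpers shared across modules.

# Deterministic sub-seed derived from a root seed and a stream label, kept
# below .Machine$integer.max so it is always a valid set.seed() argument.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 65536 * 7919 + h * 131) %% 2147483647L)
}

# Evaluate `code` under a labelled sub-stream of `seed`, restoring the
# caller's RNG state afterwards. A NULL seed uses (and advances) the
# caller's RNG.
with_stream <- function(seed, label, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, label))
  force(code)
}

# log(exp(a) + exp(b)) without overflow, vectorised.
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Validate a survival data frame: time_years > 0 finite, event in {0, 1},
# all model covariates finite. Errors cite the offending row.
validate_survival <- function(data, covariates = character()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of survival records.")
  }
  for (col in c("time_years", "event")) {
    if (!col %in% names(data)) {
      abort(paste0("`data` must contain a `", col, "` column."))
    }
  }
  t <- data$time_years
  bad <- which(!is.finite(t) | t <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "`time_years` must be finite and > 0; first violation at row ", bad[1],
      " (value ", format(t[bad[1]]), "). Events at time 0 are rejected, not shifted."
    ))
  }
  e <- data$event
  bad <- which(!(e %in% c(0, 1)))
  if (length(bad) > 0) {
    abort(paste0("`event` must be 0 or 1; first violation at row ", bad[1], "."))
  }
  for (cv in covariates) {
    if (!cv %in% names(data)) {
      abort(paste0("covariate `", cv, "` not found in `data`."))
    }
    v <- data[[cv]]
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(paste0("covariate `", cv, "` must be finite; first violation at row ",
                   bad[1], "."))
    }
  }
  invisible(data)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
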