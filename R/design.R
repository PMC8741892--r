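#' Specify which covariates enter each regression part
#'
#' The mixture cure model has three regression parts: a logistic part for
#' the susceptibility probability `Pr(D = 1 | Z)`, an AFT location part for
#' the centre of log event time, and a scale part for its spread (modelled
#' through `log sigma` so positivity is automatic). Each part always
#' contains an intercept; `cure_design()` names the additional covariates
#' that enter each part.
#'
#' @param logistic,location,scale Character vectors of covariate (column)
#'   names, possibly empty. Intercepts are implicit and always estimated.
#'
#' @return An object of class `cure_design`.
#' @examples
#' cure_design(location = "high")
#' @export
cure_design <- function(logistic = character(), location = character(),
                        scale = character()) {
  parts <- list(logistic = as.character(logistic),
                location = as.character(location),
                scale = as.character(scale))
  for (p in names(parts)) {
    if (anyDuplicated(parts[[p]])) {
      abort(paste0("duplicate covariate names in the ", p, " part."))
    }
  }
  structure(parts, class = "cure_design")
}

#' @export
print.cure_design <- function(x, ...) {
  cat("<cure_design> ", design_label(x), "\n", sep = "")
  invisible(x)
}

design_label <- function(design) {
  fmt <- function(terms) {
    if (length(terms) == 0) "1" else paste(c("1", terms), collapse = " + ")
  }
  paste0("logistic: ", fmt(design$logistic),
         " | location: ", fmt(design$location),
         " | scale: ", fmt(design$scale))
}

design_terms <- function(design) {
  unique(unlist(design, use.names = FALSE))
}

# Number of free parameters (one intercept per part plus named terms).
design_df <- function(design) {
  3L + length(design$logistic) + length(design$location) + length(design$scale)
}

# TRUE when `null` is nested in `full` part by part.
design_nested <- function(null, full) {
  all(vapply(c("logistic", "location", "scale"),
             function(p) all(null[[p]] %in% full[[p]]), logical(1)))
}

#' All placements of one covariate across the three regression parts
#'
#' The candidate universe used for AIC model selection: the eight designs
#' obtained by including or omitting a single group covariate in each of the
#' logistic, location and scale parts (including total absence, the
#' covariate-free null).
#'
#' @param covariate Name of the binary group covariate.
#' @return A list of eight `cure_design` objects, the covariate-free design
#'   first.
#' @examples
#' length(candidate_designs("high"))
#' @export
candidate_designs <- function(covariate) {
  stopifnot(is.character(covariate), length(covariate) == 1)
  grid <- expand.grid(logistic = c(FALSE, TRUE), location = c(FALSE, TRUE),
                      scale = c(FALSE, TRUE))
  purrr::pmap(grid, function(logistic, location, scale) {
    cure_design(
      logistic = if (logistic) covariate else character(),
      location = if (location) covariate else character(),
      scale = if (scale) covariate else character()
    )
  })
}

# Design matrix for one part: intercept column plus named covariates.
part_matrix <- function(data, terms) {
  n <- nrow(data)
  X <- matrix(1, nrow = n, ncol = 1 + length(terms))
  colnames(X) <- c("(Intercept)", terms)
  for (i in seq_along(terms)) {
    X[, i + 1] <- data[[terms[i]]]
  }
  X
}

#' Bundle coefficient vectors for the three regression parts
#'
#' @param beta,gamma,alpha Numeric coefficient vectors for the logistic,
#'   location, and scale parts, intercept first.
#' @return An object of class `cure_params`.
#' @examples
#' cure_params(beta = -0.715, gamma = c(2.249, -1.022), alpha = -0.545)
#' @export
cure_params <- function(beta, gamma, alpha) {
  for (v in list(beta, gamma, alpha)) {
    if (!is.numeric(v) || length(v) < 1 || any(!is.finite(v))) {
      abort("each coefficient vector must be numeric, nonempty and finite.")
    }
  }
  structure(list(beta = as.numeric(beta), gamma = as.numeric(gamma),
                 alpha = as.numeric(alpha)),
            class = "cure_params")
}

check_params_design <- function(params, design) {
  lens <- c(beta = 1L + length(design$logistic),
            gamma = 1L + length(design$location),
            alpha = 1L + length(design$scale))
  for (nm in names(lens)) {
    if (length(params[[nm]]) != lens[[nm]]) {
      abort(paste0("`", nm, "` has length ", length(params[[nm]]),
                   " but the design requires ", lens[[nm]], "."))
    }
  }
  invisible(params)
}

# theta <-> params packing for the optimizer.
pack_params <- function(params) {
  c(params$beta, params$gamma, params$alpha)
}

unpack_params <- function(theta, design) {
  nb <- 1L + length(design$logistic)
  ng <- 1L + length(design$location)
  na <- 1L + length(design$scale)
  cure_params(beta = theta[seq_len(nb)],
              gamma = theta[nb + seq_len(ng)],
              alpha = theta[nb + ng + seq_len(na)])
}

param_names <- function(design) {
  c(paste0("logistic:", c("(Intercept)", design$logistic)),
    paste0("location:", c("(Intercept)", design$location)),
    paste0("scale:", c("(Intercept)", design$scale)))
}

param_table_skeleton <- function(design) {
  tibble::tibble(
    part = c(rep("logistic", 1L + length(design$logistic)),
             rep("location", 1L + length(design$location)),
             rep("scale", 1L + length(design$scale))),
    term = c("(Intercept)", design$logistic,
             "(Intercept)", design$location,
             "(Intercept)", design$scale)
  )
}
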