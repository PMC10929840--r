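#' The benchmark 5-year mortality model
#'
#' The 13-parameter logistic model (intercept plus 12 indicator effects)
#' that drives outcome generation and serves as the truth against which
#' imputation strategies are scored. Coefficients are the published
#' inverse-variance weighted averages from the three complete SNAC
#' studies. Category level 1 is the reference throughout; the sex
#' indicator fires for women (category 2).
#'
#' The two estimands of interest are the gait-speed contrasts:
#' `gait2` = -0.599 (0.8-1.2 vs <=0.8 m/s, OR 0.55) and
#' `gait3` = -1.237 (>1.2 vs <=0.8 m/s, OR 0.29).
#'
#' @param intercept intercept of the linear predictor.
#' @param coefficients named numeric vector of the 12 indicator effects.
#'   Names must be exactly the canonical design columns (see
#'   [design_terms()]).
#' @return an object of class `benchmark_model`: a list with elements
#'   `intercept` and `coefficients`.
#' @examples
#' m <- benchmark_model()
#' exp(m$coefficients[["gait2"]])  # odds ratio 0.55
#' @export
benchmark_model <- function(intercept = -0.786,
                            coefficients = c(
                              gait2 = -0.599, gait3 = -1.237,
                              mmse2 = -0.791, mmse3 = -1.13,
                              adl2 = 0.297, iadl2 = 0.520,
                              comorb2 = -0.0197, comorb3 = 0.297,
                              sex2 = -0.725,
                              age2 = 0.949, age3 = 1.382, age4 = 2.17
                            )) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  coefficients <- coefficients[design_terms()]
  if (length(coefficients) != 12L || anyNA(coefficients)) {
    stop("coefficients must be named exactly: ",
         paste(design_terms(), collapse = ", "))
  }
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "benchmark_model")
}

#' Canonical indicator terms of the outcome design matrix
#'
#' @return character vector of the 12 indicator-column names, in the
#'   order used everywhere in the package.
#' @export
design_terms <- function() {
  c("gait2", "gait3", "mmse2", "mmse3", "adl2", "iadl2",
    "comorb2", "comorb3", "sex2", "age2", "age3", "age4")
}

#' @export
print.benchmark_model <- function(x, ...) {
  cat("Benchmark logistic model for 5-year mortality\n")
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-8s %8.4g  (OR %.3g)\n", nm, x$coefficients[[nm]],
                exp(x$coefficients[[nm]])))
  }
  invisible(x)
}

## Indicator design matrix (without intercept) from integer-coded
## categorical columns. Used by the DGM and the analysis stage so the
## two cannot drift apart.
indicator_matrix <- function(data) {
  n <- nrow(data)
  X <- matrix(0, n, 12L, dimnames = list(NULL, design_terms()))
  X[, "gait2"] <- as.numeric(data$gait == 2L)
  X[, "gait3"] <- as.numeric(data$gait == 3L)
  X[, "mmse2"] <- as.numeric(data$mmse == 2L)
  X[, "mmse3"] <- as.numeric(data$mmse == 3L)
  X[, "adl2"] <- as.numeric(data$adl == 2L)
  X[, "iadl2"] <- as.numeric(data$iadl == 2L)
  X[, "comorb2"] <- as.numeric(data$comorb == 2L)
  X[, "comorb3"] <- as.numeric(data$comorb == 3L)
  X[, "sex2"] <- as.numeric(data$sex == 2L)
  X[, "age2"] <- as.numeric(data$age == 2L)
  X[, "age3"] <- as.numeric(data$age == 3L)
  X[, "age4"] <- as.numeric(data$age == 4L)
  X
}

#' Linear predictor of the benchmark mortality model
#'
#' Evaluates `intercept + X beta` for subjects with fully observed
#' categories. Called by the data generator before gait speed is masked,
#' so a missing gait value signals a pipeline error.
#'
#' @param data data frame with integer-coded columns `gait`, `adl`,
#'   `iadl`, `mmse`, `comorb`, `sex`, `age` (level 1 = reference).
#' @param model a [benchmark_model()].
#' @return numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(data, model = benchmark_model()) {
  stopifnot(inherits(model, "benchmark_model"))
  if (anyNA(data$gait)) {
    stop("gait is missing: the linear predictor must be computed before masking")
  }
  drop(model$intercept + indicator_matrix(data) %*% model$coefficients)
}
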