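#' Step I: per-study gait association models in the complete studies
#'
#' Fits one multinomial logistic regression of gait on all covariates
#' plus the outcome in each complete-gait study separately (no study
#' indicators - the models are study-specific by construction).
#'
#' @param data an `ipdma_data` replicate with at least one
#'   complete-gait study.
#' @param ridge ridge penalty passed to [fit_multinomial()]; also
#'   stabilises contrasts for categories unobserved within a study.
#' @return named list of `multinomial_fit` objects, one per complete
#'   study.
#' @export
fit_per_study <- function(data, ridge = 1e-6) {
  obs <- !is.na(data$gait)
  if (!any(obs)) stop("no complete-gait studies")
  complete_studies <- levels(droplevels(data$study[obs]))
  fits <- lapply(complete_studies, function(s) {
    d <- data[data$study == s, , drop = FALSE]
    X <- indicator_matrix(transform(d, gait = 1L))
    X <- X[, setdiff(colnames(X), c("gait2", "gait3")), drop = FALSE]
    X <- cbind(X, y = d$y)
    if (length(unique(d$gait)) < 3L) {
      warning(sprintf("study '%s': not all gait categories observed; ridge-stabilised fit", s))
    }
    fit_multinomial(X, factor(d$gait, levels = 1:3), ridge = ridge)
  })
  names(fits) <- complete_studies
  fits
}

#' Step II (pooling): average the per-study relationships
#'
#' Element-wise inverse-variance weighted average of the per-study
#' multinomial coefficients, using each fit's diagonal variances as
#' weights; the variance of the average is the inverse of the summed
#' precisions (diagonal IVW). A simple unweighted mean is available via
#' `weights = "equal"`. Design columns must already be harmonised
#' (identical `design_spec` across fits, which holds when all fits come
#' from [fit_per_study()]).
#'
#' @param fits list of `multinomial_fit` objects.
#' @param weights `"ivw"` (default) or `"equal"`.
#' @return object of class `averaged_model`: list with `theta_bar`,
#'   `vbar` (element-wise variance of the average), `design_spec`,
#'   `levels`, `source_fits`.
#' @export
average_relationships <- function(fits, weights = c("ivw", "equal")) {
  weights <- match.arg(weights)
  stopifnot(length(fits) >= 1L)
  spec <- fits[[1L]]$design_spec
  for (f in fits) {
    if (!identical(f$design_spec, spec)) {
      stop("design columns differ across per-study fits")
    }
  }
  Theta <- do.call(rbind, lapply(fits, `[[`, "theta_hat"))
  Vars <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  if (any(Vars <= 0)) stop("zero variance in a per-study fit: degenerate fit")
  if (weights == "ivw") {
    prec <- 1 / Vars
    theta_bar <- colSums(Theta * prec) / colSums(prec)
    vbar <- 1 / colSums(prec)
  } else {
    theta_bar <- colMeans(Theta)
    vbar <- colSums(Vars) / length(fits)^2
  }
  names(theta_bar) <- names(vbar) <- colnames(Theta)
  structure(list(theta_bar = theta_bar, vbar = vbar,
                 design_spec = spec, levels = fits[[1L]]$levels,
                 source_fits = fits),
            class = "averaged_model")
}

#' Step II (prediction): conditional category probabilities in the
#' missing study
#'
#' Softmax of the averaged linear predictors evaluated at the missing
#' study's observed covariates and outcome. When
#' `draw_parameters = TRUE` the coefficients are first redrawn from
#' N(theta_bar, vbar) (element-wise), which propagates estimation
#' uncertainty into the imputations (proper multiple imputation); with
#' `FALSE` the averaged coefficients are used as fixed.
#'
#' @param averaged an [average_relationships()] result.
#' @param newdata data frame of missing-study rows (covariates and
#'   outcome observed).
#' @param draw_parameters logical, default `TRUE`.
#' @return matrix of per-subject probabilities (columns "1","2","3"),
#'   each row summing to 1.
#' @export
predict_cqi_probabilities <- function(averaged, newdata,
                                      draw_parameters = TRUE) {
  stopifnot(inherits(averaged, "averaged_model"))
  X <- indicator_matrix(transform(newdata, gait = 1L))
  X <- X[, setdiff(colnames(X), c("gait2", "gait3")), drop = FALSE]
  X <- cbind(X, y = newdata$y)
  theta <- averaged$theta_bar
  if (draw_parameters) {
    theta <- theta + stats::rnorm(length(theta), 0, sqrt(averaged$vbar))
  }
  multinomial_probs(theta, averaged$design_spec, X, averaged$levels)
}

#' Step III: inverse-CDF draw of a category from probabilities
#'
#' For each subject a uniform `u` is drawn and the imputed category is
#' the smallest k whose cumulative predicted probability reaches `u`.
#'
#' @param probs matrix of per-subject category probabilities.
#' @param u optional uniform draws (recycled); defaults to fresh
#'   `runif(nrow(probs))`. Exposed for the monotone-coupling property.
#' @return integer vector of categories.
#' @export
inverse_cdf_impute <- function(probs, u = NULL) {
  if (is.null(u)) u <- stats::runif(nrow(probs))
  cum1 <- probs[, 1L]
  cum2 <- probs[, 1L] + probs[, 2L]
  as.integer(1L + (u > cum1) + (u > cum2))
}

#' Impute gait speed by conditional quantile imputation
#'
#' The three-step procedure: (I) fit the gait association model in each
#' complete study ([fit_per_study()]); (II) average the relationships
#' across studies ([average_relationships()]) and predict conditional
#' category probabilities for the missing study
#' ([predict_cqi_probabilities()]); (III) impute each missing value by
#' inverting the cumulative predicted distribution at a uniform draw
#' ([inverse_cdf_impute()]). With `draw_parameters = TRUE` (default)
#' the averaged coefficients are redrawn per imputation so that
#' between-imputation variance reflects estimation uncertainty.
#'
#' @param data an `ipdma_data` replicate.
#' @param M number of imputations, at least 2.
#' @param ridge ridge penalty for the per-study fits.
#' @param draw_parameters redraw coefficients per imputation (proper
#'   MI); `FALSE` reuses the fixed average and redraws only the
#'   uniforms.
#' @param weights averaging scheme, see [average_relationships()].
#' @return an [imputation_set()] with `method = "CQI"`.
#' @export
impute_cqi <- function(data, M = 100L, ridge = 1e-6,
                       draw_parameters = TRUE,
                       weights = c("ivw", "equal")) {
  if (M < 2L) stop("M must be at least 2 (Rubin's rules need between-imputation variance)")
  weights <- match.arg(weights)
  fits <- fit_per_study(data, ridge = ridge)
  averaged <- average_relationships(fits, weights = weights)
  mis <- is.na(data$gait)
  dmis <- data[mis, , drop = FALSE]
  imputed <- matrix(NA_integer_, sum(mis), M)
  for (m in seq_len(M)) {
    probs <- predict_cqi_probabilities(averaged, dmis,
                                       draw_parameters = draw_parameters)
    imputed[, m] <- inverse_cdf_impute(probs)
  }
  imputation_set(data, imputed, method = "CQI")
}
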