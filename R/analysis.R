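#' Fit the 13-parameter mortality model in one study
#'
#' Maximum-likelihood logistic regression of 5-year mortality on the
#' exact indicator design of the benchmark model (intercept + 12
#' indicators), for one study's complete rows.
#'
#' @param study_data data frame of one study's rows with no missing
#'   cells and both outcome classes present.
#' @return object of class `study_fit`: list with `beta_hat` (named
#'   13-vector), `vcov`, `study`, `converged`.
#' @export
fit_outcome_model <- function(study_data) {
  if (anyNA(study_data$gait)) stop("study has missing gait values")
  if (length(unique(study_data$y)) < 2L) {
    stop("outcome is constant in this study: degenerate fit")
  }
  X <- indicator_matrix(study_data)
  df <- data.frame(y = study_data$y, X, check.names = FALSE)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  beta <- stats::coef(fit)
  ok <- fit$converged && !anyNA(beta)
  V <- if (ok) stats::vcov(fit) else NULL
  if (ok && any(!is.finite(V))) ok <- FALSE
  structure(list(beta_hat = beta, vcov = V,
                 study = as.character(study_data$study[1L]),
                 converged = ok),
            class = "study_fit")
}

#' Common-effect (inverse-variance) meta-analysis of one coefficient
#'
#' Combines per-study estimates of a single coefficient under the
#' common-effect assumption: weighted mean with weights 1/variance,
#' combined variance the inverse of the summed precisions.
#'
#' @param estimates numeric vector of per-study estimates.
#' @param variances numeric vector of positive per-study variances.
#' @return list with `estimate` and `se`.
#' @export
common_effect_meta <- function(estimates, variances) {
  if (length(estimates) == 0L) stop("no studies to combine")
  stopifnot(length(estimates) == length(variances), all(variances > 0))
  w <- 1 / variances
  list(estimate = sum(w * estimates) / sum(w), se = sqrt(1 / sum(w)))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the M per-imputation estimates; total
#' variance `T = W + (1 + 1/M) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. The 95% CI uses
#' Rubin's degrees of freedom
#' `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2`; when `B = 0` the normal
#' quantile is used.
#'
#' @param estimates M per-imputation point estimates.
#' @param variances M per-imputation (squared-SE) variances.
#' @param conf confidence level, default 0.95.
#' @param estimand optional label.
#' @return object of class `pooled_estimate`: list with `estimate`,
#'   `se`, `ci_low`, `ci_high`, `within_var`, `between_var`, `df`, `M`,
#'   `estimand`.
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95,
                       estimand = NA_character_) {
  M <- length(estimates)
  if (M < 2L) stop("Rubin's rules need M >= 2 imputations")
  stopifnot(length(variances) == M)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tvar <- W + (1 + 1 / M) * B
  if (B > 0) {
    nu <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
    q <- stats::qt(1 - (1 - conf) / 2, df = nu)
  } else {
    nu <- Inf
    q <- stats::qnorm(1 - (1 - conf) / 2)
  }
  se <- sqrt(Tvar)
  structure(list(estimate = qbar, se = se,
                 ci_low = qbar - q * se, ci_high = qbar + q * se,
                 within_var = W, between_var = B, df = nu, M = M,
                 estimand = estimand),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], W = %.5f, B = %.5f, M = %d\n",
              if (is.na(x$estimand)) "estimate" else x$estimand,
              x$estimate, x$se, x$ci_low, x$ci_high,
              x$within_var, x$between_var, x$M))
  invisible(x)
}

#' Two-stage analysis of one imputation set
#'
#' For each imputation: fit the mortality model in every study and
#' combine each gait coefficient across studies by common-effect
#' meta-analysis; then pool the M meta-analytic estimates across
#' imputations by Rubin's rules. Studies without imputed cells are
#' identical across imputations and fitted once.
#'
#' @param set an [imputation_set()].
#' @param estimands coefficient names to pool (default the two gait
#'   contrasts).
#' @return list of [rubin_pool()] results, one per estimand, plus
#'   attribute `converged` (FALSE if any study fit failed in any
#'   imputation, in which case estimates are `NA`).
#' @export
analyse_replicate <- function(set, estimands = c("gait2", "gait3")) {
  stopifnot(inherits(set, "imputation_set"))
  data <- set$data
  studies <- levels(data$study)
  mis_idx <- is.na(data$gait)
  varying <- unique(as.character(data$study[mis_idx]))
  fixed <- setdiff(studies, varying)

  fixed_fits <- lapply(fixed, function(s) {
    fit_outcome_model(data[data$study == s, , drop = FALSE])
  })
  names(fixed_fits) <- fixed
  if (!all(vapply(fixed_fits, `[[`, logical(1), "converged"))) {
    warning("a complete-study fit failed to converge; replicate flagged")
    return(failed_analysis(estimands, set$method))
  }

  per_imp <- array(NA_real_, c(set$M, length(estimands), 2L),
                   dimnames = list(NULL, estimands, c("est", "var")))
  for (m in seq_len(set$M)) {
    comp <- complete_dataset(set, m)
    fits <- fixed_fits
    for (s in varying) {
      fits[[s]] <- fit_outcome_model(comp[comp$study == s, , drop = FALSE])
    }
    if (!all(vapply(fits, `[[`, logical(1), "converged"))) {
      warning(sprintf("imputation %d: a study fit failed; replicate flagged", m))
      return(failed_analysis(estimands, set$method))
    }
    for (e in estimands) {
      est <- vapply(fits, function(f) f$beta_hat[[e]], numeric(1))
      v <- vapply(fits, function(f) f$vcov[e, e], numeric(1))
      cm <- common_effect_meta(est, v)
      per_imp[m, e, "est"] <- cm$estimate
      per_imp[m, e, "var"] <- cm$se^2
    }
  }
  out <- lapply(estimands, function(e) {
    rubin_pool(per_imp[, e, "est"], per_imp[, e, "var"], estimand = e)
  })
  names(out) <- estimands
  attr(out, "converged") <- TRUE
  attr(out, "method") <- set$method
  out
}

failed_analysis <- function(estimands, method) {
  out <- lapply(estimands, function(e) {
    structure(list(estimate = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   within_var = NA_real_, between_var = NA_real_,
                   df = NA_real_, M = NA_integer_, estimand = e),
              class = "pooled_estimate")
  })
  names(out) <- estimands
  attr(out, "converged") <- FALSE
  attr(out, "method") <- method
  out
}

#' Complete-case two-stage analysis
#'
#' Drops the study with systematically missing gait entirely and runs
#' the two-stage common-effect meta-analysis over the remaining
#' studies. With by-study missingness this comparator loses the masked
#' study's information but introduces no imputation model.
#'
#' @param data an `ipdma_data` replicate.
#' @param estimands coefficient names to combine.
#' @return list of per-estimand results (`estimate`, `se`, `ci_low`,
#'   `ci_high` using normal quantiles), attribute `converged`.
#' @export
complete_case <- function(data, estimands = c("gait2", "gait3")) {
  keep <- !is.na(data$gait)
  studies <- levels(droplevels(data$study[keep]))
  fits <- lapply(studies, function(s) {
    fit_outcome_model(data[data$study == s & keep, , drop = FALSE])
  })
  if (!all(vapply(fits, `[[`, logical(1), "converged"))) {
    warning("a study fit failed to converge in complete-case analysis")
    out <- lapply(estimands, function(e)
      list(estimate = NA_real_, se = NA_real_,
           ci_low = NA_real_, ci_high = NA_real_, estimand = e))
    names(out) <- estimands
    attr(out, "converged") <- FALSE
    return(out)
  }
  z <- stats::qnorm(0.975)
  out <- lapply(estimands, function(e) {
    est <- vapply(fits, function(f) f$beta_hat[[e]], numeric(1))
    v <- vapply(fits, function(f) f$vcov[e, e], numeric(1))
    cm <- common_effect_meta(est, v)
    list(estimate = cm$estimate, se = cm$se,
         ci_low = cm$estimate - z * cm$se,
         ci_high = cm$estimate + z * cm$se, estimand = e)
  })
  names(out) <- estimands
  attr(out, "converged") <- TRUE
  out
}
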