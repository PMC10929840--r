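#' Build the appended-data imputation design for gait speed
#'
#' Rows are the subjects with observed gait, pooled ("appended") across
#' the complete-gait studies. Columns are the indicator codings of ADL,
#' IADL, MMSE, comorbidities, sex and age, the mortality outcome `y`,
#' and study indicators for the complete-gait studies (reference = the
#' first complete study). Columns constant over the fitting rows are
#' dropped with a warning.
#'
#' @param data an `ipdma_data` replicate with at least one
#'   complete-gait study.
#' @return list with elements `X` (numeric matrix, no intercept),
#'   `response` (factor of observed gait categories), `study_cols`
#'   (names of the study-indicator columns), `dropped` (names of any
#'   dropped constant columns).
#' @export
build_imputation_design <- function(data) {
  obs <- !is.na(data$gait)
  if (!any(obs)) stop("no observed gait values anywhere: nothing to fit")
  d <- data[obs, , drop = FALSE]
  X <- indicator_matrix(transform(d, gait = 1L))
  X <- X[, setdiff(colnames(X), c("gait2", "gait3")), drop = FALSE]
  X <- cbind(X, y = d$y)
  complete_studies <- levels(droplevels(d$study))
  study_cols <- character(0)
  if (length(complete_studies) > 1L) {
    for (s in complete_studies[-1L]) {
      cn <- paste0("study_", s)
      X <- cbind(X, as.numeric(d$study == s))
      colnames(X)[ncol(X)] <- cn
      study_cols <- c(study_cols, cn)
    }
  }
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping constant design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    study_cols <- intersect(study_cols, colnames(X))
  }
  list(X = X, response = factor(d$gait, levels = 1:3),
       study_cols = study_cols, dropped = dropped)
}

#' Fit a (ridge-stabilised) multinomial logistic regression
#'
#' Thin wrapper around [nnet::multinom()] returning the flattened
#' coefficient vector and its observed-information covariance in a
#' fixed order (all columns for the level-2 contrast, then level 3).
#' A small weight decay acts as a ridge penalty guarding against
#' separation in small studies.
#'
#' @param X numeric design matrix without intercept.
#' @param response factor of gait categories (levels 1:3; level 1 is
#'   the baseline contrast).
#' @param ridge non-negative ridge penalty (`decay`); default 1e-6.
#' @return object of class `multinomial_fit`: list with `theta_hat`,
#'   `vcov`, `design_spec` (column names incl. `(Intercept)`),
#'   `n_used`, `levels`.
#' @export
fit_multinomial <- function(X, response, ridge = 1e-6) {
  stopifnot(is.matrix(X), nrow(X) == length(response), ridge >= 0)
  response <- droplevels(factor(response))
  if (nlevels(response) < 2L) stop("need at least 2 observed gait categories")
  df <- data.frame(.resp = response, X, check.names = FALSE)
  fit <- nnet::multinom(.resp ~ ., data = df, Hess = TRUE,
                        decay = ridge, trace = FALSE,
                        maxit = 500, MaxNWts = 5000)
  if (fit$convergence != 0) {
    stop("multinomial fit did not converge; consider a larger ridge")
  }
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(levels(response)[2L],
                                                     names(cf)))
  theta <- as.vector(t(cf))
  names(theta) <- as.vector(t(outer(rownames(cf), colnames(cf),
                                    paste, sep = ":")))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    stop("singular information matrix; consider a larger ridge")
  }
  structure(list(theta_hat = theta, vcov = V,
                 design_spec = colnames(cf), n_used = nrow(X),
                 levels = c(levels(response)[1L], rownames(cf))),
            class = "multinomial_fit")
}

## Per-row category probabilities from a flattened coefficient vector.
## theta is contrast-major over design_spec; X must carry exactly the
## non-intercept columns of design_spec (order enforced here).
multinomial_probs <- function(theta, design_spec, X, levels = c("1", "2", "3")) {
  p <- length(design_spec)
  K1 <- length(theta) / p
  stopifnot(K1 == round(K1))
  sel <- design_spec[-1L]
  Xi <- if (length(sel)) {
    cbind(`(Intercept)` = 1, X[, sel, drop = FALSE])
  } else {
    matrix(1, nrow(X), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  eta <- matrix(0, nrow(Xi), K1 + 1L)
  for (k in seq_len(K1)) {
    th <- theta[((k - 1L) * p + 1L):(k * p)]
    eta[, k + 1L] <- Xi %*% th
  }
  eta <- eta - apply(eta, 1L, max)
  w <- exp(eta)
  probs <- w / rowSums(w)
  ## expand to the full 3 levels in case a category was unobserved
  out <- matrix(0, nrow(Xi), 3L, dimnames = list(NULL, c("1", "2", "3")))
  fitted_levels <- levels[seq_len(K1 + 1L)]
  out[, fitted_levels] <- probs
  out
}

## Inverse-CDF draw of one category per row from a probability matrix.
sample_categories <- function(probs) {
  cum1 <- probs[, 1L]
  cum2 <- probs[, 1L] + probs[, 2L]
  u <- stats::runif(nrow(probs))
  as.integer(1L + (u > cum1) + (u > cum2))
}

#' Impute gait speed by fully conditional specification
#'
#' FCS for a single systematically missing variable: one multinomial
#' logistic imputation model for gait is fitted on the appended
#' complete-gait studies (predictors: all covariates, the outcome, and
#' study indicators). With only one incomplete variable the FCS Gibbs
#' cycle collapses to this single conditional model, so no chained
#' iteration is needed. Each of the M imputations is made proper by
#' redrawing the model coefficients from their asymptotic normal
#' distribution N(theta_hat, vcov) before predicting category
#' probabilities for the missing study and drawing gait values.
#'
#' The missing study has no estimable study effect. By default it is
#' predicted at the reference study level (all study indicators 0);
#' `study_effect = "average"` instead uses the mean of the fitted
#' study effects (each indicator set to 1/S for S complete studies).
#'
#' @param data an `ipdma_data` replicate.
#' @param M number of imputations, at least 2.
#' @param ridge ridge penalty passed to [fit_multinomial()].
#' @param study_effect `"reference"` (default) or `"average"`.
#' @return an [imputation_set()] with `method = "FCS"`.
#' @export
impute_fcs <- function(data, M = 100L, ridge = 1e-6,
                       study_effect = c("reference", "average")) {
  study_effect <- match.arg(study_effect)
  if (M < 2L) stop("M must be at least 2 (Rubin's rules need between-imputation variance)")
  des <- build_imputation_design(data)
  fit <- fit_multinomial(des$X, des$response, ridge = ridge)

  mis <- is.na(data$gait)
  dmis <- data[mis, , drop = FALSE]
  Xnew <- indicator_matrix(transform(dmis, gait = 1L))
  Xnew <- Xnew[, setdiff(colnames(Xnew), c("gait2", "gait3")), drop = FALSE]
  Xnew <- cbind(Xnew, y = dmis$y)
  s_complete <- length(des$study_cols) + 1L
  for (cn in des$study_cols) {
    Xnew <- cbind(Xnew, if (study_effect == "average") 1 / s_complete else 0)
    colnames(Xnew)[ncol(Xnew)] <- cn
  }

  imputed <- matrix(NA_integer_, sum(mis), M)
  for (m in seq_len(M)) {
    theta_m <- drop(MASS::mvrnorm(1L, mu = fit$theta_hat, Sigma = fit$vcov))
    probs <- multinomial_probs(theta_m, fit$design_spec, Xnew, fit$levels)
    imputed[, m] <- sample_categories(probs)
  }
  imputation_set(data, imputed, method = "FCS")
}
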