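#' Numeric working matrix for joint-normal imputation
#'
#' Encodes the replicate as the numeric matrix the joint multivariate
#' normal model operates on: gait as two dummy columns (levels 2 and 3,
#' both `NA` where gait is missing), every other categorical predictor
#' dummy-coded, the outcome `y`, and study indicators (reference = the
#' first study). Mirrors the FCS imputation model's predictor set.
#'
#' @param data an `ipdma_data` replicate.
#' @return list with `W` (numeric matrix), `gait_cols` (the two gait
#'   dummy column names), `missing_rows` (row indices with missing
#'   gait).
#' @export
to_working_matrix <- function(data) {
  gait_filled <- data$gait
  gait_filled[is.na(gait_filled)] <- 1L   # placeholder, overwritten by NA below
  X <- indicator_matrix(transform(data, gait = gait_filled))
  X[is.na(data$gait), c("gait2", "gait3")] <- NA_real_
  W <- cbind(X, y = data$y)
  studies <- levels(data$study)
  for (s in studies[-1L]) {
    W <- cbind(W, as.numeric(data$study == s))
    colnames(W)[ncol(W)] <- paste0("study_", s)
  }
  list(W = W, gait_cols = c("gait2", "gait3"),
       missing_rows = which(is.na(data$gait)))
}

#' Data-augmentation MCMC under a joint multivariate normal model
#'
#' Alternates an I-step (draw the missing block from its conditional
#' normal given the observed columns and the current mean/covariance)
#' and a P-step (draw mean and covariance from their
#' normal-inverse-Wishart posterior given the completed data, under a
#' weakly informative conjugate prior: identity scale, p+2 degrees of
#' freedom, near-zero mean precision). After `n_burn` iterations, every
#' `n_between`-th completed matrix is retained as one imputation.
#'
#' @param W numeric matrix with missingness confined to `gait_cols`.
#' @param gait_cols names of the columns allowed to contain `NA`.
#' @param M number of imputations to retain, at least 2.
#' @param n_burn burn-in iterations (default 200).
#' @param n_between thinning interval between retained states
#'   (default 25).
#' @param kappa0 prior precision on the mean (default 0.01).
#' @return list of M completed matrices (attribute `trace`: matrix of
#'   retained-state means of the gait dummy columns, for diagnostics).
#' @export
da_mcmc <- function(W, gait_cols, M, n_burn = 200L, n_between = 25L,
                    kappa0 = 0.01) {
  if (M < 2L) stop("M must be at least 2")
  p <- ncol(W)
  mis_cols <- match(gait_cols, colnames(W))
  mis_rows <- which(apply(W[, mis_cols, drop = FALSE], 1L, anyNA))
  obs_cols <- setdiff(seq_len(p), mis_cols)
  bad <- is.na(W[, obs_cols, drop = FALSE])
  if (any(bad)) stop("missingness must be confined to the gait columns")

  if (length(mis_rows) == 0L) {
    return(structure(rep(list(W), M), trace = NULL))
  }

  ## start from observed-column means
  Wc <- W
  for (j in mis_cols) {
    Wc[mis_rows, j] <- mean(W[-mis_rows, j])
  }

  nu0 <- p + 2
  n <- nrow(W)
  kn <- kappa0 + n
  nun <- nu0 + n
  out <- vector("list", M)
  trace <- matrix(NA_real_, M, length(mis_cols),
                  dimnames = list(NULL, gait_cols))
  kept <- 0L
  it <- 0L
  total <- n_burn + n_between * M
  Xobs <- Wc[mis_rows, obs_cols, drop = FALSE]

  while (kept < M) {
    it <- it + 1L
    ## P-step: (mu, Sigma) ~ posterior given completed data
    ybar <- colMeans(Wc)
    S <- crossprod(sweep(Wc, 2L, ybar))
    Lambda_n <- diag(p) + S + (kappa0 * n / kn) * tcrossprod(ybar)
    Lambda_n <- (Lambda_n + t(Lambda_n)) / 2
    Prec <- stats::rWishart(1L, df = nun, Sigma = solve(Lambda_n))[, , 1L]
    Sigma <- solve((Prec + t(Prec)) / 2)
    Sigma <- (Sigma + t(Sigma)) / 2
    mu_n <- (n / kn) * ybar
    mu <- drop(MASS::mvrnorm(1L, mu_n, Sigma / kn))

    ## I-step: missing block | observed block, (mu, Sigma)
    Soo <- Sigma[obs_cols, obs_cols]
    Smo <- Sigma[mis_cols, obs_cols, drop = FALSE]
    Smm <- Sigma[mis_cols, mis_cols]
    B <- Smo %*% solve(Soo)
    Cond <- Smm - B %*% t(Smo)
    Cond <- (Cond + t(Cond)) / 2
    ev <- eigen(Cond, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("singular conditional covariance in I-step; strengthen the prior (larger kappa0)")
    }
    cond_mean <- matrix(mu[mis_cols], length(mis_rows), length(mis_cols),
                        byrow = TRUE) +
      sweep(Xobs, 2L, mu[obs_cols]) %*% t(B)
    draw <- cond_mean + matrix(stats::rnorm(length(mis_rows) * length(mis_cols)),
                               ncol = length(mis_cols)) %*% chol(Cond)
    Wc[mis_rows, mis_cols] <- draw

    if (it > n_burn && (it - n_burn) %% n_between == 0L) {
      kept <- kept + 1L
      out[[kept]] <- Wc
      trace[kept, ] <- colMeans(draw)
    }
    if (it > total) break
  }
  structure(out, trace = trace)
}

#' Map continuous gait-dummy draws back to categories
#'
#' The joint-normal model imputes the two gait dummies as real numbers.
#' Per subject the three category scores are
#' `(1 - d2 - d3, d2, d3)`; the imputed category is the argmax, with
#' ties broken toward the lower category. A stochastic alternative
#' (`mode = "stochastic"`) draws the category with probabilities
#' proportional to the scores clamped to \[0, 1\].
#'
#' @param d2,d3 numeric vectors of imputed dummy values.
#' @param mode `"argmax"` (default) or `"stochastic"`.
#' @return integer vector of categories 1..3.
#' @export
map_to_categories <- function(d2, d3, mode = c("argmax", "stochastic")) {
  mode <- match.arg(mode)
  s <- cbind(1 - d2 - d3, d2, d3)
  if (mode == "argmax") {
    as.integer(apply(s, 1L, which.max))  # which.max takes the first maximum
  } else {
    sc <- pmin(pmax(s, 0), 1)
    rs <- rowSums(sc)
    flat <- rs <= 0
    sc[flat, ] <- 1
    rs[flat] <- 3
    sample_categories(sc / rs)
  }
}

#' Impute gait speed by joint multivariate-normal data augmentation
#'
#' Runs [da_mcmc()] on the working-matrix encoding of the replicate and
#' maps each retained state's continuous gait-dummy draws to categories
#' via [map_to_categories()].
#'
#' @param data an `ipdma_data` replicate.
#' @param M number of imputations, at least 2.
#' @param n_burn,n_between chain schedule, see [da_mcmc()].
#' @param mapping category mapping mode, see [map_to_categories()].
#' @return an [imputation_set()] with `method = "MVN"` (attribute
#'   `trace` carries the chain diagnostics).
#' @export
impute_mvn <- function(data, M = 100L, n_burn = 200L, n_between = 25L,
                       mapping = c("argmax", "stochastic")) {
  mapping <- match.arg(mapping)
  wm <- to_working_matrix(data)
  chains <- da_mcmc(wm$W, wm$gait_cols, M = M, n_burn = n_burn,
                    n_between = n_between)
  imputed <- matrix(NA_integer_, length(wm$missing_rows), M)
  for (m in seq_len(M)) {
    Wm <- chains[[m]]
    imputed[, m] <- map_to_categories(Wm[wm$missing_rows, "gait2"],
                                      Wm[wm$missing_rows, "gait3"],
                                      mode = mapping)
  }
  out <- imputation_set(data, imputed, method = "MVN")
  attr(out, "trace") <- attr(chains, "trace")
  out
}
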