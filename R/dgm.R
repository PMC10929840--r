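#' Draw latent multivariate-normal predictors for one study
#'
#' Draws `n` i.i.d. rows from N(0, latent_corr) on the standardised
#' latent scale. Uses the current R random stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param profile a [study_profile()].
#' @return numeric matrix, `n` rows by 7 named columns.
#' @export
draw_latent <- function(profile) {
  stopifnot(inherits(profile, "study_profile"))
  R <- profile$latent_corr
  if (!is_positive_definite(R)) {
    stop(sprintf("latent correlation for study '%s' is not positive-definite",
                 profile$name))
  }
  L <- chol(R)
  Z <- matrix(stats::rnorm(profile$n * 7L), profile$n, 7L)
  X <- Z %*% L
  colnames(X) <- colnames(R)
  X
}

#' Discretise a standardised latent column into ordered categories
#'
#' Inverse-CDF thresholding: subject gets category k when the normal CDF
#' of its latent value falls in the k-th cumulative-probability bin.
#' The mapping is monotone in the latent value, so the latent
#' correlation induces a Gaussian-copula dependence among categories.
#' Zero-probability categories produce empty bins and are skipped.
#'
#' @param latent_column numeric vector of standardised latent values.
#' @param probs ordered category probabilities summing to 1.
#' @return integer vector of categories in `1:length(probs)`.
#' @export
discretize <- function(latent_column, probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
    stop("probs must be non-negative and sum to 1")
  }
  cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
  findInterval(latent_column, cuts, left.open = TRUE) + 1L
}

#' Draw Bernoulli outcomes from a vector of log-odds
#'
#' @param eta numeric vector of log-odds.
#' @return integer 0/1 vector with `P(1) = expit(eta)`.
#' @export
draw_outcome <- function(eta) {
  stopifnot(all(is.finite(eta) | eta == -Inf | eta == Inf))
  as.integer(stats::runif(length(eta)) < expit(eta))
}

#' Simulate one synthetic IPD meta-analysis replicate
#'
#' Full generative pipeline for one replicate: per study, draw latent
#' normals, discretise each variable to its marginal frequencies, draw
#' 5-year mortality from the benchmark logistic model, then mask gait
#' speed in the study flagged systematically missing. Outcomes are
#' generated *before* masking, so mortality depends on the (hidden)
#' gait values of the masked study.
#'
#' @param profiles list of four [study_profile()]s, exactly one flagged
#'   `gait_systematically_missing`.
#' @param model a [benchmark_model()].
#' @return an `ipdma_data` data frame with columns `study` (factor),
#'   `gait` (integer, `NA` in the masked study), `adl`, `iadl`, `mmse`,
#'   `comorb`, `sex`, `age` (integers), `y` (0/1), and attributes
#'   `missing_study` and `true_gait` (the pre-masking gait values of the
#'   masked study, kept for diagnostics only - no imputation method may
#'   read it).
#' @export
simulate_ipdma <- function(profiles = snac_profiles(),
                           model = benchmark_model()) {
  flagged <- vapply(profiles, function(p) p$gait_systematically_missing,
                    logical(1))
  if (sum(flagged) != 1L) {
    stop("exactly one study must be flagged gait_systematically_missing")
  }
  vars <- names(profile_variables())
  per_study <- lapply(profiles, function(p) {
    Z <- draw_latent(p)
    cols <- lapply(vars, function(v) discretize(Z[, v], p$marginals[[v]]))
    names(cols) <- vars
    df <- as.data.frame(cols)
    df$study <- p$name
    df
  })
  dat <- do.call(rbind, per_study)
  dat$study <- factor(dat$study,
                      levels = vapply(profiles, `[[`, "", "name"))
  dat <- dat[, c("study", vars)]
  dat$y <- draw_outcome(linear_predictor(dat, model))

  missing_study <- profiles[[which(flagged)]]$name
  mask <- dat$study == missing_study
  true_gait <- dat$gait[mask]
  dat$gait[mask] <- NA_integer_
  structure(dat,
            missing_study = missing_study,
            true_gait = true_gait,
            class = c("ipdma_data", "data.frame"))
}

#' @export
print.ipdma_data <- function(x, ...) {
  ms <- attr(x, "missing_study")
  cat(sprintf(
    "Synthetic IPDMA replicate: %d subjects in %d studies; gait missing in '%s' (%d subjects)\n",
    nrow(x), nlevels(x$study), ms, sum(is.na(x$gait))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write / read an IPDMA replicate as CSV
#'
#' Missing gait is encoded as an empty field. The masked study is
#' re-derived on read as the study whose gait values are all missing.
#'
#' @param data an `ipdma_data` object.
#' @param path CSV destination.
#' @return `path` invisibly (write); an `ipdma_data` object (read).
#' @export
write_ipdma_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_ipdma_csv
#' @export
read_ipdma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", names(profile_variables()), "y")
  if (!all(req %in% names(df))) {
    stop("CSV must have columns: ", paste(req, collapse = ", "))
  }
  df$study <- factor(df$study, levels = unique(df$study))
  for (v in c(names(profile_variables()), "y")) {
    df[[v]] <- as.integer(df[[v]])
  }
  miss_by_study <- tapply(is.na(df$gait), df$study, all)
  missing_study <- names(miss_by_study)[which(miss_by_study)]
  if (length(missing_study) > 1L) {
    stop("more than one study has gait entirely missing")
  }
  structure(df,
            missing_study = if (length(missing_study)) missing_study else NA_character_,
            class = c("ipdma_data", "data.frame"))
}
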