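#' Summarise per-replicate results into a performance table
#'
#' Computes, per (method, estimand) cell over the R replicates:
#' average estimate, average model-based SE, bias (mean estimate minus
#' truth), relative bias as a percentage of the true coefficient's
#' magnitude (`100 |bias| / |beta|`; the signed version is stored
#' alongside), empirical SE (SD of the point estimates), nominal 95%
#' coverage in percent, and Monte Carlo standard errors of bias
#' (`empirical SE / sqrt(R)`) and coverage
#' (`100 sqrt(p (1 - p) / R)`). Replicates flagged non-converged are
#' excluded and counted via `R_effective`.
#'
#' @param results data frame with columns `replicate`, `method`,
#'   `estimand`, `estimate`, `se`, `ci_low`, `ci_high` (and optionally
#'   `B`, `W`, `converged`).
#' @param truth named vector of true coefficient values (defaults to
#'   the benchmark gait contrasts).
#' @param se_method `"mean"` (the plain average of per-replicate SEs,
#'   default) or `"rms"` (root-mean-square).
#' @return a `performance_table` data frame, one row per
#'   (method, estimand).
#' @export
summarize_performance <- function(results,
                                  truth = c(gait2 = -0.599,
                                            gait3 = -1.237),
                                  se_method = c("mean", "rms")) {
  se_method <- match.arg(se_method)
  req <- c("method", "estimand", "estimate", "se", "ci_low", "ci_high")
  stopifnot(all(req %in% names(results)))
  cells <- unique(results[, c("method", "estimand")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mth <- cells$method[i]
    est <- cells$estimand[i]
    if (!est %in% names(truth)) stop("no truth supplied for estimand ", est)
    beta <- truth[[est]]
    d <- results[results$method == mth & results$estimand == est, ]
    ok <- is.finite(d$estimate) & is.finite(d$se)
    d <- d[ok, ]
    R <- nrow(d)
    if (R < 2L) stop("fewer than 2 converged replicates for ", mth, "/", est)
    bias <- mean(d$estimate) - beta
    emp_se <- stats::sd(d$estimate)
    cover <- mean(d$ci_low <= beta & beta <= d$ci_high)
    data.frame(
      method = mth, estimand = est,
      avg_estimate = mean(d$estimate),
      avg_model_se = if (se_method == "mean") mean(d$se)
                     else sqrt(mean(d$se^2)),
      bias = bias,
      relative_bias_pct = 100 * abs(bias) / abs(beta),
      relative_bias_signed_pct = 100 * bias / beta,
      empirical_se = emp_se,
      coverage_pct = 100 * cover,
      mcse_bias = emp_se / sqrt(R),
      mcse_coverage = coverage_mcse(100 * cover, R),
      R_effective = R,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Monte Carlo standard error of a coverage percentage
#'
#' Binomial MCSE on the percentage scale:
#' `100 sqrt(p (1 - p) / R)` with `p` the coverage proportion.
#'
#' @param coverage_pct coverage in percent.
#' @param R number of replications.
#' @return MCSE in percentage points.
#' @export
coverage_mcse <- function(coverage_pct, R) {
  p <- coverage_pct / 100
  100 * sqrt(p * (1 - p) / R)
}

#' @export
print.performance_table <- function(x, digits = 3, ...) {
  cat("Simulation performance by method and estimand\n")
  for (est in unique(x$estimand)) {
    d <- x[x$estimand == est, ]
    cat(sprintf("\nEstimand %s:\n", est))
    lines <- rbind(
      `Average estimate` = sprintf("%.3f", d$avg_estimate),
      `Average model SE` = sprintf("%.3f", d$avg_model_se),
      `Bias in point estimate` = sprintf("%.3f", d$bias),
      `Relative bias (%)` = sprintf("%.3f", d$relative_bias_pct),
      `Empirical SE` = sprintf("%.3f", d$empirical_se),
      `Nominal coverage (MCSE)` = sprintf("%.2f (%.3f)",
                                          d$coverage_pct, d$mcse_coverage)
    )
    colnames(lines) <- d$method
    print(lines, quote = FALSE, right = TRUE)
  }
  invisible(x)
}

#' Write / read a performance table as CSV
#'
#' @param table a `performance_table`.
#' @param path CSV destination.
#' @return `path` invisibly (write); a `performance_table` (read).
#' @export
write_performance_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_performance_csv
#' @export
read_performance_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("performance_table", "data.frame")
  out
}
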