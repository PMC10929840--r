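#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return probabilities `exp(x) / (1 + exp(x))`, computed stably.
#' @export
expit <- function(x) {
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

## Symmetric PD check via eigenvalues; tol relative to largest eigenvalue.
is_positive_definite <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > tol * max(abs(ev[1]), 1)
}

#' Nearest positive-definite projection of a correlation matrix
#'
#' Utility for repairing user-supplied latent correlation matrices that
#' fail the positive-definiteness requirement. Eigenvalues are floored at
#' `eig_floor` and the result rescaled to unit diagonal. The data
#' generator itself rejects non-PD matrices rather than repairing them;
#' call this explicitly (it warns) if a repair is wanted.
#'
#' @param m square symmetric matrix.
#' @param eig_floor smallest eigenvalue allowed in the projection.
#' @return a symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_pd_corr <- function(m, eig_floor = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  warning("matrix projected to nearest positive-definite correlation")
  out
}

## Deterministic child seeds below 2^31 derived from one master seed, so
## replicates are reproducible independently and under parallel execution.
derive_seeds <- function(master_seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
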