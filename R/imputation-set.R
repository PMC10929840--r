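#' Container for M multiply imputed datasets
#'
#' Stores the shared (never-imputed) data once plus an
#' `n_missing x M` matrix of imputed gait categories, which is both
#' compact and makes the "non-missing cells identical across copies"
#' invariant true by construction.
#'
#' @param data the incomplete `ipdma_data` replicate.
#' @param imputed integer matrix, rows = subjects with missing gait (in
#'   data order), columns = the M imputations; entries in 1..3.
#' @param method label: one of "FCS", "MVN", "CQI".
#' @return an object of class `imputation_set`.
#' @export
imputation_set <- function(data, imputed, method) {
  stopifnot(inherits(data, "ipdma_data"), is.matrix(imputed))
  if (nrow(imputed) != sum(is.na(data$gait))) {
    stop("imputed must have one row per missing gait value")
  }
  if (ncol(imputed) < 2L) stop("M must be at least 2")
  if (!all(imputed %in% 1:3)) stop("imputed gait categories must be in 1..3")
  structure(list(data = data, imputed = imputed, method = method,
                 M = ncol(imputed)),
            class = "imputation_set")
}

#' Extract the m-th completed dataset
#'
#' @param set an [imputation_set()].
#' @param m imputation index in `1:set$M`.
#' @return an `ipdma_data` data frame with gait filled in.
#' @export
complete_dataset <- function(set, m) {
  stopifnot(inherits(set, "imputation_set"), m >= 1L, m <= set$M)
  out <- set$data
  out$gait[is.na(out$gait)] <- set$imputed[, m]
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("%s imputation set: M = %d imputations of %d missing gait values\n",
              x$method, x$M, nrow(x$imputed)))
  freq <- prop.table(table(factor(x$imputed, levels = 1:3)))
  cat("  imputed gait frequencies:",
      paste(sprintf("%d: %.3f", 1:3, freq), collapse = "  "), "\n")
  invisible(x)
}

#' Write an imputation set as long-format CSV
#'
#' Columns: `imputation_index`, `subject_id` (row index in the
#' replicate), `gait_imputed`. Only the imputed cells are written; the
#' shared observed data round-trips via [write_ipdma_csv()].
#'
#' @param set an [imputation_set()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_imputations_csv <- function(set, path) {
  idx <- which(is.na(set$data$gait))
  long <- data.frame(
    imputation_index = rep(seq_len(set$M), each = length(idx)),
    subject_id = rep(idx, times = set$M),
    gait_imputed = as.vector(set$imputed)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
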