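#' Study profile for the synthetic data generator
#'
#' A study profile bundles everything the Gaussian-copula generator
#' needs for one cohort: the sample size, the marginal category
#' probabilities of the seven predictors, the 7x7 latent correlation
#' matrix, and whether gait speed is systematically missing there.
#'
#' Variables, in fixed order: gait (3 levels), adl (2), iadl (2),
#' mmse (3), comorb (3), sex (2, level 2 = female), age (4).
#'
#' Generation happens on a standardised latent scale (mean 0, unit
#' variance), so only the correlation structure - not latent means or
#' variances - affects the discretised output.
#'
#' @param name study label.
#' @param n number of subjects, positive integer.
#' @param marginals named list of probability vectors, one per variable,
#'   each summing to 1 with lengths 3, 2, 2, 3, 3, 2, 4.
#' @param latent_corr 7x7 symmetric positive-definite correlation
#'   matrix with unit diagonal, rows/columns ordered as the variables.
#' @param gait_systematically_missing logical; if `TRUE`, gait is masked
#'   for every subject of this study after outcome generation.
#' @return an object of class `study_profile`.
#' @export
study_profile <- function(name, n, marginals, latent_corr,
                          gait_systematically_missing = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  vars <- profile_variables()
  if (!identical(names(marginals), names(vars))) {
    stop("marginals must be a named list over, in order: ",
         paste(names(vars), collapse = ", "))
  }
  for (v in names(vars)) {
    p <- marginals[[v]]
    if (length(p) != vars[[v]]) {
      stop(sprintf("marginals$%s must have %d entries", v, vars[[v]]))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("marginals$%s must be non-negative and sum to 1", v))
    }
  }
  latent_corr <- as.matrix(latent_corr)
  if (!identical(dim(latent_corr), c(7L, 7L))) {
    stop("latent_corr must be 7x7")
  }
  if (max(abs(diag(latent_corr) - 1)) > 1e-10) {
    stop("latent_corr must have unit diagonal")
  }
  if (!is_positive_definite(latent_corr)) {
    stop(sprintf(
      "latent correlation matrix for study '%s' is not symmetric positive-definite; see nearest_pd_corr() to repair deliberately",
      name))
  }
  dimnames(latent_corr) <- list(names(vars), names(vars))
  structure(list(name = name, n = n, marginals = marginals,
                 latent_corr = latent_corr,
                 gait_systematically_missing =
                   isTRUE(gait_systematically_missing)),
            class = "study_profile")
}

## Variable names and category counts, in canonical order.
profile_variables <- function() {
  c(gait = 3L, adl = 2L, iadl = 2L, mmse = 3L, comorb = 3L,
    sex = 2L, age = 4L)
}

#' @export
print.study_profile <- function(x, ...) {
  cat(sprintf("Study profile '%s': n = %d%s\n", x$name, x$n,
              if (x$gait_systematically_missing)
                " (gait systematically missing)" else ""))
  for (v in names(x$marginals)) {
    cat(sprintf("  %-7s %s\n", v,
                paste(format(x$marginals[[v]], digits = 3),
                      collapse = " ")))
  }
  invisible(x)
}

#' Gait marginals for a study where gait speed is unobserved
#'
#' For the study where gait speed was never measured, no empirical gait
#' frequencies exist; the generator uses the component-wise arithmetic
#' mean of the gait frequencies observed in the complete studies.
#'
#' @param profiles_with_gait list of gait probability vectors (one per
#'   complete-gait study), each of length 3 summing to 1.
#' @return length-3 probability vector, the element-wise mean.
#' @examples
#' blekinge_gait_marginals(list(
#'   c(0.30, 0.21, 0.49), c(0.33, 0.46, 0.21), c(0.06, 0.26, 0.68)))
#' @export
blekinge_gait_marginals <- function(profiles_with_gait) {
  if (!is.list(profiles_with_gait) || length(profiles_with_gait) < 1L) {
    stop("need at least one complete study's gait probability vector")
  }
  for (p in profiles_with_gait) {
    if (length(p) != 3L || abs(sum(p) - 1) > 1e-12) {
      stop("each gait vector must have 3 entries summing to 1")
    }
  }
  colMeans(do.call(rbind, profiles_with_gait))
}

#' Default latent correlation matrix for a study
#'
#' Reads the synthetic default correlation fixture shipped with the
#' package. The fixtures are a documented stand-in for the (unpublished)
#' empirical covariance structure of the SNAC sites: one base matrix
#' with clinically signed pairwise correlations (|r| 0.10-0.40 among
#' gait/ADL/IADL/MMSE/comorbidities/age, near zero with sex), with
#' off-diagonals scaled by 1.0, 0.9 and 1.1 for Kungsholmen, Skane and
#' Nordanstig to emulate between-study variation. The Blekinge matrix
#' takes its gait row as the element-wise mean of the three complete
#' studies' gait rows, mirroring the marginal-averaging logic.
#'
#' @param study one of "kungsholmen", "skane", "nordanstig", "blekinge".
#' @return 7x7 correlation matrix with variable names as dimnames.
#' @export
default_latent_corr <- function(study = c("kungsholmen", "skane",
                                          "nordanstig", "blekinge")) {
  study <- match.arg(study)
  path <- system.file("extdata",
                      sprintf("latent_corr_%s_synthetic.csv", study),
                      package = "ipdmi", mustWork = TRUE)
  read_corr_csv(path)
}

#' Read a latent correlation matrix from CSV
#'
#' Expects a 7x7 numeric matrix with a header row and a leading column
#' of variable names (gait, adl, iadl, mmse, comorb, sex, age).
#'
#' @param path path to the CSV file.
#' @return 7x7 named correlation matrix.
#' @export
read_corr_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  vars <- names(profile_variables())
  if (!identical(rownames(m), vars) || !identical(colnames(m), vars)) {
    stop("correlation CSV must have rows/columns named: ",
         paste(vars, collapse = ", "))
  }
  m
}

#' Write a latent correlation matrix to CSV
#'
#' @param m 7x7 named correlation matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path)
  invisible(path)
}

#' Default four-study SNAC-like profiles
#'
#' Builds the four study profiles used throughout: sample sizes and
#' marginal category frequencies as published for the SNAC sites
#' Kungsholmen (n = 3,363), Skane (n = 768), Nordanstig (n = 2,397) and
#' Blekinge (n = 1,402), with gait speed flagged systematically missing
#' in Blekinge and its unobservable gait marginals set to the arithmetic
#' mean of the other three (via [blekinge_gait_marginals()]).
#'
#' @param latent_corr optional named list of 7x7 correlation matrices
#'   (names `kungsholmen`, `skane`, `nordanstig`, `blekinge`) overriding
#'   the shipped synthetic defaults.
#' @return list of four `study_profile` objects.
#' @export
snac_profiles <- function(latent_corr = NULL) {
  studies <- c("kungsholmen", "skane", "nordanstig", "blekinge")
  if (is.null(latent_corr)) {
    latent_corr <- lapply(studies, default_latent_corr)
    names(latent_corr) <- studies
  }
  stopifnot(all(studies %in% names(latent_corr)))

  gait <- list(kungsholmen = c(0.30, 0.21, 0.49),
               skane = c(0.33, 0.46, 0.21),
               nordanstig = c(0.06, 0.26, 0.68))
  gait$blekinge <- blekinge_gait_marginals(unname(gait))

  marg <- list(
    kungsholmen = list(gait = gait$kungsholmen,
                       adl = c(0.90, 0.10), iadl = c(0.76, 0.24),
                       mmse = c(0.07, 0.07, 0.86),
                       comorb = c(0.30, 0.33, 0.37),
                       sex = c(0.35, 0.65),
                       age = c(0.39, 0.28, 0.19, 0.14)),
    skane = list(gait = gait$skane,
                 adl = c(0.92, 0.08), iadl = c(0.72, 0.28),
                 mmse = c(0.08, 0.06, 0.86),
                 comorb = c(0.64, 0.24, 0.12),
                 sex = c(0.46, 0.54),
                 age = c(0.34, 0.25, 0.32, 0.09)),
    nordanstig = list(gait = gait$nordanstig,
                      adl = c(0.95, 0.05), iadl = c(0.76, 0.24),
                      mmse = c(0.03, 0.19, 0.78),
                      comorb = c(0.17, 0.36, 0.47),
                      sex = c(0.46, 0.54),
                      age = c(0.54, 0.20, 0.22, 0.04)),
    blekinge = list(gait = gait$blekinge,
                    adl = c(0.87, 0.13), iadl = c(0.56, 0.44),
                    mmse = c(0.11, 0.18, 0.71),
                    comorb = c(0.50, 0.30, 0.20),
                    sex = c(0.42, 0.58),
                    age = c(0.28, 0.25, 0.36, 0.11))
  )
  sizes <- c(kungsholmen = 3363L, skane = 768L, nordanstig = 2397L,
             blekinge = 1402L)

  lapply(studies, function(s) {
    study_profile(name = s, n = sizes[[s]], marginals = marg[[s]],
                  latent_corr = latent_corr[[s]],
                  gait_systematically_missing = (s == "blekinge"))
  })
}
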