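## Shared fixtures, built in code at test time.

## Default profiles with sample sizes scaled down by `factor`, for
## fast end-to-end tests that do not need the full cohort sizes.
scaled_profiles <- function(factor = 0.1) {
  profiles <- snac_profiles()
  lapply(profiles, function(p) {
    p$n <- max(50L, as.integer(round(p$n * factor)))
    p
  })
}

## Wrap a plain data frame as an ipdma_data object (for constructed
## edge-case datasets).
as_ipdma <- function(df, missing_study = NA_character_) {
  df$study <- factor(df$study, levels = unique(df$study))
  structure(df, missing_study = missing_study,
            class = c("ipdma_data", "data.frame"))
}

## A small complete (no-missingness) single-study dataset drawn from
## the benchmark model, used by analysis tests.
simulate_single_study <- function(n, model = benchmark_model(),
                                  profile = snac_profiles()[[1]]) {
  profile$n <- as.integer(n)
  profile$gait_systematically_missing <- FALSE
  Z <- draw_latent(profile)
  vars <- c("gait", "adl", "iadl", "mmse", "comorb", "sex", "age")
  cols <- lapply(vars, function(v) discretize(Z[, v], profile$marginals[[v]]))
  names(cols) <- vars
  df <- as.data.frame(cols)
  df$study <- "s1"
  df <- df[, c("study", vars)]
  df$y <- NA_integer_
  df <- as_ipdma(df)
  df$y <- draw_outcome(linear_predictor(df, model))
  df
}

## Memoised small replicate shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

small_replicate <- function() {
  if (is.null(.fixture_cache$small)) {
    set.seed(1234)
    .fixture_cache$small <- simulate_ipdma(scaled_profiles(0.1))
  }
  .fixture_cache$small
}

default_replicate <- function() {
  if (is.null(.fixture_cache$default)) {
    set.seed(4321)
    .fixture_cache$default <- simulate_ipdma()
  }
  .fixture_cache$default
}

## Hand-built multinomial_fit stub for averaging tests.
fake_fit <- function(theta, vars, spec = c("(Intercept)", "x")) {
  structure(list(theta_hat = theta,
                 vcov = diag(vars, length(theta)),
                 design_spec = spec, n_used = 100L,
                 levels = c("1", "2", "3")),
            class = "multinomial_fit")
}
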