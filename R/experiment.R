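#' Experiment configuration
#'
#' Bundles everything one simulation experiment needs: the four study
#' profiles, the benchmark outcome model, the number of replications R
#' and imputations M, the methods to compare, the master seed, and
#' method-specific options.
#'
#' @param profiles list of [study_profile()]s (default: the SNAC-like
#'   four-study profiles).
#' @param model a [benchmark_model()].
#' @param R number of simulation replications (default 1000).
#' @param M number of imputations per method (default 100).
#' @param methods subset of `c("FCS", "MVN", "CQI", "CC")`.
#' @param master_seed integer master seed; per-replicate child seeds
#'   are derived from it deterministically, so replicates are
#'   reproducible independently and under any parallelisation.
#' @param output_dir optional directory for result CSVs and manifest.
#' @param ridge ridge penalty for multinomial imputation models.
#' @param fcs_study_effect study-effect handling for the missing study
#'   in FCS ("reference" or "average").
#' @param mvn_n_burn,mvn_n_between MVN chain schedule.
#' @param mvn_mapping MVN category mapping ("argmax" or "stochastic").
#' @param cqi_draw_parameters redraw averaged coefficients per CQI
#'   imputation (proper MI), default `TRUE`.
#' @param cqi_weights CQI averaging scheme ("ivw" or "equal").
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(profiles = snac_profiles(),
                              model = benchmark_model(),
                              R = 1000L, M = 100L,
                              methods = c("FCS", "MVN", "CQI"),
                              master_seed = 20260101L,
                              output_dir = NULL,
                              ridge = 1e-6,
                              fcs_study_effect = "reference",
                              mvn_n_burn = 200L, mvn_n_between = 25L,
                              mvn_mapping = "argmax",
                              cqi_draw_parameters = TRUE,
                              cqi_weights = "ivw") {
  R <- as.integer(R); M <- as.integer(M)
  if (is.na(R) || R < 1L) stop("R must be at least 1")
  if (is.na(M) || M < 2L) stop("M must be at least 2")
  methods <- match.arg(methods, c("FCS", "MVN", "CQI", "CC"),
                       several.ok = TRUE)
  if (!length(methods)) stop("methods must be non-empty")
  stopifnot(inherits(model, "benchmark_model"),
            all(vapply(profiles, inherits, logical(1), "study_profile")))
  structure(list(profiles = profiles, model = model, R = R, M = M,
                 methods = methods,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir, ridge = ridge,
                 fcs_study_effect = fcs_study_effect,
                 mvn_n_burn = as.integer(mvn_n_burn),
                 mvn_n_between = as.integer(mvn_n_between),
                 mvn_mapping = mvn_mapping,
                 cqi_draw_parameters = isTRUE(cqi_draw_parameters),
                 cqi_weights = cqi_weights),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' Recognised top-level keys: `R`, `M`, `methods`, `master_seed`,
#' `output_dir`, `ridge`, `fcs_study_effect`, `mvn_n_burn`,
#' `mvn_n_between`, `mvn_mapping`, `cqi_draw_parameters`,
#' `cqi_weights`; `model` (`intercept` plus named `coefficients`);
#' and `studies`, a list of study entries with `name`, `n`,
#' `marginals` (named probability vectors), `latent_corr` (inline 7x7
#' matrix, a CSV path, or omitted for the shipped default), and
#' `gait_systematically_missing`. Omitted keys fall back to the
#' package defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE)
  }
  args <- list()
  for (key in c("R", "M", "methods", "master_seed", "output_dir",
                "ridge", "fcs_study_effect", "mvn_n_burn",
                "mvn_n_between", "mvn_mapping", "cqi_draw_parameters",
                "cqi_weights")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$model)) {
    args$model <- benchmark_model(
      intercept = raw$model$intercept,
      coefficients = unlist(raw$model$coefficients))
  }
  if (!is.null(raw$studies)) {
    args$profiles <- lapply(raw$studies, function(s) {
      corr <- s$latent_corr
      if (is.null(corr)) {
        corr <- default_latent_corr(tolower(s$name))
      } else if (is.character(corr)) {
        corr <- read_corr_csv(corr)
      } else {
        if (is.list(corr)) corr <- do.call(rbind, lapply(corr, as.numeric))
        corr <- matrix(as.numeric(corr), 7L, 7L,
                       dimnames = rep(list(names(profile_variables())), 2))
      }
      study_profile(name = s$name, n = s$n,
                    marginals = lapply(s$marginals, as.numeric),
                    latent_corr = corr,
                    gait_systematically_missing =
                      isTRUE(s$gait_systematically_missing))
    })
  }
  do.call(experiment_config, args)
}

## One replicate: generate, impute with each method, analyse.
## Returns a data frame of per-method, per-estimand rows.
run_replicate <- function(r, seed, config) {
  set.seed(seed)
  data <- simulate_ipdma(config$profiles, config$model)
  rows <- list()
  for (method in config$methods) {
    res <- tryCatch({
      if (method == "CC") {
        cc <- complete_case(data)
        lapply(cc, function(e) {
          list(estimate = e$estimate, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high, within_var = NA_real_,
               between_var = NA_real_)
        })
      } else {
        set <- switch(method,
          FCS = impute_fcs(data, M = config$M, ridge = config$ridge,
                           study_effect = config$fcs_study_effect),
          MVN = impute_mvn(data, M = config$M,
                           n_burn = config$mvn_n_burn,
                           n_between = config$mvn_n_between,
                           mapping = config$mvn_mapping),
          CQI = impute_cqi(data, M = config$M, ridge = config$ridge,
                           draw_parameters = config$cqi_draw_parameters,
                           weights = config$cqi_weights))
        analyse_replicate(set)
      }
    }, error = function(e) {
      warning(sprintf("replicate %d, method %s failed: %s",
                      r, method, conditionMessage(e)))
      NULL
    })
    for (est in c("gait2", "gait3")) {
      e <- res[[est]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = method, estimand = est,
        estimate = if (is.null(e)) NA_real_ else e$estimate,
        se = if (is.null(e)) NA_real_ else e$se,
        ci_low = if (is.null(e)) NA_real_ else e$ci_low,
        ci_high = if (is.null(e)) NA_real_ else e$ci_high,
        B = if (is.null(e)) NA_real_ else
          (if (is.null(e$between_var)) NA_real_ else e$between_var),
        W = if (is.null(e)) NA_real_ else
          (if (is.null(e$within_var)) NA_real_ else e$within_var),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full simulation experiment
#'
#' Executes the R x methods x M grid: for each replicate a fresh
#' synthetic IPDMA is generated from a child seed, each requested
#' method imputes (M times) and analyses it, and the per-replicate
#' results are aggregated into a [summarize_performance()] table.
#' With `workers > 1` replicates run in parallel via forked processes;
#' results are identical for any worker count because every replicate
#' re-seeds from its own pre-derived child seed.
#'
#' @param config an [experiment_config()].
#' @param workers number of parallel workers (default 1).
#' @param progress print per-replicate progress to stderr.
#' @return object of class `ipdmi_experiment`: list with `results`
#'   (per-replicate data frame), `performance` (the summary table),
#'   `config`, and `seeds`. If `config$output_dir` is set, writes
#'   `replicates.csv`, `performance_table.csv` and `manifest.json`
#'   there.
#' @export
run_experiment <- function(config, workers = 1L, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$master_seed, config$R)
  one <- function(r) {
    if (progress) message(sprintf("replicate %d/%d", r, config$R))
    run_replicate(r, seeds[r], config)
  }
  res_list <- if (workers > 1L) {
    parallel::mclapply(seq_len(config$R), one, mc.cores = workers)
  } else {
    lapply(seq_len(config$R), one)
  }
  results <- do.call(rbind, res_list)
  performance <- summarize_performance(
    results, truth = c(gait2 = config$model$coefficients[["gait2"]],
                       gait3 = config$model$coefficients[["gait3"]]))
  out <- structure(list(results = results, performance = performance,
                        config = config, seeds = seeds),
                   class = "ipdmi_experiment")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results,
                     file.path(config$output_dir, "replicates.csv"),
                     row.names = FALSE)
    write_performance_csv(performance,
                          file.path(config$output_dir,
                                    "performance_table.csv"))
    manifest <- list(
      R = config$R, M = config$M, methods = config$methods,
      master_seed = config$master_seed,
      package_version = as.character(utils::packageVersion("ipdmi")),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.ipdmi_experiment <- function(x, ...) {
  cat(sprintf("Simulation experiment: R = %d replicates, M = %d imputations, methods: %s\n",
              x$config$R, x$config$M,
              paste(x$config$methods, collapse = ", ")))
  print(x$performance)
  invisible(x)
}

#' @export
summary.ipdmi_experiment <- function(object, ...) {
  object$performance
}
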