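test_that("invalid configurations are rejected before any computation", {
  expect_error(experiment_config(M = 1), "at least 2")
  expect_error(experiment_config(R = 0), "at least 1")
  expect_error(experiment_config(methods = character(0)))
  expect_error(experiment_config(methods = "PMM"))
})

test_that("a small experiment produces the full results grid and is reproducible", {
  profs <- scaled_profiles(0.08)
  cfg <- experiment_config(profiles = profs, R = 2, M = 2,
                           methods = "CQI", master_seed = 99L)
  ex1 <- suppressWarnings(run_experiment(cfg))
  expect_s3_class(ex1, "ipdmi_experiment")
  expect_equal(nrow(ex1$results), 2 * 1 * 2)   # R x methods x estimands
  expect_setequal(unique(ex1$results$estimand), c("gait2", "gait3"))
  expect_equal(nrow(ex1$performance), 2)

  ex2 <- suppressWarnings(run_experiment(cfg))
  expect_identical(ex1$results, ex2$results)

  out <- capture.output(print(ex1))
  expect_true(any(grepl("R = 2 replicates", out)))
  expect_identical(summary(ex1), ex1$performance)
})

test_that("results are invariant to the number of workers", {
  profs <- scaled_profiles(0.08)
  cfg <- experiment_config(profiles = profs, R = 2, M = 2,
                           methods = "CC", master_seed = 7L)
  ex1 <- suppressWarnings(run_experiment(cfg, workers = 1))
  ex2 <- suppressWarnings(run_experiment(cfg, workers = 2))
  expect_equal(ex1$results, ex2$results)
})

test_that("experiment output files are written with a manifest", {
  dir <- withr::local_tempdir()
  profs <- scaled_profiles(0.08)
  cfg <- experiment_config(profiles = profs, R = 2, M = 2,
                           methods = "CC", master_seed = 7L,
                           output_dir = dir)
  suppressWarnings(run_experiment(cfg))
  expect_true(file.exists(file.path(dir, "replicates.csv")))
  expect_true(file.exists(file.path(dir, "performance_table.csv")))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$R, 2)
  expect_equal(manifest$M, 2)
  expect_equal(manifest$master_seed, 7)
})

test_that("configurations round-trip through JSON and YAML", {
  cfg_list <- list(
    R = 3, M = 4, methods = c("CQI", "CC"), master_seed = 11,
    ridge = 1e-5, cqi_draw_parameters = FALSE,
    model = list(intercept = -0.786, coefficients = as.list(
      benchmark_model()$coefficients)),
    studies = list(
      list(name = "a", n = 100,
           marginals = list(gait = c(0.3, 0.3, 0.4), adl = c(0.9, 0.1),
                            iadl = c(0.8, 0.2), mmse = c(0.1, 0.1, 0.8),
                            comorb = c(0.3, 0.3, 0.4), sex = c(0.5, 0.5),
                            age = c(0.4, 0.3, 0.2, 0.1))),
      list(name = "b", n = 50,
           marginals = list(gait = c(0.3, 0.3, 0.4), adl = c(0.9, 0.1),
                            iadl = c(0.8, 0.2), mmse = c(0.1, 0.1, 0.8),
                            comorb = c(0.3, 0.3, 0.4), sex = c(0.5, 0.5),
                            age = c(0.4, 0.3, 0.2, 0.1)),
           gait_systematically_missing = TRUE)))
  ## inline correlation matrices travel as a list of rows
  cfg_list$studies[[1]]$latent_corr <- lapply(1:7, function(i) diag(7)[i, ])
  cfg_list$studies[[2]]$latent_corr <- lapply(1:7, function(i) diag(7)[i, ])

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jpath, auto_unbox = TRUE, digits = NA)
  cfg <- read_experiment_config(jpath)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$R, 3L)
  expect_equal(cfg$M, 4L)
  expect_identical(cfg$methods, c("CQI", "CC"))
  expect_false(cfg$cqi_draw_parameters)
  expect_length(cfg$profiles, 2)
  expect_true(cfg$profiles[[2]]$gait_systematically_missing)
  expect_equal(cfg$profiles[[1]]$n, 100L)
  expect_equal(cfg$model$coefficients[["gait3"]], -1.237)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, ypath)
  cfg_y <- read_experiment_config(ypath)
  expect_equal(cfg_y$R, cfg$R)
  expect_equal(cfg_y$profiles[[2]]$marginals$gait,
               cfg$profiles[[2]]$marginals$gait)

  ## a correlation CSV path is also accepted
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_corr_csv(default_latent_corr("skane"), cpath)
  cfg_list$studies[[1]]$latent_corr <- cpath
  jsonlite::write_json(cfg_list, jpath, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_experiment_config(jpath)
  expect_equal(cfg2$profiles[[1]]$latent_corr,
               default_latent_corr("skane"))
})

test_that("shipped correlation fixtures are valid and CSV round-trips preserve them", {
  for (s in c("kungsholmen", "skane", "nordanstig", "blekinge")) {
    m <- default_latent_corr(s)
    expect_equal(dim(m), c(7L, 7L))
    expect_equal(unname(diag(m)), rep(1, 7))
    expect_true(isSymmetric(m))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  ## Blekinge gait correlations are the element-wise mean of the
  ## complete studies' gait rows
  g <- (default_latent_corr("kungsholmen")["gait", ] +
        default_latent_corr("skane")["gait", ] +
        default_latent_corr("nordanstig")["gait", ]) / 3
  g["gait"] <- 1
  expect_equal(default_latent_corr("blekinge")["gait", ], g)

  path <- withr::local_tempfile(fileext = ".csv")
  write_corr_csv(default_latent_corr("nordanstig"), path)
  expect_equal(read_corr_csv(path), default_latent_corr("nordanstig"))
})

test_that("imputation sets export to long-format CSV", {
  d <- small_replicate()
  set.seed(91)
  set <- impute_cqi(d, M = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imputations_csv(set, path)
  long <- read.csv(path)
  expect_equal(nrow(long), 3 * sum(is.na(d$gait)))
  expect_setequal(names(long),
                  c("imputation_index", "subject_id", "gait_imputed"))
  expect_true(all(long$gait_imputed %in% 1:3))
  m2 <- matrix(long$gait_imputed[long$imputation_index == 2], ncol = 1)
  expect_equal(as.vector(m2), set$imputed[, 2])
})
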