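test_that("averaged gait marginals for the unmeasured study are the component-wise mean", {
  expect_equal(
    blekinge_gait_marginals(list(c(0.30, 0.21, 0.49), c(0.33, 0.46, 0.21),
                                 c(0.06, 0.26, 0.68))),
    c(0.23, 0.31, 0.46))
  expect_equal(blekinge_gait_marginals(list(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5),
                                            c(0.2, 0.3, 0.5))),
               c(0.2, 0.3, 0.5))
  expect_equal(blekinge_gait_marginals(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               rep(1 / 3, 3))
  expect_error(blekinge_gait_marginals(list()), "at least one")
  expect_error(blekinge_gait_marginals(list(c(0.5, 0.6, 0.2))), "summing to 1")
})

test_that("inverse-CDF discretisation respects the cumulative bins and is monotone", {
  probs <- c(0.30, 0.21, 0.49)
  expect_identical(discretize(qnorm(0.25), probs), 1L)
  expect_identical(discretize(qnorm(0.30), probs), 1L)   # boundary goes to the lower bin
  expect_identical(discretize(qnorm(0.31), probs), 2L)
  expect_identical(discretize(qnorm(0.999), probs), 3L)
  expect_identical(discretize(c(-2, 0, 2), c(1, 0, 0)), c(1L, 1L, 1L))
  ## zero-probability leading category: empty bin skipped
  expect_identical(discretize(qnorm(0.1), c(0, 0.5, 0.5)), 2L)

  set.seed(7)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 100, runif(3))) / 100
    z <- sort(rnorm(50))
    cats <- discretize(z, p)
    expect_true(all(diff(cats) >= 0))
  }
  expect_error(discretize(0, c(0.5, 0.6)), "sum to 1")
})

test_that("linear predictor reproduces hand-computed benchmark values", {
  ref <- data.frame(study = "s", gait = 1L, adl = 1L, iadl = 1L, mmse = 1L,
                    comorb = 1L, sex = 1L, age = 1L)
  expect_equal(linear_predictor(ref), -0.786)
  expect_equal(linear_predictor(transform(ref, gait = 3L)), -0.786 - 1.237)
  expect_equal(linear_predictor(transform(ref, sex = 2L)), -0.786 - 0.725)
  expect_error(linear_predictor(transform(ref, gait = NA_integer_)),
               "before masking")
})

test_that("outcome draws have the right prevalence and limits", {
  set.seed(11)
  y <- draw_outcome(rep(-0.786, 1e5))
  expect_equal(mean(y), expit(-0.786), tolerance = 0.005 / expit(-0.786))
  expect_true(all(draw_outcome(rep(-Inf, 100)) == 0L))
  expect_true(all(draw_outcome(rep(Inf, 100)) == 1L))
  set.seed(12)
  expect_equal(mean(draw_outcome(rep(0, 1e5))), 0.5, tolerance = 0.01)
})

test_that("latent draws have the requested correlation structure and are seed-deterministic", {
  p <- snac_profiles()[[1]]
  p$latent_corr <- diag(7)
  dimnames(p$latent_corr) <- dimnames(snac_profiles()[[1]]$latent_corr)
  p$n <- 100000L
  set.seed(5)
  Z <- draw_latent(p)
  sc <- cor(Z)
  expect_lt(max(abs(sc[upper.tri(sc)])), 4 / sqrt(p$n) * 1.6)

  p$n <- 1L
  set.seed(6); a <- draw_latent(p)
  expect_identical(dim(a), c(1L, 7L))
  set.seed(6); b <- draw_latent(p)
  expect_identical(a, b)

  bad <- p
  bad$latent_corr[1, 2] <- bad$latent_corr[2, 1] <- 0.999
  bad$latent_corr[1, 3] <- bad$latent_corr[3, 1] <- -0.999
  bad$latent_corr[2, 3] <- bad$latent_corr[3, 2] <- 0.999
  expect_error(draw_latent(bad), "positive-definite")
})

test_that("non-positive-definite user matrices are rejected at profile construction, repairable explicitly", {
  base <- snac_profiles()[[1]]
  m <- base$latent_corr
  m[1, 2] <- m[2, 1] <- 0.999
  m[1, 3] <- m[3, 1] <- -0.999
  m[2, 3] <- m[3, 2] <- 0.999
  expect_error(
    study_profile("bad", 10, base$marginals, m),
    "bad")
  fixed <- suppressWarnings(nearest_pd_corr(m))
  expect_warning(nearest_pd_corr(m), "projected")
  expect_true(min(eigen(fixed, symmetric = TRUE)$values) > 0)
  expect_equal(unname(diag(fixed)), rep(1, 7))
  expect_silent(study_profile("ok", 10, base$marginals, fixed))
})

test_that("simulated replicate has the published layout and exact masking", {
  d <- default_replicate()
  expect_equal(nrow(d), 3363 + 768 + 2397 + 1402)
  expect_equal(sum(is.na(d$gait)), 1402)
  expect_identical(attr(d, "missing_study"), "blekinge")
  expect_true(all(is.na(d$gait[d$study == "blekinge"])))
  expect_true(all(!is.na(d$gait[d$study != "blekinge"])))
  expect_true(all(!is.na(d[, c("adl", "iadl", "mmse", "comorb", "sex", "age", "y")])))
  expect_equal(as.vector(table(d$study)), c(3363, 768, 2397, 1402))

  set.seed(99); a <- simulate_ipdma(scaled_profiles(0.05))
  set.seed(99); b <- simulate_ipdma(scaled_profiles(0.05))
  expect_identical(a, b)

  none <- scaled_profiles(0.05)
  none[[4]]$gait_systematically_missing <- FALSE
  expect_error(simulate_ipdma(none), "exactly one")
})

test_that("discretisation recovers the per-study marginal frequencies (chi-square GOF)", {
  profs <- snac_profiles()
  p <- profs[[2]]           # Skane: the least balanced gait marginals
  p$n <- 100000L
  p$gait_systematically_missing <- FALSE
  set.seed(314)
  Z <- draw_latent(p)
  for (v in c("gait", "adl", "iadl", "mmse", "comorb", "sex", "age")) {
    cats <- discretize(Z[, v], p$marginals[[v]])
    counts <- tabulate(cats, nbins = length(p$marginals[[v]]))
    gof <- suppressWarnings(chisq.test(counts, p = p$marginals[[v]]))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("simulated prevalence matches the plug-in expectation of the benchmark model", {
  d <- small_replicate()
  complete <- d
  complete$gait[is.na(complete$gait)] <- attr(d, "true_gait")
  pbar <- mean(expit(linear_predictor(complete)))
  mcse <- sqrt(pbar * (1 - pbar) / nrow(d))
  expect_lt(abs(mean(d$y) - pbar), 3 * mcse)
})

test_that("replicates round-trip through CSV with empty-field missing encoding", {
  d <- small_replicate()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipdma_csv(d, path)
  txt <- readLines(path, n = 2)
  expect_match(txt[1], "study")
  back <- read_ipdma_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(d),
               ignore_attr = TRUE)
  for (col in names(d)) {
    expect_equal(unclass(back[[col]]), unclass(d[[col]]),
                 ignore_attr = TRUE)
  }
  expect_identical(attr(back, "missing_study"), attr(d, "missing_study"))
})
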