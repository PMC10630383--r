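# Distribution specs, Monte Carlo sampling, and goodness-of-fit machinery.

test_that("spec validation catches malformed parameters", {
  expect_error(dist_spec("uniform", min = 2, max = 1), "min")
  expect_error(dist_spec("normal", mean = 0, sd = 0), "sd")
  expect_error(dist_spec("logistic", location = 0, scale = -1), "scale")
  expect_error(dist_spec("triangular", min = 0, mode = 3, max = 2), "mode")
  expect_error(dist_spec("normal", mean = 0), "missing")
})

test_that("point specs yield constant draws and degenerate CDFs", {
  sp <- dist_spec("point", value = 3.5)
  expect_identical(sample_mc(sp, 10, seed = 1), rep(3.5, 10))
})

test_that("sampling is reproducible and matches distribution moments", {
  sp <- dist_spec("uniform", min = 0.01, max = 1.97)
  x1 <- sample_mc(sp, 5000, seed = 7)
  x2 <- sample_mc(sp, 5000, seed = 7)
  expect_identical(x1, x2)
  # mean -> (min+max)/2 within 3 standard errors
  se <- (1.97 - 0.01) / sqrt(12 * 5000)
  expect_lt(abs(mean(x1) - 0.99), 3 * se)
})

test_that("untruncated logistic concentration draws go negative at the CDF rate", {
  sp <- dist_spec("logistic", location = 34.25, scale = 24.04)
  x <- sample_mc(sp, 20000, seed = 3)
  p <- plogis(0, 34.25, 24.04)  # 0.1939: the oracle for P(X < 0)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(x < 0) - p), 3 * se)
})

test_that("truncation is honoured by rejection and errors on empty regions", {
  sp <- dist_spec("logistic", location = 34.25, scale = 24.04,
                  truncate = c(0, 128.3))
  x <- sample_mc(sp, 2000, seed = 9)
  expect_true(all(x >= 0 & x <= 128.3))
  far <- dist_spec("normal", mean = 0, sd = 1, truncate = c(50, 51))
  expect_error(sample_mc(far, 10, seed = 1, max_rounds = 3), "negligible")
})

test_that("KS distance against a fully specified uniform is the sup distance", {
  sp <- dist_spec("uniform", min = 0, max = 1)
  ks <- suppressWarnings(
    stats::ks.test(c(0.25, 0.5, 0.75), function(q) aquarisk:::.spec_p(sp, q)))
  expect_equal(unname(ks$statistic), 0.25)
})

test_that("auto-selection picks the generating family", {
  # exact uniform quantiles: uniform wins with a tiny KS distance
  u <- qunif(ppoints(200))
  fit <- fit_distribution(u, candidates = c("uniform", "normal", "logistic"),
                          pvalues = FALSE)
  expect_equal(fit$selected, "uniform")
  expect_lt(fit$report$ks[fit$report$family == "uniform"], 0.01)
  # logistic draws: logistic wins and parameters are near truth
  x <- sample_mc(dist_spec("logistic", location = 34.25, scale = 24.04),
                 3000, seed = 2)
  fl <- fit_distribution(x, candidates = c("normal", "logistic"),
                         pvalues = FALSE)
  expect_equal(fl$selected, "logistic")
  expect_lt(abs(fl$spec$par$location - 34.25), 1.5)
  expect_lt(abs(fl$spec$par$scale - 24.04), 1.5)
})

test_that("degenerate samples admit only the point family", {
  fit <- fit_distribution(rep(2.5, 10),
                          candidates = c("normal", "uniform", "logistic"))
  expect_equal(fit$selected, "point")
  expect_equal(fit$spec$par$value, 2.5)
  rep_rows <- fit$report
  expect_false(any(rep_rows$fitted[rep_rows$family != "point"]))
})

test_that("GoF statistics are sane and the chi-square df accounts for params", {
  set.seed(6)
  x <- rnorm(30, 5, 2)
  fit <- fit_distribution(x, candidates = c("normal", "uniform"),
                          pvalues = FALSE)
  rep_rows <- fit$report[fit$report$fitted, ]
  expect_true(all(rep_rows$ad >= 0))
  expect_true(all(rep_rows$ks >= 0 & rep_rows$ks <= 1))
  expect_true(all(rep_rows$ks_p >= 0 & rep_rows$ks_p <= 1))
  # n = 30 -> k = max(5, 6) = 6 equal-probability bins; df = 6 - 1 - 2
  expect_equal(rep_rows$chisq_df[rep_rows$family == "normal"], 3)
})

test_that("AD and KS statistics agree with the fitdistrplus cross-check", {
  set.seed(11)
  x <- rnorm(200, 10, 3)
  fit <- fit_distribution(x, candidates = "normal", pvalues = FALSE)
  ref <- fitdistrplus::gofstat(fitdistrplus::fitdist(x, "norm"))
  expect_equal(fit$report$ad, unname(ref$ad), tolerance = 1e-6)
  expect_equal(fit$report$ks, unname(ref$ks), tolerance = 1e-6)
})

test_that("bootstrap AD p-values are calibrated enough to pass a true model", {
  x <- sample_mc(dist_spec("uniform", min = 0, max = 2), 100, seed = 15)
  fit <- fit_distribution(x, candidates = "uniform", pvalues = TRUE,
                          ad_reps = 199, seed = 1)
  expect_gt(fit$report$ad_p, 0.01)
  expect_lte(fit$report$ad_p, 1)
})

test_that("truncation-aware refits recover the generating parameters", {
  sp <- dist_spec("logistic", location = 34.25, scale = 24.04,
                  truncate = c(0, 128.3))
  x <- sample_mc(sp, 8000, seed = 21)
  fit <- fit_distribution(x, candidates = c("normal", "logistic"),
                          pvalues = FALSE, truncate = c(0, 128.3))
  expect_equal(fit$selected, "logistic")
  expect_lt(abs(fit$spec$par$location - 34.25), 1)
  expect_lt(abs(fit$spec$par$scale - 24.04), 1)
})
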