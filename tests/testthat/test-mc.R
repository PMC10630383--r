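# Monte Carlo risk engine: degenerate limit, closed-form oracle, seeded
# streams, sensitivity and the uncertainty report.

point_conc_config <- function(C, n = 200, seed = 5) {
  mc_config(
    n_iterations = n, seed = seed,
    concentration = list(NO3 = dist_spec("point", value = C)),
    exposure = default_exposure_specs(spread = 0)
  )
}

test_that("all-point specs collapse the simulation onto the deterministic HQ", {
  C <- 45
  mc <- point_conc_config(C)
  res <- mc_risk(mc, chemicals = "NO3")
  det <- deterministic_risk_table(water_row(NO3 = C), chemicals = "NO3")
  for (pw in c("ingestion", "dermal", "combined")) {
    p <- res$summary[res$summary$pathway == pw, ]
    d <- det[det$pathway == pw, ]
    expect_equal(p$mean, d$mean, tolerance = 1e-9)
    expect_equal(p$sd, rep(0, nrow(p)), tolerance = 1e-12)
    expect_true(all(p$rcl_percent %in% c(0, 100)))
  }
})

test_that("uniform concentration with point exposures matches the closed form", {
  pr <- default_exposure_profiles()$infants
  k <- pr$IR_w * pr$EF_r * pr$ED / (pr$BW * pr$AT_r) / 1.6  # HQ = k * C
  n <- 10000
  for (s in 1:3) {
    set.seed(s)
    a <- runif(1, 5, 12)
    b <- a + runif(1, 15, 60)
    mc <- mc_config(n_iterations = n, seed = 100 + s,
                    concentration = list(NO3 = dist_spec("uniform", min = a, max = b)),
                    exposure = default_exposure_specs(spread = 0))
    res <- mc_risk(mc, chemicals = "NO3")
    ing <- res$summary[res$summary$pathway == "ingestion" &
                         res$summary$age_group == "infants", ]
    mean_true <- k * (a + b) / 2
    p95_true <- k * (a + 0.95 * (b - a))
    p_true <- min(max((b - 1 / k) / (b - a), 0), 1)
    se_mean <- k * (b - a) / sqrt(12 * n)
    se_p95 <- sqrt(0.95 * 0.05 / n) * k * (b - a)
    se_rcl <- 100 * sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(ing$mean - mean_true), 3 * se_mean)
    expect_lt(abs(ing$p95 - p95_true), 3 * se_p95)
    expect_lt(abs(ing$rcl_percent - 100 * p_true), 3 * se_rcl)
  }
})

test_that("identical config and seed reproduce bit-identical summaries", {
  mc <- mc_config(n_iterations = 500, seed = 77)
  r1 <- mc_risk(mc)
  r2 <- mc_risk(mc)
  expect_identical(r1$summary, r2$summary)
  r3 <- mc_risk(mc_config(n_iterations = 500, seed = 78))
  expect_false(identical(r1$summary$mean, r3$summary$mean))
})

test_that("per-variable child streams isolate each input's draws", {
  mc1 <- mc_config(n_iterations = 300, seed = 9)
  specs2 <- default_exposure_specs()
  # widen one variable only: the concentration draws must not move
  specs2$infants$BW <- dist_spec("normal", mean = 6.9, sd = 2,
                                 truncate = c(1, 30))
  mc2 <- mc_config(n_iterations = 300, seed = 9, exposure = specs2)
  d1 <- mc_risk(mc1, chemicals = "NO3")$draws[["NO3.infants"]]
  d2 <- mc_risk(mc2, chemicals = "NO3")$draws[["NO3.infants"]]
  expect_identical(d1$C, d2$C)
  expect_identical(d1$IR_w, d2$IR_w)
  expect_false(identical(d1$BW, d2$BW))
})

test_that("empirical concentration mode resamples the measured values", {
  tab <- generate_samples(synthetic_config(seed = 14))
  mc <- mc_config(n_iterations = 400, seed = 2,
                  concentration_mode = "empirical")
  expect_error(mc_risk(mc), "sample table")
  res <- mc_risk(mc, table = tab)
  expect_true(all(res$draws[["NO3.infants"]]$C %in% tab$NO3))
})

test_that("sensitivity attributes all variance to the only varying input", {
  mc <- mc_config(
    n_iterations = 1000, seed = 4,
    concentration = list(NO3 = dist_spec("uniform", min = 10, max = 60)),
    exposure = default_exposure_specs(spread = 0))
  res <- mc_risk(mc, chemicals = "NO3")
  s <- risk_sensitivity(res)
  si <- s[s$age_group == "infants", ]
  expect_equal(si$contribution_percent[si$variable == "C"], 100,
               tolerance = 1e-9)
  expect_true(all(si$contribution_percent[si$variable != "C"] == 0))
  expect_true(all(si$constant[si$variable %in% c("Kp", "CF")]))
})

test_that("body weight contributes negatively and contributions sum to 100", {
  res <- mc_risk(mc_config(n_iterations = 2000, seed = 31))
  s <- risk_sensitivity(res)
  for (grp in split(s, paste(s$chemical, s$age_group))) {
    expect_equal(sum(abs(grp$contribution_percent)), 100, tolerance = 1e-9)
    expect_lt(grp$contribution_percent[grp$variable == "BW"], 0)
  }
})

test_that("two multiplicative inputs with equal CV contribute about equally", {
  # HQ = C * IR * const: lognormal C and IR with the same log-sd
  mc <- mc_config(
    n_iterations = 8000, seed = 12,
    concentration = list(NO3 = dist_spec("lognormal", meanlog = 3, sdlog = 0.4)),
    exposure = local({
      sp <- default_exposure_specs(spread = 0)
      sp$infants$IR_w <- dist_spec("lognormal", meanlog = 0, sdlog = 0.4)
      sp
    }))
  s <- risk_sensitivity(mc_risk(mc, chemicals = "NO3"))
  si <- s[s$age_group == "infants", ]
  cc <- si$contribution_percent[si$variable == "C"]
  ci <- si$contribution_percent[si$variable == "IR_w"]
  expect_lt(abs(cc - ci), 6)  # symmetry up to Monte Carlo noise
})

test_that("uncertainty report enumerates the run's assumptions", {
  mc <- mc_config(n_iterations = 10000, seed = 3)
  rep_lines <- uncertainty_report(mc)
  expect_true(any(grepl("10000", rep_lines)))
  expect_true(any(grepl("logistic", rep_lines)))
  allpt <- mc_config(n_iterations = 100,
                     concentration = list(NO3 = dist_spec("point", value = 40)),
                     exposure = default_exposure_specs(spread = 0))
  expect_true(any(grepl("deterministic-equivalent", uncertainty_report(allpt))))
  tr <- mc_config(truncate_conc_at_zero = TRUE)
  expect_true(any(grepl("truncated to \\[0, Inf\\]", uncertainty_report(tr))))
})
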