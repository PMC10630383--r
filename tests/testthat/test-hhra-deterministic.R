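# Dose equations, hazard quotient/index, risk certainty level, and the
# deterministic risk table.

ref_profile <- function() {
  exposure_profile("adults", IR_w = 2.5, EF_r = 365, ED = 30, BW = 57.5,
                   SA = 18000, Kp = 0.001, ET = 0.5, CF = 0.001, AT_r = 10950)
}

test_that("ingestion dose matches the hand-evaluated equation", {
  pr <- ref_profile()
  expect_equal(add_ingestion(45, pr),
               45 * 2.5 * 365 * 30 / (57.5 * 10950), tolerance = 1e-12)
  expect_equal(add_ingestion(45, pr), 1.95652173913, tolerance = 1e-9)
  expect_equal(add_ingestion(0, pr), 0)
  # linearity in concentration
  expect_identical(add_ingestion(90, pr), 2 * add_ingestion(45, pr))
  expect_equal(add_ingestion(c(1, 7), pr), c(1, 7) * add_ingestion(1, pr),
               tolerance = 1e-12)
})

test_that("dermal dose matches the hand-evaluated equation", {
  pr <- ref_profile()
  expect_equal(add_dermal(100, pr),
               100 * 18000 * 0.001 * 365 * 30 * 0.5 * 0.001 / (57.5 * 10950),
               tolerance = 1e-12)
  expect_equal(add_dermal(100, pr), 0.01565217391, tolerance = 1e-9)
  expect_equal(add_dermal(0, pr), 0)
  # inverse proportionality to body weight
  half <- exposure_profile("adults", IR_w = 2.5, EF_r = 365, ED = 30,
                           BW = 57.5 / 2, SA = 18000, Kp = 0.001, ET = 0.5,
                           CF = 0.001, AT_r = 10950)
  expect_equal(add_dermal(100, half), 2 * add_dermal(100, pr),
               tolerance = 1e-12)
})

test_that("hazard quotient and index follow their definitions", {
  expect_equal(hazard_quotient(1.6, 1.6), 1)
  expect_equal(hazard_quotient(1.95652173913, 1.6), 1.22282608696,
               tolerance = 1e-9)
  expect_equal(hazard_quotient(0, 1.6), 0)
  expect_error(hazard_quotient(1, 0), "> 0")
  expect_equal(hazard_index(1.2, 0.005), 1.205)
  expect_equal(hazard_index(0, 0), 0)
  hq <- cbind(runif(20), runif(20))
  expect_true(all(hazard_index(hq[, 1], hq[, 2]) >= pmax(hq[, 1], hq[, 2])))
})

test_that("risk certainty level counts strict exceedances of the threshold", {
  expect_equal(rcl(c(0.5, 1.2, 2.0, 0.9)), 50)
  expect_equal(rcl(c(0.2, 1.0, 0.7)), 0)     # exactly 1 is not above 1
  expect_equal(rcl(rep(2, 5)), 100)
  expect_error(rcl(numeric(0)), "non-empty")
  # invariance under a joint strictly monotone transform of values + threshold
  v <- c(0.3, 0.8, 1.4, 2.2, 0.99)
  expect_equal(rcl(exp(v), threshold = exp(1)), rcl(v))
  expect_equal(rcl(10 * v + 2, threshold = 12), rcl(v))
})

test_that("deterministic risk table summarises per-sample hazard quotients", {
  one <- water_row(NO3 = 45, F = 1)
  d1 <- deterministic_risk_table(one)
  ing <- d1[d1$chemical == "NO3" & d1$pathway == "ingestion" &
              d1$age_group == "adults", ]
  pr <- default_exposure_profiles()$adults
  expect_equal(ing$mean, hazard_quotient(add_ingestion(45, pr), 1.6),
               tolerance = 1e-12)
  expect_equal(ing$mean, ing$median)
  expect_equal(ing$sd, 0)

  tab <- generate_samples(synthetic_config(seed = 21))
  det <- deterministic_risk_table(tab)
  # ordering of the distributional summary
  expect_true(all(det$p5 <= det$median + 1e-12))
  expect_true(all(det$median <= det$p95 + 1e-12))
  expect_true(all(det$rcl_percent >= 0 & det$rcl_percent <= 100))
  # HI row dominates each pathway HQ row, and so does its RCL
  for (ag in c("infants", "adults")) {
    hi <- det[det$chemical == "NO3" & det$age_group == ag, ]
    comb <- hi[hi$pathway == "combined", ]
    ing <- hi[hi$pathway == "ingestion", ]
    expect_gte(comb$mean, ing$mean)
    expect_gte(comb$rcl_percent, ing$rcl_percent)
  }
})

test_that("deterministic summaries scale linearly with concentration", {
  tab <- generate_samples(synthetic_config(n_samples = 9, seed = 13))
  det <- deterministic_risk_table(tab)
  scaled <- as.data.frame(tab)
  scaled$NO3 <- scaled$NO3 * 3
  scaled[["F"]] <- scaled[["F"]] * 3
  det3 <- deterministic_risk_table(sample_table(scaled))
  for (col in c("mean", "median", "sd", "p5", "p95")) {
    expect_equal(det3[[col]], 3 * det[[col]], tolerance = 1e-9)
  }
})

test_that("exposure profile validation rejects impossible values", {
  expect_error(exposure_profile("adults", IR_w = -1, EF_r = 365, ED = 30,
                                BW = 57.5, SA = 18000), "> 0")
  expect_error(exposure_profile("adults", IR_w = 2, EF_r = 400, ED = 30,
                                BW = 57.5, SA = 18000), "365")
})
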