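# Piper and Gibbs classification, ionic ratios, OLS scatter fits, and the
# simplified saturation index.

test_that("Piper percentages match hand meq arithmetic", {
  tab <- water_row(Ca = 60, Mg = 12, Na = 23, K = 2, HCO3 = 244, Cl = 35.5,
                   SO4 = 48)
  pi <- piper_classify(tab)
  s <- pi$samples
  expect_equal(s$pct_Ca, 59.5, tolerance = 0.1)
  expect_equal(s$pct_Mg, 19.6, tolerance = 0.1)
  expect_equal(s$pct_NaK, 20.9, tolerance = 0.1)
  expect_equal(s$pct_HCO3, 66.7, tolerance = 0.1)
  expect_equal(s$pct_Cl, 16.7, tolerance = 0.1)
  expect_equal(s$pct_SO4, 16.7, tolerance = 0.1)
  expect_equal(s$facies, "Ca-Mg-HCO3")
  expect_equal(s$pct_Ca + s$pct_Mg + s$pct_NaK, 100)
  expect_equal(s$pct_HCO3 + s$pct_Cl + s$pct_SO4, 100)
})

test_that("end-member waters classify to their known facies and types", {
  # pure Ca(HCO3)2: 2 meq Ca vs 2 meq HCO3
  pure <- water_row(Ca = 40.08, Mg = 0, Na = 0, K = 0, HCO3 = 122.04,
                    Cl = 0, SO4 = 0, NO3 = 0, F = 0)
  s <- piper_classify(pure)$samples
  expect_equal(s$cation_zone, "Ca")
  expect_equal(s$anion_zone, "HCO3")
  expect_equal(s$water_type, "Ca-HCO3")
  expect_equal(s$facies, "Ca-Mg-HCO3")
  # pure NaCl water
  brine <- water_row(Ca = 0, Mg = 0, Na = 229.9, K = 0, HCO3 = 0,
                     Cl = 354.5, SO4 = 0, NO3 = 0, F = 0)
  sb <- piper_classify(brine)$samples
  expect_equal(sb$facies, "Na-K-Cl-SO4")
  expect_equal(sb$water_type, "Na-Cl")
  # zero ions: flagged unclassifiable, no crash
  zero <- water_row(Ca = 0, Mg = 0, Na = 0, K = 0, HCO3 = 0, Cl = 0,
                    SO4 = 0, NO3 = 0, F = 0)
  expect_true(piper_classify(zero)$samples$unclassifiable)
})

test_that("Piper outputs are scale invariant and facies sum to 100", {
  tab <- generate_samples(synthetic_config(seed = 17))
  pi1 <- piper_classify(tab)
  scaled <- as.data.frame(tab)
  ions <- c("Ca", "Mg", "Na", "K", "HCO3", "Cl", "SO4", "NO3", "F")
  scaled[ions] <- scaled[ions] * 4.2
  pi2 <- piper_classify(sample_table(scaled))
  expect_equal(pi2$samples$pct_Ca, pi1$samples$pct_Ca, tolerance = 1e-9)
  expect_equal(pi2$samples$facies, pi1$samples$facies)
  expect_equal(sum(pi1$facies_summary$percent), 100, tolerance = 1e-9)
  # every sample receives exactly one facies
  expect_false(anyNA(pi1$samples$facies))
})

test_that("Gibbs ratios are bounded and the classic corners classify", {
  corner <- function(r, tds) {
    tab <- water_row(Ca = 40.08 * (1 - r), Na = 22.99 * r, Mg = 0, K = 0,
                     HCO3 = 30.51, Cl = 17.725, SO4 = 0, NO3 = 0, F = 0,
                     TDS = tds)
    gibbs_classify(tab)
  }
  expect_equal(corner(0.2, 300)$zone_cation, "rock")
  expect_equal(corner(0.95, 30000)$zone_cation, "evaporation")
  expect_equal(corner(0.9, 15)$zone_cation, "precipitation")
  tab <- generate_samples(synthetic_config(seed = 18))
  g <- gibbs_classify(tab)
  expect_true(all(g$cation_ratio >= 0 & g$cation_ratio <= 1))
  expect_true(all(g$anion_ratio >= 0 & g$anion_ratio <= 1))
  # monotone in Na (cation panel)
  base <- as.data.frame(water_row())
  ratios <- vapply(c(10, 50, 120), function(na) {
    base$Na <- na
    gibbs_classify(sample_table(base))$cation_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_error(gibbs_classify(water_row(TDS = 0)), "TDS")
})

test_that("ionic ratios apply the published reading of Ca/Mg", {
  # 2 meq Ca vs 1 meq Mg: ratio exactly 2, boundary maps to calcite
  tab <- water_row(Ca = 2 * 20.04, Mg = 12.15)
  r <- ionic_ratios(tab)
  expect_equal(r$ca_mg, 2, tolerance = 1e-12)
  expect_equal(r$ca_mg_call, "calcite")
  expect_equal(ionic_ratios(water_row(Ca = 20.04, Mg = 12.15))$ca_mg_call,
               "dolomite")
  expect_equal(ionic_ratios(water_row(Ca = 3 * 20.04, Mg = 12.15))$ca_mg_call,
               "silicate weathering")
  # zero magnesium: flagged undefined, no crash
  r0 <- ionic_ratios(water_row(Mg = 0))
  expect_true(is.na(r0$ca_mg))
  expect_true(is.na(r0$ca_mg_call))
  # alkali fraction of total cations is a proportion
  expect_true(r$nak_tz >= 0 && r$nak_tz <= 1)
  # Ca >> SO4 on the meq scale sits below the equiline
  expect_equal(r$ca_so4_position, "below")
})

test_that("scatter fits agree with the closed-form normal equations", {
  x <- c(1, 2, 3, 4)
  f <- scatter_fit(x, 2 * x)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  set.seed(30)
  for (i in 1:5) {
    xi <- rnorm(20); yi <- rnorm(20)
    f <- scatter_fit(xi, yi)
    # brute-force normal equations
    sl <- cov(xi, yi) / var(xi)
    expect_equal(f$slope, sl, tolerance = 1e-10)
    expect_equal(f$intercept, mean(yi) - sl * mean(xi), tolerance = 1e-10)
    expect_equal(f$r_squared, cor(xi, yi)^2, tolerance = 1e-12)
  }
  expect_error(scatter_fit(c(1, 2), c(1, 2)), "3")
  expect_error(scatter_fit(rep(1, 5), rnorm(5)), "variance")
})

test_that("saturation index is zero at equilibrium and additive in logs", {
  # unit activity coefficients: Ca 1e-3 M and F 10^-3.8 M give IAP = Ksp
  eq <- water_row(Ca = 40.08, F = 10^-3.8 * 19.00 * 1000)
  si <- saturation_index(eq, "fluorite", activity = "unit")
  expect_equal(si$si, 0, tolerance = 1e-9)
  # hand case: Ca 1e-3 M, F 1e-4 M -> SI = -11 - (-10.6) = -0.4
  hand <- water_row(Ca = 40.08, F = 1.9)
  expect_equal(saturation_index(hand, "fluorite", activity = "unit")$si,
               -0.4, tolerance = 1e-9)
  # doubling F raises SI by 2 log10(2)
  dbl <- water_row(Ca = 40.08, F = 3.8)
  expect_equal(saturation_index(dbl, "fluorite", activity = "unit")$si -
                 saturation_index(hand, "fluorite", activity = "unit")$si,
               2 * log10(2), tolerance = 1e-9)
  # a zero required ion flags -Inf rather than crashing
  z <- saturation_index(water_row(F = 0), "fluorite")
  expect_false(z$defined)
  expect_equal(z$si, -Inf)
  # Debye-Hueckel activity corrections lower the index below the unit-gamma one
  tab <- generate_samples(synthetic_config(n_samples = 5, seed = 19))
  si_dh <- saturation_index(tab, "fluorite")
  si_un <- saturation_index(tab, "fluorite", activity = "unit")
  expect_true(all(si_dh$si < si_un$si))
  expect_true(all(si_dh$ionic_strength > 0))
})

test_that("calcite index responds to pH through the carbonate activity", {
  lo <- saturation_index(water_row(pH = 7), "calcite", activity = "unit")
  hi <- saturation_index(water_row(pH = 8), "calcite", activity = "unit")
  expect_equal(hi$si - lo$si, 1, tolerance = 1e-9)
})
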