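# Hydrochemical facies classification (Piper, Gibbs), ionic-ratio source
# diagnostics, scatter-plot OLS fits, and a simplified Debye-Hueckel mineral
# saturation index.

# molar masses (g/mol) for the nine major ions
.MOLAR_MASS <- c(Ca = 40.08, Mg = 24.31, Na = 22.99, K = 39.10,
                 HCO3 = 61.02, Cl = 35.45, SO4 = 96.06, NO3 = 62.00, F = 19.00)

#' Piper trilinear classification
#'
#' Computes the cation (Ca, Mg, Na+K) and anion (HCO3, Cl, SO4) percentage
#' triples on a meq basis, the dominance zone of each triangle (an ion is
#' dominant when it holds more than 50% of its triangle, otherwise
#' "no dominant"), the central-diamond hydrochemical facies (from the alkaline
#' earth vs alkali and weak acid vs strong acid percentages), and a water-type
#' label formed by the ions that cumulatively contribute at least 50% of their
#' triangle, in decreasing order.
#'
#' All outputs are invariant to a common scaling of the ion concentrations.
#'
#' @param table A [sample_table()].
#' @return A list of class `"piper_result"` with `samples` (per-sample data
#'   frame of percentages and labels) and `facies_summary` (facies percentage
#'   table).
#' @export
piper_classify <- function(table) {
  meq <- to_meq(table)
  n <- nrow(meq)
  cat_tot <- rowSums(meq[, .CATIONS, drop = FALSE])
  an_tot <- rowSums(meq[, .ANIONS[1:3], drop = FALSE])  # HCO3, Cl, SO4
  unclassifiable <- cat_tot == 0 | an_tot == 0
  pct_ca <- 100 * meq[, "Ca"] / cat_tot
  pct_mg <- 100 * meq[, "Mg"] / cat_tot
  pct_nak <- 100 * (meq[, "Na"] + meq[, "K"]) / cat_tot
  pct_hco3 <- 100 * meq[, "HCO3"] / an_tot
  pct_cl <- 100 * meq[, "Cl"] / an_tot
  pct_so4 <- 100 * meq[, "SO4"] / an_tot

  dominance <- function(p, labels) {
    lab <- rep("no dominant", length(p[[1]]))
    for (i in seq_along(labels)) lab[p[[i]] > 50] <- labels[i]
    lab
  }
  cation_zone <- dominance(list(pct_ca, pct_mg, pct_nak), c("Ca", "Mg", "Na+K"))
  anion_zone <- dominance(list(pct_hco3, pct_cl, pct_so4), c("HCO3", "Cl", "SO4"))

  alk_earth <- pct_ca + pct_mg       # diamond x: alkaline earths vs alkalis
  weak_acid <- pct_hco3              # diamond y: weak acids vs strong acids
  facies <- ifelse(alk_earth > 50,
                   ifelse(weak_acid > 50, "Ca-Mg-HCO3", "Ca-Mg-Cl-SO4"),
                   ifelse(weak_acid > 50, "Na-K-HCO3", "Na-K-Cl-SO4"))

  cum_type <- function(p, labels) {
    vapply(seq_along(p[[1]]), function(i) {
      v <- c(p[[1]][i], p[[2]][i], p[[3]][i])
      if (anyNA(v) || any(!is.finite(v))) return(NA_character_)
      names(v) <- labels
      v <- sort(v, decreasing = TRUE)
      k <- which(cumsum(v) >= 50)[1L]
      paste(names(v)[seq_len(k)], collapse = "-")
    }, character(1))
  }
  water_type <- paste(cum_type(list(pct_ca, pct_mg, pct_nak), c("Ca", "Mg", "Na")),
                      cum_type(list(pct_hco3, pct_cl, pct_so4),
                               c("HCO3", "Cl", "SO4")), sep = "-")

  samples <- data.frame(
    sample_id = rownames(meq) %||% paste0("S", seq_len(n)),
    pct_Ca = pct_ca, pct_Mg = pct_mg, pct_NaK = pct_nak,
    pct_HCO3 = pct_hco3, pct_Cl = pct_cl, pct_SO4 = pct_so4,
    cation_zone = cation_zone, anion_zone = anion_zone,
    facies = facies, water_type = water_type,
    unclassifiable = unclassifiable,
    stringsAsFactors = FALSE, row.names = NULL
  )
  samples[unclassifiable, c("cation_zone", "anion_zone", "facies",
                            "water_type")] <- NA_character_
  ok <- !unclassifiable
  tab <- table(samples$facies[ok])
  out <- list(
    samples = samples,
    facies_summary = data.frame(
      facies = names(tab), n = as.integer(tab),
      percent = 100 * as.integer(tab) / sum(ok),
      stringsAsFactors = FALSE)
  )
  class(out) <- "piper_result"
  out
}

#' @export
print.piper_result <- function(x, ...) {
  cat("Piper classification, n = ", nrow(x$samples), "\n", sep = "")
  print(x$facies_summary, row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# even-odd ray casting; boundary points count as inside
.point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    if ((py - yi) * (xj - xi) == (px - xi) * (yj - yi) &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

#' Gibbs boomerang boundary polygons
#'
#' Vertex sets, in (ion ratio, log10 TDS) space, delimiting the three classic
#' Gibbs zones: precipitation dominance (dilute, high ratio), rock (water-rock
#' interaction) dominance, and evaporation dominance (saline, high ratio).
#' The classic diagram is drawn, not defined, in the literature; these
#' vertices are this package's digitization of the familiar boomerang and can
#' be replaced wholesale by the caller.
#'
#' @return Named list of two-column matrices (`ratio`, `log10_tds`).
#' @export
gibbs_polygons <- function() {
  list(
    precipitation = cbind(ratio = c(0.35, 1.00, 1.00, 0.35),
                          log10_tds = c(0.30, 0.30, 1.80, 1.50)),
    rock = cbind(ratio = c(0.02, 0.50, 0.90, 0.85, 0.50, 0.02),
                 log10_tds = c(1.85, 1.70, 2.40, 3.00, 3.10, 2.70)),
    evaporation = cbind(ratio = c(0.50, 0.85, 1.00, 1.00, 0.55),
                        log10_tds = c(3.10, 3.00, 3.40, 4.80, 4.10))
  )
}

#' Gibbs mechanism classification
#'
#' Computes the Gibbs cation ratio `Na/(Na + Ca)` and anion ratio
#' `Cl/(Cl + HCO3)` (meq basis, both bounded in \code{[0, 1]}) and places each
#' sample against `TDS` within the precipitation-, rock- or
#' evaporation-dominance polygon of both panels. The sample-level zone is the
#' panel consensus; on disagreement the cation-panel zone is kept and the
#' sample flagged discordant. Points inside no polygon are `"outside"`.
#'
#' @param table A [sample_table()].
#' @param polygons Zone polygons, see [gibbs_polygons()].
#' @return Data frame of class `"gibbs_result"`.
#' @export
gibbs_classify <- function(table, polygons = gibbs_polygons()) {
  meq <- to_meq(table)
  df <- as.data.frame(table)
  tds <- df$TDS
  if (any(tds <= 0)) stop("TDS must be positive for Gibbs classification")
  cation_ratio <- meq[, "Na"] / (meq[, "Na"] + meq[, "Ca"])
  anion_ratio <- meq[, "Cl"] / (meq[, "Cl"] + meq[, "HCO3"])
  zone_of <- function(r, y) {
    if (is.na(r)) return(NA_character_)
    for (z in names(polygons)) {
      if (.point_in_poly(r, y, polygons[[z]])) return(z)
    }
    "outside"
  }
  y <- log10(tds)
  zc <- vapply(seq_along(y), function(i) zone_of(cation_ratio[i], y[i]),
               character(1))
  za <- vapply(seq_along(y), function(i) zone_of(anion_ratio[i], y[i]),
               character(1))
  zone <- ifelse(zc == za, zc, zc)
  out <- data.frame(
    sample_id = df$sample_id %||% paste0("S", seq_along(y)),
    cation_ratio = cation_ratio, anion_ratio = anion_ratio, tds = tds,
    zone_cation = zc, zone_anion = za, zone = zone,
    discordant = zc != za,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("gibbs_result", "data.frame")
  out
}

#' Ionic-ratio source diagnostics
#'
#' Per-sample meq-basis ratios used in source apportionment: `Ca/Mg` (with the
#' customary reading: about 1 suggests dolomite dissolution, 1-2 calcite,
#' above 2 silicate weathering), `Na/Ca` (evapotranspiration vs rock-water
#' control on Ca activity), `HCO3/Ca` (fluoride-enrichment potential),
#' `(Na+K)/TZ+` where TZ+ is the total cation charge, and the position of each
#' sample relative to the Ca = SO4 equiline. Ratios with a zero denominator
#' are flagged undefined rather than raising an error.
#'
#' @param table A [sample_table()].
#' @return Data frame of class `"ionic_ratios"` with the ratios, the Ca/Mg
#'   categorical call (`dolomite` in \code{[0.9, 1.1]}, `calcite` up to and
#'   including 2, `silicate weathering` above 2, `Mg-enriched` below 0.9) and
#'   the equiline position (`below`/`above`/`on`).
#' @export
ionic_ratios <- function(table) {
  meq <- to_meq(table)
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  ca_mg <- safe_div(meq[, "Ca"], meq[, "Mg"])
  tz <- rowSums(meq[, .CATIONS, drop = FALSE])
  ca_mg_call <- rep(NA_character_, length(ca_mg))
  ca_mg_call[!is.na(ca_mg) & ca_mg < 0.9] <- "Mg-enriched"
  ca_mg_call[!is.na(ca_mg) & ca_mg >= 0.9 & ca_mg <= 1.1] <- "dolomite"
  ca_mg_call[!is.na(ca_mg) & ca_mg > 1.1 & ca_mg <= 2] <- "calcite"
  ca_mg_call[!is.na(ca_mg) & ca_mg > 2] <- "silicate weathering"
  d <- meq[, "Ca"] - meq[, "SO4"]
  out <- data.frame(
    sample_id = rownames(meq) %||% paste0("S", seq_len(nrow(meq))),
    ca_mg = ca_mg, na_ca = safe_div(meq[, "Na"], meq[, "Ca"]),
    hco3_ca = safe_div(meq[, "HCO3"], meq[, "Ca"]),
    nak_tz = safe_div(meq[, "Na"] + meq[, "K"], tz),
    ca_mg_call = ca_mg_call,
    ca_so4_position = ifelse(abs(d) < 1e-9, "on",
                             ifelse(d > 0, "below", "above")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "basis") <- "meq/L"
  class(out) <- c("ionic_ratios", "data.frame")
  out
}

#' Ordinary least squares scatter fit
#'
#' The simple bivariate regression behind a hydrochemical scatter plot:
#' `y = slope * x + intercept` with `r_squared` equal to the squared Pearson
#' correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points; `x` must
#'   vary).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
scatter_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("scatter_fit needs at least 3 complete points")
  if (stats::sd(x) == 0) stop("scatter_fit: x has zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = unname(stats::cor(x, y)^2), n = length(x))
}

# Debye-Hueckel ion size parameters (Angstrom) for the species used in the
# simplified saturation indices
.DH_A <- 0.5085
.DH_B <- 0.3281
.ION_SIZE <- c(Ca = 6.0, Mg = 8.0, Na = 4.0, K = 3.0, HCO3 = 4.0, CO3 = 4.5,
               Cl = 3.0, SO4 = 4.0, NO3 = 3.0, F = 3.5)
.ION_CHARGE <- c(Ca = 2, Mg = 2, Na = 1, K = 1, HCO3 = -1, CO3 = -2, Cl = -1,
                 SO4 = -2, NO3 = -1, F = -1)

.log_gamma <- function(ion, I) {
  z <- .ION_CHARGE[[ion]]
  -.DH_A * z^2 * sqrt(I) / (1 + .DH_B * .ION_SIZE[[ion]] * sqrt(I))
}

#' Simplified mineral saturation index
#'
#' `SI = log10(IAP / Ksp)` for fluorite (`Ca F2`) or calcite (`CaCO3`), from
#' the measured major-ion composition: molalities approximated by molarities
#' from mg/L, single-ion activity coefficients by the extended Debye-Hueckel
#' equation with ionic strength over all nine measured ions, and equilibrium
#' constants at 25 degrees C (fluorite Ksp 10^-10.6, calcite Ksp 10^-8.48,
#' second carbonate dissociation K2 10^-10.33), all overridable. The carbonate
#' activity for calcite is derived from bicarbonate and pH. This is a
#' screening-level index, not a full speciation model (no ion pairing, no
#' pCO2 solving).
#'
#' @param table A [sample_table()].
#' @param mineral `"fluorite"` or `"calcite"`.
#' @param temperature Temperature in degrees C; the shipped constants are
#'   25 degree values, so other temperatures trigger a warning.
#' @param activity `"debye-huckel"` (default) or `"unit"` (all activity
#'   coefficients 1, useful for hand checks).
#' @param log_ksp Log10 solubility product override.
#' @return Data frame of class `"saturation_result"`: `sample_id`,
#'   `ionic_strength` (mol/L), the activity coefficients used, `si` (log10
#'   units; `-Inf` with `defined = FALSE` when a required ion is zero).
#' @export
saturation_index <- function(table, mineral = c("fluorite", "calcite"),
                             temperature = 25,
                             activity = c("debye-huckel", "unit"),
                             log_ksp = NULL) {
  mineral <- match.arg(mineral)
  activity <- match.arg(activity)
  if (!isTRUE(all.equal(temperature, 25))) {
    warning("equilibrium constants are 25 degree C values; results at ",
            temperature, " degrees are approximate", call. = FALSE)
  }
  if (is.null(log_ksp)) log_ksp <- switch(mineral, fluorite = -10.6,
                                          calcite = -8.48)
  log_k2 <- -10.33  # HCO3- = H+ + CO3--
  df <- as.data.frame(table)
  # molarity (mol/L) per ion
  mol <- sapply(names(.MOLAR_MASS), function(ion) {
    df[[ion]] / .MOLAR_MASS[[ion]] / 1000
  })
  mol <- matrix(mol, nrow = nrow(df), dimnames = list(NULL, names(.MOLAR_MASS)))
  I <- 0.5 * rowSums(sweep(mol, 2L, .ION_CHARGE[colnames(mol)]^2, "*"))
  lg <- function(ion) {
    if (activity == "unit") rep(0, nrow(df)) else
      vapply(I, function(ii) .log_gamma(ion, ii), numeric(1))
  }
  if (mineral == "fluorite") {
    lg_ca <- lg("Ca"); lg_f <- lg("F")
    log_iap <- log10(mol[, "Ca"]) + lg_ca + 2 * (log10(mol[, "F"]) + lg_f)
    gammas <- data.frame(gamma_Ca = 10^lg_ca, gamma_F = 10^lg_f)
  } else {
    lg_ca <- lg("Ca"); lg_hco3 <- lg("HCO3")
    # carbonate activity from the bicarbonate mass action: aCO3 = aHCO3*K2/aH
    log_a_co3 <- log10(mol[, "HCO3"]) + lg_hco3 + log_k2 + df$pH
    log_iap <- log10(mol[, "Ca"]) + lg_ca + log_a_co3
    gammas <- data.frame(gamma_Ca = 10^lg_ca, gamma_HCO3 = 10^lg_hco3)
  }
  si <- log_iap - log_ksp
  out <- cbind(
    data.frame(sample_id = df$sample_id %||% paste0("S", seq_len(nrow(df))),
               mineral = mineral, ionic_strength = I,
               stringsAsFactors = FALSE),
    gammas,
    data.frame(si = si, defined = is.finite(si))
  )
  row.names(out) <- NULL
  class(out) <- c("saturation_result", "data.frame")
  out
}
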