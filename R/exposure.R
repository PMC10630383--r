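# Exposure profiles (point values) and their Monte Carlo distribution specs,
# per age group, plus the reference-dose registry.
#
# The shipped default profiles are SYNTHETIC: plausible high-end point values
# assembled from the ICMR/USEPA exposure-factor literature for an Indian rural
# population, intended for reproducible end-to-end runs, not as a substitute
# for site-specific survey data. The deterministic point values are deliberate
# upper-bound ("extreme value") choices; the Monte Carlo specs span the likely
# range below them, which is the standard conservative-vs-likely design of a
# paired deterministic/probabilistic assessment.

.AGE_GROUPS <- c("infants", "children", "teens", "adults")
.EXPO_VARS <- c("IR_w", "EF_r", "ED", "BW", "SA", "Kp", "ET", "CF")

#' Exposure profile for one age group
#'
#' Point values of the exposure variables entering the average-daily-dose
#' equations: water ingestion rate `IR_w` (L/day), exposure frequency `EF_r`
#' (days/year), exposure duration `ED` (years), body weight `BW` (kg), exposed
#' skin surface `SA` (cm^2), dermal permeability `Kp` (cm/h), exposure time
#' `ET` (h/day) and volumetric conversion `CF` (L/cm^3). The averaging time
#' `AT_r` (days) defaults to `ED * 365`, the non-carcinogenic convention.
#'
#' @param age_group One of `"infants"`, `"children"`, `"teens"`, `"adults"`.
#' @param IR_w,EF_r,ED,BW,SA,Kp,ET,CF Positive numerics (units above).
#' @param AT_r Averaging time in days (default `ED * 365`).
#' @return A list of class `"exposure_profile"`.
#' @export
exposure_profile <- function(age_group, IR_w, EF_r, ED, BW, SA,
                             Kp = 0.001, ET = 0.25, CF = 0.001,
                             AT_r = ED * 365) {
  age_group <- match.arg(age_group, .AGE_GROUPS)
  vals <- c(IR_w = IR_w, EF_r = EF_r, ED = ED, BW = BW, SA = SA,
            Kp = Kp, ET = ET, CF = CF, AT_r = AT_r)
  if (any(vals <= 0)) {
    stop("exposure profile (", age_group, "): all fields must be > 0 (",
         paste(names(vals)[vals <= 0], collapse = ", "), ")")
  }
  if (EF_r > 365) stop("EF_r cannot exceed 365 days/year")
  if (AT_r < ED) stop("AT_r (days) must be at least ED (years) expressed in days")
  structure(c(list(age_group = age_group), as.list(vals)),
            class = "exposure_profile")
}

#' Default (synthetic) exposure profiles
#'
#' High-end point values per age group for deterministic assessment. These are
#' synthetic defaults for reproducible runs; site studies should supply their
#' own via the YAML config.
#'
#' @return Named list of [exposure_profile()]s for the four age groups.
#' @export
default_exposure_profiles <- function() {
  list(
    infants  = exposure_profile("infants",  IR_w = 0.8, EF_r = 365, ED = 1,
                                BW = 6.9,  SA = 3800),
    children = exposure_profile("children", IR_w = 1.5, EF_r = 365, ED = 10,
                                BW = 18.6, SA = 8700),
    teens    = exposure_profile("teens",    IR_w = 2.0, EF_r = 365, ED = 7,
                                BW = 50.0, SA = 16000),
    adults   = exposure_profile("adults",   IR_w = 2.5, EF_r = 365, ED = 30,
                                BW = 57.5, SA = 18000)
  )
}

#' Default (synthetic) Monte Carlo exposure distribution specs
#'
#' For each age group, a named list of [dist_spec()]s for the distributed
#' exposure variables. Relative to the deterministic point values `p`:
#' `IR_w` triangular(0.3p, 0.6p, p); `EF_r` triangular(300, 350, 365);
#' `ED` uniform(0.25p, p); `BW` normal(p, 0.15p); `SA` normal(p, 0.1p);
#' `ET` triangular(0.5p, 0.8p, 1.2p); `Kp` and `CF` point. Central tendencies
#' sit below the conservative point values by design.
#'
#' @param profiles Point-value profiles the spreads are anchored to.
#' @param spread Scale factor on all spreads; `spread = 0` collapses every
#'   variable to a point spec (deterministic-equivalent configuration).
#' @return Named list (per age group) of named lists of [dist_spec()]s.
#' @export
default_exposure_specs <- function(profiles = default_exposure_profiles(),
                                   spread = 1) {
  stopifnot(spread >= 0)
  lapply(profiles, function(pr) {
    if (spread == 0) {
      sp <- lapply(.EXPO_VARS, function(v) dist_spec("point", value = pr[[v]]))
      return(stats::setNames(sp, .EXPO_VARS))
    }
    tri <- function(p, lo, mo, hi) {
      dist_spec("triangular", min = p * (1 - spread * (1 - lo)),
                mode = p * (1 - spread * (1 - mo)),
                max = p * (1 - spread * (1 - hi)))
    }
    list(
      IR_w = tri(pr$IR_w, 0.3, 0.6, 1.0),
      EF_r = dist_spec("triangular",
                       min = 365 - spread * 65, mode = 365 - spread * 15,
                       max = 365),
      ED = dist_spec("uniform", min = pr$ED * (1 - 0.75 * spread),
                     max = pr$ED),
      BW = dist_spec("normal", mean = pr$BW, sd = pmax(0.15 * spread, 1e-9) * pr$BW,
                     truncate = c(0.2 * pr$BW, 3 * pr$BW)),
      SA = dist_spec("normal", mean = pr$SA, sd = pmax(0.10 * spread, 1e-9) * pr$SA,
                     truncate = c(0.2 * pr$SA, 3 * pr$SA)),
      Kp = dist_spec("point", value = pr$Kp),
      ET = tri(pr$ET, 0.5, 0.8, 1.2),
      CF = dist_spec("point", value = pr$CF)
    )
  })
}

#' Reference dose registry
#'
#' Oral reference doses: 1.6 mg/kg/day for nitrate and 0.06 mg/kg/day for
#' fluoride (USEPA); the dermal RfD defaults to the same value per chemical,
#' as one RfD is customarily applied to both pathways for these ions.
#'
#' @param overrides Named list, e.g. `list(NO3 = list(ingestion = 1.6))`.
#' @return Data frame with columns `chemical`, `ingestion`, `dermal`.
#' @export
rfd_registry <- function(overrides = NULL) {
  rfd <- data.frame(
    chemical = c("NO3", "F"),
    ingestion = c(1.6, 0.06),
    dermal = c(1.6, 0.06),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (ch in names(overrides)) {
      i <- match(ch, rfd$chemical)
      if (is.na(i)) stop("unknown chemical in RfD overrides: ", ch)
      for (f in names(overrides[[ch]])) rfd[[f]][i] <- overrides[[ch]][[f]]
    }
  }
  if (any(rfd$ingestion <= 0) || any(rfd$dermal <= 0)) {
    stop("reference doses must be > 0")
  }
  rfd
}

.get_rfd <- function(rfd, chemical, pathway) {
  i <- match(chemical, rfd$chemical)
  if (is.na(i)) stop("no reference dose for chemical ", chemical)
  rfd[[pathway]][i]
}
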