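# Deterministic (point-estimate) human health risk assessment: average daily
# doses, hazard quotients, hazard index and the risk certainty level statistic.

#' Average daily dose via ingestion
#'
#' `ADD_ingestion = C_M * IR_w * EF_r * ED / (BW * AT_r)` in mg/kg/day, for a
#' chemical concentration `C_M` in mg/L. Linear in `C_M`.
#'
#' @param C_M Concentration(s) in mg/L (vectorised).
#' @param profile An [exposure_profile()].
#' @return ADD in mg/kg/day.
#' @export
add_ingestion <- function(C_M, profile) {
  C_M * profile$IR_w * profile$EF_r * profile$ED / (profile$BW * profile$AT_r)
}

#' Average daily dose via dermal contact
#'
#' `ADD_dermal = C_M * SA * Kp * EF_r * ED * ET * CF / (BW * AT_r)` in
#' mg/kg/day.
#'
#' @inheritParams add_ingestion
#' @return ADD in mg/kg/day.
#' @export
add_dermal <- function(C_M, profile) {
  C_M * profile$SA * profile$Kp * profile$EF_r * profile$ED * profile$ET *
    profile$CF / (profile$BW * profile$AT_r)
}

#' Hazard quotient
#'
#' `HQ = ADD / RfD` (unitless); HQ above 1 flags potential non-carcinogenic
#' risk for one pathway.
#'
#' @param ADD Average daily dose (mg/kg/day).
#' @param rfd Reference dose (mg/kg/day), must be positive.
#' @return HQ (unitless).
#' @export
hazard_quotient <- function(ADD, rfd) {
  if (any(rfd <= 0)) stop("reference dose must be > 0")
  ADD / rfd
}

#' Hazard index
#'
#' The pathway sum of one chemical's hazard quotients for one age group
#' (ingestion + dermal here).
#'
#' @param hq_ingestion,hq_dermal Hazard quotients (vectorised).
#' @return HI (unitless).
#' @export
hazard_index <- function(hq_ingestion, hq_dermal) hq_ingestion + hq_dermal

#' Risk certainty level
#'
#' The percentage of evaluated units (field samples, or Monte Carlo draws)
#' whose HQ or HI strictly exceeds the threshold, by default 1.
#'
#' @param values Non-empty numeric vector of HQ or HI values.
#' @param threshold Exceedance threshold (default 1; strict `>`).
#' @return Percentage in \code{[0, 100]}.
#' @examples
#' rcl(c(0.5, 1.2, 2.0, 0.9))  # 50
#' @export
rcl <- function(values, threshold = 1) {
  if (!length(values)) stop("rcl needs a non-empty vector")
  100 * sum(values > threshold) / length(values)
}

# summary statistics over a set of HQ/HI values: percentile method is linear
# interpolation between order statistics (quantile type 7, inclusive)
.risk_stats <- function(v) {
  q <- stats::quantile(v, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  data.frame(mean = mean(v), median = q[2], sd = stats::sd(v),
             p5 = q[1], p95 = q[3], rcl_percent = rcl(v))
}

#' Deterministic risk table
#'
#' Point-estimate assessment in which only the measured concentration varies
#' across samples: for each chemical, pathway and age group, the per-sample
#' hazard quotients (exposure variables at their point values) are summarised
#' by mean, median, SD, 5th and 95th percentiles and the risk certainty level;
#' the hazard index row summarises the per-sample ingestion + dermal sums.
#'
#' @param table A [sample_table()].
#' @param profiles Named list of [exposure_profile()]s.
#' @param rfd A [rfd_registry()].
#' @param chemicals Chemicals to assess (default nitrate and fluoride).
#' @return Data frame of class `"risk_summary"` with columns `chemical`,
#'   `pathway` (`ingestion`, `dermal`, `combined`), `age_group`, `approach`,
#'   `mean`, `median`, `sd`, `p5`, `p95`, `rcl_percent`.
#' @export
deterministic_risk_table <- function(table,
                                     profiles = default_exposure_profiles(),
                                     rfd = rfd_registry(),
                                     chemicals = c("NO3", "F")) {
  df <- as.data.frame(table)
  one_sample <- nrow(df) == 1L
  rows <- list()
  for (chem in chemicals) {
    conc <- df[[chem]]
    if (is.null(conc)) stop("chemical ", chem, " not present in sample table")
    for (ag in names(profiles)) {
      pr <- profiles[[ag]]
      hq_i <- hazard_quotient(add_ingestion(conc, pr), .get_rfd(rfd, chem, "ingestion"))
      hq_d <- hazard_quotient(add_dermal(conc, pr), .get_rfd(rfd, chem, "dermal"))
      hi <- hazard_index(hq_i, hq_d)
      for (pw in c("ingestion", "dermal", "combined")) {
        v <- switch(pw, ingestion = hq_i, dermal = hq_d, combined = hi)
        st <- if (one_sample) {
          data.frame(mean = v, median = v, sd = 0, p5 = v, p95 = v,
                     rcl_percent = rcl(v))
        } else .risk_stats(v)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(chemical = chem, pathway = pw, age_group = ag,
                     approach = "deterministic", stringsAsFactors = FALSE),
          st)
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  class(out) <- c("risk_summary", "data.frame")
  out
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Risk summary (", paste(unique(x$approach), collapse = " + "),
      "): HQ/HI statistics and risk certainty level\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4, ...)
  invisible(x)
}
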