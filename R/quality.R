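# Analytical QA (charge balance error), descriptive statistics and the named
# water-quality classification schemes.

#' Charge balance error per sample
#'
#' `CBE% = (sum cations - sum anions) / (sum cations + sum anions) * 100`,
#' with both sums in meq/L over the nine major ions. Laboratories accept an
#' analysis when |CBE| is at most 5%.
#'
#' @param table A [sample_table()].
#' @param tolerance Pass threshold on |CBE| in percent (default 5).
#' @return A data frame of class `"cbe_result"`: `sample_id`, `sum_cations`,
#'   `sum_anions`, `cbe_percent`, `pass`, `defined`. A sample whose ion totals
#'   are both zero has an undefined CBE (`defined = FALSE`, `cbe_percent = NA`).
#' @export
charge_balance_error <- function(table, tolerance = 5) {
  meq <- to_meq(table)
  cat_sum <- rowSums(meq[, .CATIONS, drop = FALSE])
  an_sum  <- rowSums(meq[, .ANIONS, drop = FALSE])
  tot <- cat_sum + an_sum
  cbe <- ifelse(tot > 0, 100 * (cat_sum - an_sum) / tot, NA_real_)
  out <- data.frame(
    sample_id = table$sample_id,
    sum_cations = cat_sum, sum_anions = an_sum,
    cbe_percent = cbe,
    pass = !is.na(cbe) & abs(cbe) <= tolerance,
    defined = !is.na(cbe),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("cbe_result", "data.frame")
  attr(out, "tolerance") <- tolerance
  out
}

#' Descriptive statistics per parameter
#'
#' Range, mean and sample standard deviation (n - 1 denominator) of each
#' canonical parameter, the usual summary table of a hydrochemical survey.
#'
#' @param table A [sample_table()].
#' @return Data frame with columns `parameter`, `min`, `max`, `mean`, `sd`.
#' @export
descriptive_stats <- function(table) {
  if (nrow(table) < 2L) stop("descriptive statistics need at least 2 samples")
  params <- canonical_parameters()
  df <- as.data.frame(table)
  data.frame(
    parameter = params,
    min = vapply(params, function(p) min(df[[p]]), numeric(1)),
    max = vapply(params, function(p) max(df[[p]]), numeric(1)),
    mean = vapply(params, function(p) mean(df[[p]]), numeric(1)),
    sd = vapply(params, function(p) stats::sd(df[[p]]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Build a classification scheme
#'
#' A scheme is an ordered set of contiguous bins `[lower, upper)` (the top bin
#' is closed above) that maps every value in its range to exactly one label.
#'
#' @param name Scheme name.
#' @param lower,upper Numeric vectors of bin bounds (contiguous,
#'   non-overlapping, increasing).
#' @param labels Character vector of bin labels.
#' @param gap_warn Optional list of `c(lo, hi)` intervals that are formally
#'   outside the cited scheme but are absorbed into the enclosing bin with a
#'   warning (used for schemes published with gaps).
#' @return An object of class `"classification_scheme"`.
#' @export
classification_scheme <- function(name, lower, upper, labels, gap_warn = NULL) {
  stopifnot(length(lower) == length(upper), length(lower) == length(labels))
  if (any(upper <= lower)) stop("scheme ", name, ": empty or inverted bin")
  if (length(lower) > 1L && any(abs(lower[-1L] - upper[-length(upper)]) > 1e-12)) {
    stop("scheme ", name, ": bins are not contiguous")
  }
  structure(
    list(name = name, lower = lower, upper = upper, labels = labels,
         gap_warn = gap_warn),
    class = "classification_scheme"
  )
}

#' Built-in water-quality classification schemes
#'
#' The classification schemes customary in groundwater-quality appraisal:
#' \describe{
#'   \item{`sawyer_mccarty_th`}{Total hardness (mg/L as CaCO3): soft < 75,
#'     moderately hard 75-150, hard 150-300, very hard > 300 (Sawyer & McCarty).}
#'   \item{`freeze_cherry_tds`}{TDS: freshwater < 1000, brackish 1000-10000,
#'     saline 10000-100000 mg/L (Freeze & Cherry).}
#'   \item{`davis_dewiest_tds`}{TDS: desirable < 500, permissible 500-1000,
#'     useful for irrigation 1000-3000 mg/L (Davis & DeWiest).}
#'   \item{`ec_salinity`}{EC (uS/cm): excellent/low < 250, moderately saline
#'     250-750, medium to high 750-2250, high > 2250; bin edges follow the
#'     irrigation-salinity convention and are configurable.}
#'   \item{`adimalla_no3`}{Nitrate health-risk classes: no risk < 45, high
#'     45-100, very high > 100 mg/L (Adimalla).}
#'   \item{`adimalla_f`}{Fluoride classes: dental caries < 0.5, required
#'     0.6-1.5, fluorosis 1.6-2.0 mg/L (Adimalla). The published scheme leaves
#'     0.5-0.6 and 1.5-1.6 unlabelled; such values are mapped to "required"
#'     with a warning.}
#' }
#'
#' @param name One of the scheme names above.
#' @return A [classification_scheme()].
#' @export
builtin_scheme <- function(name = c("sawyer_mccarty_th", "freeze_cherry_tds",
                                    "davis_dewiest_tds", "ec_salinity",
                                    "adimalla_no3", "adimalla_f")) {
  name <- match.arg(name)
  switch(name,
    sawyer_mccarty_th = classification_scheme(
      name, c(0, 75, 150, 300), c(75, 150, 300, Inf),
      c("soft", "moderately hard", "hard", "very hard")),
    freeze_cherry_tds = classification_scheme(
      name, c(0, 1000, 10000), c(1000, 10000, 100000),
      c("freshwater", "brackish", "saline")),
    davis_dewiest_tds = classification_scheme(
      name, c(0, 500, 1000), c(500, 1000, 3000),
      c("desirable", "permissible", "useful for irrigation")),
    ec_salinity = classification_scheme(
      name, c(0, 250, 750, 2250), c(250, 750, 2250, Inf),
      c("excellent/low", "moderately saline", "medium to high", "high")),
    adimalla_no3 = classification_scheme(
      name, c(0, 45, 100), c(45, 100, Inf),
      c("no risk", "high risk", "very high risk")),
    adimalla_f = classification_scheme(
      name, c(0, 0.5, 1.6), c(0.5, 1.6, 2.0),
      c("dental caries", "required", "fluorosis"),
      gap_warn = list(c(0.5, 0.6), c(1.5, 1.6)))
  )
}

#' Classify parameter values under a scheme
#'
#' Maps each value to exactly one label (lower bound inclusive, upper bound
#' exclusive; the top bin closed above) and tabulates label percentages, which
#' always sum to 100.
#'
#' @param values Numeric vector (one value per sample).
#' @param scheme A [classification_scheme()] or a [builtin_scheme()] name.
#' @param sample_ids Optional sample labels.
#' @return A list of class `"classification"`: `scheme`, `labels` (per sample)
#'   and `summary` (label, n, percent).
#' @export
classify <- function(values, scheme, sample_ids = NULL) {
  if (is.character(scheme)) scheme <- builtin_scheme(scheme)
  stopifnot(inherits(scheme, "classification_scheme"))
  k <- length(scheme$labels)
  lab <- rep(NA_character_, length(values))
  for (i in seq_len(k)) {
    top <- i == k || !is.finite(scheme$upper[i])
    hit <- values >= scheme$lower[i] &
      (if (top) values <= scheme$upper[i] else values < scheme$upper[i])
    lab[hit & is.na(lab)] <- scheme$labels[i]
  }
  if (anyNA(lab)) {
    stop("scheme ", scheme$name, " does not cover value(s): ",
         paste(unique(values[is.na(lab)]), collapse = ", "))
  }
  if (!is.null(scheme$gap_warn)) {
    for (g in scheme$gap_warn) {
      in_gap <- values > g[1] & values < g[2]
      if (any(in_gap)) {
        warning("scheme ", scheme$name, ": ", sum(in_gap), " value(s) in the ",
                "unlabelled interval (", g[1], ", ", g[2], ") mapped to the ",
                "enclosing bin", call. = FALSE)
      }
    }
  }
  counts <- table(factor(lab, levels = scheme$labels))
  out <- list(
    scheme = scheme$name,
    labels = stats::setNames(lab, sample_ids),
    summary = data.frame(
      label = names(counts), n = as.integer(counts),
      percent = 100 * as.integer(counts) / length(values),
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "classification"
  out
}

#' @export
print.classification <- function(x, ...) {
  cat("Classification (", x$scheme, "), n = ", length(x$labels), "\n", sep = "")
  print(x$summary, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.cbe_result <- function(x, ...) {
  tol <- attr(x, "tolerance")
  cat("Charge balance error: ", sum(x$pass), "/", nrow(x),
      " samples within +/-", tol, "%\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4, ...)
  invisible(x)
}
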