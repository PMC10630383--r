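# The central model-fitting interface: hhra() runs the paired deterministic /
# probabilistic non-carcinogenic assessment on a sample table and returns a
# classed object with print, summary and plot methods.

#' Fit a non-carcinogenic human health risk assessment
#'
#' The front door of the package's risk module. Given a validated sample
#' table, `hhra()`:
#' \enumerate{
#'   \item runs the deterministic assessment ([deterministic_risk_table()]):
#'     per-sample hazard quotients with exposure variables at their point
#'     values;
#'   \item fits the concentration marginals of the target chemicals by
#'     GoF-ranked auto-selection ([fit_distribution()]), unless explicit
#'     concentration specs are supplied in `mc`;
#'   \item runs the Monte Carlo simulation ([mc_risk()]) and the
#'     contribution-to-variance sensitivity analysis ([risk_sensitivity()]).
#' }
#'
#' @param table A [sample_table()].
#' @param profiles Named list of [exposure_profile()]s.
#' @param rfd A [rfd_registry()].
#' @param chemicals Chemicals to assess (columns of `table`).
#' @param approach `"both"` (default), `"deterministic"` or `"probabilistic"`.
#' @param mc An [mc_config()]. When `fit_concentration = TRUE` its
#'   concentration specs are replaced by the families fitted to the table.
#' @param fit_concentration Refit the concentration marginals from `table`
#'   (default `TRUE`)? Ignored when `mc$concentration_mode = "empirical"`.
#' @param candidates Candidate families for the concentration auto-fit.
#' @param gof_pvalues Compute bootstrap Anderson-Darling p-values for the
#'   concentration fits?
#' @return An object of class `"hhra"` with elements `deterministic`,
#'   `probabilistic` (an [mc_risk()] result), `sensitivity`, `gof` (named list
#'   of [fit_distribution()] results), `uncertainty`, `table`, `profiles`,
#'   `rfd` and `call`.
#' @examples
#' tab <- generate_samples(synthetic_config(seed = 7))
#' fit <- hhra(tab, mc = mc_config(n_iterations = 500))
#' summary(fit)
#' @export
hhra <- function(table, profiles = default_exposure_profiles(),
                 rfd = rfd_registry(), chemicals = c("NO3", "F"),
                 approach = c("both", "deterministic", "probabilistic"),
                 mc = mc_config(), fit_concentration = TRUE,
                 candidates = c("normal", "lognormal", "uniform", "logistic"),
                 gof_pvalues = TRUE) {
  approach <- match.arg(approach)
  stopifnot(inherits(table, "sample_table"))
  out <- list(call = match.call(), table = table, profiles = profiles,
              rfd = rfd, chemicals = chemicals,
              deterministic = NULL, probabilistic = NULL,
              sensitivity = NULL, gof = NULL, uncertainty = NULL)
  if (approach %in% c("both", "deterministic")) {
    out$deterministic <- deterministic_risk_table(table, profiles, rfd, chemicals)
  }
  if (approach %in% c("both", "probabilistic")) {
    if (fit_concentration && mc$concentration_mode == "fitted") {
      gof <- list()
      conc <- list()
      for (chem in chemicals) {
        fit <- fit_distribution(as.data.frame(table)[[chem]],
                                candidates = candidates,
                                pvalues = gof_pvalues, seed = mc$seed)
        if (mc$truncate_conc_at_zero) fit$spec$truncate <- c(0, Inf)
        gof[[chem]] <- fit
        conc[[chem]] <- fit$spec
      }
      mc$concentration <- conc
      out$gof <- gof
    }
    out$probabilistic <- mc_risk(mc, profiles, rfd, chemicals, table = table)
    out$sensitivity <- risk_sensitivity(out$probabilistic, output = "HI")
    out$uncertainty <- uncertainty_report(mc, profiles)
  }
  class(out) <- "hhra"
  out
}

#' @export
print.hhra <- function(x, ...) {
  cat("Non-carcinogenic human health risk assessment\n")
  cat("  samples:   ", nrow(x$table), "\n", sep = "")
  cat("  chemicals: ", paste(x$chemicals, collapse = ", "), "\n", sep = "")
  cat("  age groups:", paste(names(x$profiles), collapse = ", "), "\n")
  if (!is.null(x$deterministic)) cat("  deterministic assessment: done\n")
  if (!is.null(x$probabilistic)) {
    cat("  probabilistic assessment: ", x$probabilistic$config$n_iterations,
        " Monte Carlo iterations (seed ", x$probabilistic$config$seed, ")\n",
        sep = "")
  }
  cat("Use summary() for the HQ/HI tables.\n")
  invisible(x)
}

#' Summarise an hhra fit
#'
#' @param object An `"hhra"` object.
#' @param ... Unused.
#' @return A list of class `"summary.hhra"` with the deterministic and
#'   probabilistic risk tables and the hazard-index risk certainty levels side
#'   by side.
#' @export
summary.hhra <- function(object, ...) {
  both <- rbind(object$deterministic,
                if (!is.null(object$probabilistic)) object$probabilistic$summary)
  rcl_hi <- NULL
  if (!is.null(both)) {
    hi <- both[both$pathway == "combined", ]
    rcl_hi <- stats::reshape(
      hi[, c("chemical", "age_group", "approach", "rcl_percent")],
      idvar = c("chemical", "age_group"), timevar = "approach",
      direction = "wide")
    names(rcl_hi) <- sub("rcl_percent\\.", "rcl_", names(rcl_hi))
    row.names(rcl_hi) <- NULL
    class(rcl_hi) <- "data.frame"
  }
  structure(list(risk = both, rcl_hi = rcl_hi,
                 sensitivity = object$sensitivity),
            class = "summary.hhra")
}

#' @export
print.summary.hhra <- function(x, ...) {
  if (!is.null(x$risk)) print(x$risk)
  if (!is.null(x$rcl_hi)) {
    cat("\nHazard-index risk certainty levels (% of units with HI > 1):\n")
    print(x$rcl_hi, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot an hhra fit
#'
#' `type = "tornado"` draws the contribution-to-variance tornado bars for one
#' chemical and age group; `type = "hist"` draws the Monte Carlo hazard-index
#' histogram with the HI = 1 threshold marked.
#'
#' @param x An `"hhra"` object with a probabilistic component.
#' @param type `"tornado"` or `"hist"`.
#' @param chemical,age_group Which simulation to plot.
#' @param ... Passed to the underlying graphics call.
#' @return `x`, invisibly.
#' @export
plot.hhra <- function(x, type = c("tornado", "hist"), chemical = "NO3",
                      age_group = "infants", ...) {
  type <- match.arg(type)
  if (is.null(x$probabilistic)) stop("no probabilistic component to plot")
  if (type == "tornado") {
    s <- x$sensitivity
    s <- s[s$chemical == chemical & s$age_group == age_group & !s$constant, ]
    s <- s[order(abs(s$contribution_percent)), ]
    graphics::barplot(s$contribution_percent, names.arg = s$variable,
                      horiz = TRUE, las = 1,
                      xlab = "contribution to variance (%)",
                      main = paste0("HI sensitivity: ", chemical, ", ",
                                    age_group), ...)
    graphics::abline(v = 0)
  } else {
    dr <- x$probabilistic$draws[[paste(chemical, age_group, sep = ".")]]
    if (is.null(dr)) stop("no draws for ", chemical, " / ", age_group)
    graphics::hist(dr$HI, breaks = 60, xlab = "hazard index",
                   main = paste0("Monte Carlo HI: ", chemical, ", ",
                                 age_group), ...)
    graphics::abline(v = 1, lty = 2)
  }
  invisible(x)
}
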