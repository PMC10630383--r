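# Marginal distribution machinery for the Monte Carlo engine and the synthetic
# generator: distribution specs, density/CDF/quantile/sampling per family,
# maximum-likelihood fitting with Anderson-Darling / Kolmogorov-Smirnov /
# chi-square goodness-of-fit diagnostics, and auto-selection of the best family.

.DIST_FAMILIES <- c("point", "uniform", "normal", "lognormal", "triangular",
                    "logistic")

#' Distribution specification
#'
#' A small tagged container describing one marginal distribution, used for
#' Monte Carlo exposure variables and concentration inputs.
#'
#' Families and their parameters: `point` (`value`); `uniform` (`min`, `max`);
#' `normal` (`mean`, `sd`); `lognormal` (`meanlog`, `sdlog`); `triangular`
#' (`min`, `mode`, `max`); `logistic` (`location`, `scale`).
#'
#' @param family One of the families above.
#' @param ... Named family parameters.
#' @param truncate Optional `c(lo, hi)` truncation bounds (either may be
#'   infinite).
#' @return An object of class `"dist_spec"`.
#' @examples
#' dist_spec("logistic", location = 34.25, scale = 24.04)
#' dist_spec("uniform", min = 0.01, max = 1.97)
#' @export
dist_spec <- function(family, ..., truncate = NULL) {
  family <- match.arg(family, .DIST_FAMILIES)
  par <- list(...)
  need <- switch(family,
    point = "value", uniform = c("min", "max"), normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"), triangular = c("min", "mode", "max"),
    logistic = c("location", "scale"))
  missing <- setdiff(need, names(par))
  if (length(missing)) {
    stop("dist_spec(", family, "): missing parameter(s) ",
         paste(missing, collapse = ", "))
  }
  par <- par[need]
  if (family == "uniform" && par$min >= par$max) stop("uniform: min must be < max")
  if (family == "normal" && par$sd <= 0) stop("normal: sd must be > 0")
  if (family == "lognormal" && par$sdlog <= 0) stop("lognormal: sdlog must be > 0")
  if (family == "logistic" && par$scale <= 0) stop("logistic: scale must be > 0")
  if (family == "triangular" &&
      !(par$min <= par$mode && par$mode <= par$max && par$min < par$max)) {
    stop("triangular: need min <= mode <= max and min < max")
  }
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2L, truncate[1] < truncate[2])
  }
  structure(list(family = family, par = par, truncate = truncate),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(x$family, "(",
      paste(names(x$par), signif(unlist(x$par), 6), sep = " = ", collapse = ", "),
      ")", sep = "")
  if (!is.null(x$truncate)) {
    cat(" truncated to [", x$truncate[1], ", ", x$truncate[2], "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# triangular density/CDF/quantile (not in stats)
.dtri <- function(x, a, c, b) {
  d <- numeric(length(x))
  up <- x >= a & x < c
  dn <- x >= c & x <= b
  if (c > a) d[up] <- 2 * (x[up] - a) / ((b - a) * (c - a))
  if (b > c) d[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - c))
  if (c == a) d[x == a] <- 2 / (b - a)
  d
}
.ptri <- function(q, a, c, b) {
  p <- numeric(length(q))
  p[q >= b] <- 1
  up <- q > a & q < c
  dn <- q >= c & q < b
  if (c > a) p[up] <- (q[up] - a)^2 / ((b - a) * (c - a))
  if (b > c) p[dn] <- 1 - (b - q[dn])^2 / ((b - a) * (b - c))
  if (b == c) p[q >= c & q < b] <- 1
  p
}
.qtri <- function(p, a, c, b) {
  pc <- if (b > a) (c - a) / (b - a) else 0
  ifelse(p <= pc,
         a + sqrt(pmax(p, 0) * (b - a) * (c - a)),
         b - sqrt(pmax(1 - p, 0) * (b - a) * (b - c)))
}

# raw (untruncated) CDF / quantile / density dispatch
.spec_p_raw <- function(spec, q) {
  p <- spec$par
  switch(spec$family,
    point = as.numeric(q >= p$value),
    uniform = stats::punif(q, p$min, p$max),
    normal = stats::pnorm(q, p$mean, p$sd),
    lognormal = stats::plnorm(q, p$meanlog, p$sdlog),
    triangular = .ptri(q, p$min, p$mode, p$max),
    logistic = stats::plogis(q, p$location, p$scale))
}
.spec_q_raw <- function(spec, u) {
  p <- spec$par
  switch(spec$family,
    point = rep(p$value, length(u)),
    uniform = stats::qunif(u, p$min, p$max),
    normal = stats::qnorm(u, p$mean, p$sd),
    lognormal = stats::qlnorm(u, p$meanlog, p$sdlog),
    triangular = .qtri(u, p$min, p$mode, p$max),
    logistic = stats::qlogis(u, p$location, p$scale))
}
.spec_d_raw <- function(spec, x) {
  p <- spec$par
  switch(spec$family,
    point = ifelse(x == p$value, Inf, 0),
    uniform = stats::dunif(x, p$min, p$max),
    normal = stats::dnorm(x, p$mean, p$sd),
    lognormal = stats::dlnorm(x, p$meanlog, p$sdlog),
    triangular = .dtri(x, p$min, p$mode, p$max),
    logistic = stats::dlogis(x, p$location, p$scale))
}

# truncation-aware CDF / quantile / density: a spec with truncation bounds IS
# the truncated distribution, renormalized to its bounds
.trunc_mass <- function(spec) {
  plo <- .spec_p_raw(spec, spec$truncate[1])
  phi <- .spec_p_raw(spec, spec$truncate[2])
  if (phi - plo <= 0) stop("truncation region has no probability mass")
  c(plo = plo, phi = phi)
}
.spec_p <- function(spec, q) {
  if (is.null(spec$truncate)) return(.spec_p_raw(spec, q))
  m <- .trunc_mass(spec)
  pmin(pmax((.spec_p_raw(spec, q) - m["plo"]) / (m["phi"] - m["plo"]), 0), 1)
}
.spec_q <- function(spec, u) {
  if (is.null(spec$truncate)) return(.spec_q_raw(spec, u))
  m <- .trunc_mass(spec)
  .spec_q_raw(spec, m["plo"] + u * (m["phi"] - m["plo"]))
}
.spec_d <- function(spec, x) {
  if (is.null(spec$truncate)) return(.spec_d_raw(spec, x))
  m <- .trunc_mass(spec)
  ifelse(x >= spec$truncate[1] & x <= spec$truncate[2],
         .spec_d_raw(spec, x) / (m["phi"] - m["plo"]), 0)
}

# quantile honouring truncation bounds via CDF inversion (used by the copula
# generator; sample_mc() uses rejection instead, matching its contract)
spec_quantile <- function(spec, u) .spec_q(spec, u)

#' Draw Monte Carlo samples from a distribution spec
#'
#' Produces `n` independent draws, reproducible for a fixed seed. Truncation
#' bounds, when present, are enforced by rejection sampling with a bounded
#' number of retry rounds; a truncation region with negligible probability mass
#' raises an error rather than looping forever.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can manage their own streams).
#' @param max_rounds Maximum rejection rounds before giving up.
#' @return Numeric vector of length `n`.
#' @export
sample_mc <- function(spec, n, seed = NULL, max_rounds = 50L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(m) {
    p <- spec$par
    switch(spec$family,
      point = rep(p$value, m),
      uniform = stats::runif(m, p$min, p$max),
      normal = stats::rnorm(m, p$mean, p$sd),
      lognormal = stats::rlnorm(m, p$meanlog, p$sdlog),
      triangular = .qtri(stats::runif(m), p$min, p$mode, p$max),
      logistic = stats::rlogis(m, p$location, p$scale))
  }
  if (is.null(spec$truncate)) return(draw(n))
  lo <- spec$truncate[1]; hi <- spec$truncate[2]
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    cand <- draw(max(n, 1000L))
    out <- c(out, cand[cand >= lo & cand <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncation region [", lo, ", ", hi, "] has negligible probability ",
       "mass: rejection sampling failed after ", max_rounds, " rounds")
}

# ---- maximum-likelihood fitting ------------------------------------------

# closed-form / package MLE per family; returns a dist_spec or NULL when the
# family cannot be fitted to this sample (e.g. lognormal with zeros)
.fit_family <- function(x, family, truncate = NULL) {
  base <- .fit_family_plain(x, family)
  if (is.null(truncate) || is.null(base)) return(base)
  if (family %in% c("point", "uniform")) {
    # truncating these families just clips their support; the plain MLE stands
    base$truncate <- truncate
    return(base)
  }
  # maximize the truncated likelihood, initialized from the plain fit
  par0 <- switch(family,
    normal = c(base$par$mean, log(base$par$sd)),
    lognormal = c(base$par$meanlog, log(base$par$sdlog)),
    logistic = c(base$par$location, log(base$par$scale)),
    triangular = NULL)
  mk <- function(th) switch(family,
    normal = dist_spec("normal", mean = th[1], sd = exp(th[2]),
                       truncate = truncate),
    lognormal = dist_spec("lognormal", meanlog = th[1], sdlog = exp(th[2]),
                          truncate = truncate),
    logistic = dist_spec("logistic", location = th[1], scale = exp(th[2]),
                         truncate = truncate))
  if (family == "triangular") {
    base$truncate <- truncate
    return(base)
  }
  nll <- function(th) -sum(log(pmax(.spec_d(mk(th), x), 1e-300)))
  opt <- tryCatch(stats::optim(par0, nll), error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  mk(opt$par)
}

.fit_family_plain <- function(x, family) {
  n <- length(x)
  tryCatch(switch(family,
    point = {
      if (stats::sd(x) > 0) NULL else dist_spec("point", value = x[1])
    },
    uniform = dist_spec("uniform", min = min(x), max = max(x)),
    normal = dist_spec("normal", mean = mean(x),
                       sd = sqrt(mean((x - mean(x))^2))),
    lognormal = {
      if (any(x <= 0)) NULL else
        dist_spec("lognormal", meanlog = mean(log(x)),
                  sdlog = sqrt(mean((log(x) - mean(log(x)))^2)))
    },
    logistic = {
      f <- fitdistrplus::fitdist(x, "logis",
                                 start = list(location = stats::median(x),
                                              scale = stats::sd(x) * sqrt(3) / pi))
      dist_spec("logistic", location = unname(f$estimate["location"]),
                scale = unname(f$estimate["scale"]))
    },
    triangular = {
      a <- min(x) - 1e-6 * diff(range(x))
      b <- max(x) + 1e-6 * diff(range(x))
      nll <- function(cc) -sum(log(pmax(.dtri(x, a, cc, b), 1e-300)))
      opt <- stats::optim(stats::median(x), nll, method = "Brent",
                          lower = min(x), upper = max(x))
      dist_spec("triangular", min = a, mode = opt$par, max = b)
    }),
    error = function(e) NULL)
}

#' Anderson-Darling statistic against a fitted distribution
#'
#' `A^2 = -n - (1/n) * sum (2i - 1) [ln F(x_(i)) + ln(1 - F(x_(n+1-i)))]`
#' computed with the spec's CDF.
#'
#' @param x Sample values.
#' @param spec A [dist_spec()].
#' @return The (non-negative) A-squared statistic.
#' @export
ad_statistic <- function(x, spec) {
  n <- length(x)
  u <- .spec_p(spec, sort(x))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  max(-n - mean((2 * i - 1) * (log(u) + log(1 - rev(u)))), 0)
}

# Stephens' case-3 p-value for the AD statistic when a normal distribution was
# fitted with both parameters estimated from the data
.ad_p_normal <- function(a2, n) {
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a >= 0.6) {
    exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  } else if (a > 0.34) {
    exp(0.9177 - 4.279 * a - 1.38 * a^2)
  } else if (a > 0.2) {
    1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  } else {
    1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  }
  min(max(p, 0), 1)
}

# equal-probability-bin chi-square GoF: k = max(5, floor(n/5)) bins
.chisq_gof <- function(x, spec, n_par) {
  n <- length(x)
  k <- max(5L, floor(n / 5))
  br <- .spec_q(spec, seq(0, 1, length.out = k + 1L))
  br[1] <- -Inf; br[k + 1L] <- Inf
  br <- unique(br)
  k_eff <- length(br) - 1L
  obs <- tabulate(findInterval(x, br, left.open = TRUE, rightmost.closed = TRUE),
                  nbins = k_eff)
  expected <- n * diff(.spec_p(spec, br))
  expected[1] <- n * .spec_p(spec, br[2])
  expected[k_eff] <- n * (1 - .spec_p(spec, br[k_eff]))
  keep <- expected > 0
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L - n_par
  p <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(stat = stat, df = df, p = p)
}

.n_par <- function(family) {
  switch(family, point = 1L, uniform = 2L, normal = 2L, lognormal = 2L,
         triangular = 3L, logistic = 2L)
}

#' Fit candidate distributions with goodness-of-fit auto-selection
#'
#' Fits each candidate family to the sample by maximum likelihood, computes the
#' Anderson-Darling, Kolmogorov-Smirnov and equal-probability-bin chi-square
#' statistics against each fitted candidate, and selects the family with the
#' smallest AD statistic (ties broken by the smallest KS statistic). A report
#' row is returned for every candidate, including poorly fitting ones.
#'
#' KS p-values use the asymptotic Kolmogorov distribution and are optimistic
#' when parameters were estimated from the same sample; AD p-values use
#' Stephens' case formula for the normal family and a seeded parametric
#' bootstrap elsewhere.
#'
#' @param values Numeric sample (at least 5 observations).
#' @param candidates Character vector of families to try (see [dist_spec()]).
#' @param criterion `"ad"` (default) or `"ks"`: statistic minimised by the
#'   auto-selection.
#' @param pvalues Compute AD p-values (the expensive part)? KS and chi-square
#'   p-values are always reported.
#' @param ad_reps Parametric bootstrap replicates for AD p-values.
#' @param seed Seed for the bootstrap.
#' @param truncate Optional `c(lo, hi)` known truncation bounds of the sampled
#'   quantity: candidates are then fitted by truncated maximum likelihood and
#'   judged against their truncated CDFs (used e.g. when refitting marginals
#'   of a generator whose draws were range-limited).
#' @return A list of class `"dist_fit"` with elements `spec` (the selected
#'   [dist_spec()]), `report` (one row per candidate: statistics, p-values and
#'   a `fitted` flag), `criterion` and `selected`.
#' @examples
#' set.seed(1)
#' fit_distribution(runif(200), candidates = c("uniform", "normal"),
#'                  pvalues = FALSE)
#' @export
fit_distribution <- function(values, candidates = c("normal", "lognormal",
                                                    "uniform", "logistic"),
                             criterion = c("ad", "ks"), pvalues = TRUE,
                             ad_reps = 499L, seed = 1L, truncate = NULL) {
  criterion <- match.arg(criterion)
  x <- as.numeric(values)
  if (length(x) < 5L) stop("fit_distribution needs at least 5 observations")
  degenerate <- stats::sd(x) == 0
  if (degenerate) candidates <- unique(c("point", candidates))
  candidates <- match.arg(candidates, .DIST_FAMILIES, several.ok = TRUE)

  rows <- list()
  specs <- list()
  for (fam in candidates) {
    spec <- if (degenerate && fam != "point") NULL else
      .fit_family(x, fam, truncate = truncate)
    if (is.null(spec)) {
      rows[[fam]] <- data.frame(
        family = fam, fitted = FALSE, ad = NA_real_, ad_p = NA_real_,
        ks = NA_real_, ks_p = NA_real_, chisq = NA_real_, chisq_df = NA_integer_,
        chisq_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    specs[[fam]] <- spec
    ad <- ad_statistic(x, spec)
    ks <- suppressWarnings(stats::ks.test(x, function(q) .spec_p(spec, q)))
    cs <- .chisq_gof(x, spec, .n_par(fam))
    ad_p <- NA_real_
    if (pvalues && fam != "point") {
      if (fam == "normal" && is.null(truncate)) {
        ad_p <- .ad_p_normal(ad, length(x))
      } else {
        set.seed(as.integer(seed))
        boot <- vapply(seq_len(ad_reps), function(r) {
          xb <- sample_mc(spec, length(x))
          sb <- .fit_family(xb, fam, truncate = truncate)
          if (is.null(sb)) return(NA_real_)
          ad_statistic(xb, sb)
        }, numeric(1))
        boot <- boot[!is.na(boot)]
        ad_p <- (1 + sum(boot >= ad)) / (length(boot) + 1)
      }
    }
    rows[[fam]] <- data.frame(
      family = fam, fitted = TRUE, ad = ad, ad_p = ad_p,
      ks = unname(ks$statistic), ks_p = unname(ks$p.value),
      chisq = cs$stat, chisq_df = cs$df, chisq_p = cs$p,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  row.names(report) <- NULL
  ok <- report$fitted
  if (!any(ok)) stop("no candidate family could be fitted")
  key <- if (criterion == "ad") report$ad else report$ks
  tie <- if (criterion == "ad") report$ks else report$ad
  key[!ok] <- Inf; tie[!ok] <- Inf
  sel <- order(key, tie)[1L]
  out <- list(spec = specs[[report$family[sel]]], report = report,
              criterion = criterion, selected = report$family[sel])
  class(out) <- "dist_fit"
  out
}

#' @export
print.dist_fit <- function(x, ...) {
  cat("Distribution auto-fit (criterion: smallest ",
      toupper(x$criterion), " statistic)\n", sep = "")
  print(x$report, row.names = FALSE, digits = 4)
  cat("selected: "); print(x$spec)
  invisible(x)
}
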