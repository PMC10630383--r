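# Chemometric source apportionment: z-standardization, varimax-rotated PCA
# with Kaiser retention and communalities, Ward hierarchical clustering with
# the dendrogram linkage quotient, cluster mean profiles, and Sneath's
# significance cut.

#' Z-scale standardization
#'
#' Centres each canonical parameter column to mean 0 and scales it to sample
#' standard deviation 1 (dimensionless values). A zero-variance column is an
#' error, named in the message.
#'
#' @param table A [sample_table()] or numeric data frame/matrix.
#' @param parameters Columns to standardize (default: the 13 canonical
#'   parameters when present, else all numeric columns).
#' @return Numeric matrix `[sample x parameter]` with sample ids as row names.
#' @export
zscore <- function(table, parameters = NULL) {
  df <- as.data.frame(table)
  if (is.null(parameters)) {
    parameters <- intersect(canonical_parameters(), names(df))
    if (!length(parameters)) parameters <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  m <- as.matrix(df[, parameters, drop = FALSE])
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(parameters[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  rownames(z) <- if ("sample_id" %in% names(df)) df$sample_id else rownames(df)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Varimax-rotated principal component analysis
#'
#' Eigendecomposition of the correlation matrix of the standardized data;
#' components with eigenvalue above 1 are retained (Kaiser criterion by
#' default), their loadings varimax-rotated with Kaiser row normalization, and
#' communalities reported as the row sums of squared retained loadings (which
#' an orthogonal rotation leaves unchanged). Percent variance is reported from
#' the unrotated eigenvalues, the convention of the classic rotated-component
#' table; the rotated sums of squared loadings are also returned.
#'
#' Each rotated component's sign is flipped so its largest-magnitude loading
#' is positive.
#'
#' @param z A standardized matrix from [zscore()] (or any numeric matrix; the
#'   correlation matrix is taken internally).
#' @param retain `"kaiser"` (eigenvalue > 1) or an integer count.
#' @param eps Varimax convergence tolerance.
#' @return A list of class `"pca_varimax"`: `eigenvalues`, `percent_variance`,
#'   `cumulative_percent`, `retained`, `loadings` (unrotated, retained),
#'   `rotated` (varimax loadings), `rotated_ss` (sums of squared rotated
#'   loadings), `communalities`, `rotation_skipped`.
#' @export
pca_varimax <- function(z, retain = "kaiser", eps = 1e-10) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("PCA needs more than one sample")
  R <- stats::cor(z)
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  p <- ncol(z)
  pct <- 100 * lambda / p
  k <- if (identical(retain, "kaiser")) sum(lambda > 1) else as.integer(retain)
  load_full <- e$vectors %*% diag(sqrt(lambda), p, p)
  dimnames(load_full) <- list(colnames(z), paste0("PC", seq_len(p)))
  loadings <- load_full[, seq_len(max(k, 1L)), drop = FALSE]
  rotation_skipped <- k < 2L
  rotated <- if (rotation_skipped) {
    loadings
  } else {
    vm <- stats::varimax(loadings[, seq_len(k), drop = FALSE],
                         normalize = TRUE, eps = eps)
    unclass(vm$loadings)
  }
  # sign convention: largest |loading| of each component positive
  for (j in seq_len(ncol(rotated))) {
    i <- which.max(abs(rotated[, j]))
    if (rotated[i, j] < 0) rotated[, j] <- -rotated[, j]
  }
  communalities <- rowSums(rotated^2)
  out <- list(
    eigenvalues = lambda,
    percent_variance = pct,
    cumulative_percent = cumsum(pct),
    retained = k,
    loadings = loadings,
    rotated = rotated,
    rotated_ss = colSums(rotated^2),
    communalities = communalities,
    rotation_skipped = rotation_skipped
  )
  class(out) <- "pca_varimax"
  out
}

#' @export
print.pca_varimax <- function(x, digits = 2, ...) {
  cat("Correlation PCA with varimax rotation: ", x$retained,
      " component(s) retained (eigenvalue > 1)\n", sep = "")
  hdr <- data.frame(
    eigenvalue = round(x$eigenvalues[seq_len(x$retained)], digits),
    pct_variance = round(x$percent_variance[seq_len(x$retained)], digits),
    cumulative = round(x$cumulative_percent[seq_len(x$retained)], digits))
  print(hdr, row.names = paste0("PC", seq_len(x$retained)))
  cat("\nRotated loadings (communalities in last column):\n")
  m <- cbind(round(x$rotated, digits),
             communality = round(x$communalities, digits))
  print(m)
  if (x$rotation_skipped) cat("(rotation skipped: fewer than 2 components)\n")
  invisible(x)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on squared
#' Euclidean distances of the standardized data, via the Lance-Williams
#' recurrence (`hclust` method `"ward.D"` applied to the squared distance
#' matrix -- the classic convention in which merge heights equal twice the
#' increase in within-cluster error sum of squares). The dendrogram linkage
#' quotient `(D_link / D_max) * 100` is reported per merge.
#'
#' @param z Standardized matrix from [zscore()].
#' @param k Number of clusters for the default cut (default 3).
#' @return A list of class `"ward_cluster"`: `hclust` (the merge tree),
#'   `heights`, `quotient`, `k`, `assignments` (named cluster vector at the
#'   cut).
#' @export
ward_cluster <- function(z, k = 3L) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("clustering needs at least 2 samples")
  d2 <- stats::dist(z)^2
  hc <- stats::hclust(stats::as.dist(d2), method = "ward.D")
  k <- min(as.integer(k), nrow(z))
  out <- list(
    hclust = hc,
    heights = hc$height,
    quotient = 100 * hc$height / max(hc$height),
    k = k,
    assignments = stats::cutree(hc, k = k)
  )
  class(out) <- "ward_cluster"
  out
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat("Ward clustering (squared Euclidean), n = ",
      length(x$assignments), ", cut at k = ", x$k, "\n", sep = "")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @export
plot.ward_cluster <- function(x, ...) {
  hc <- x$hclust
  hc$height <- x$quotient  # y-axis as linkage quotient
  plot(hc, ylab = "(D_link / D_max) * 100", ...)
  invisible(x)
}

#' Cluster mean profiles
#'
#' Arithmetic parameter means per cluster, with per-parameter ranking flags
#' (`highest`, `second`, `lowest`) across clusters -- the usual annotated
#' cluster-average table of a chemometric survey.
#'
#' @param table A [sample_table()].
#' @param assignments Cluster assignment vector (e.g.
#'   `ward_cluster(...)$assignments`).
#' @return A list of class `"cluster_profile"`: `means`
#'   (`[parameter x cluster]` data frame) and `flags` (same shape, ranking
#'   labels).
#' @export
cluster_profile <- function(table, assignments) {
  df <- as.data.frame(table)
  params <- intersect(canonical_parameters(), names(df))
  cl <- sort(unique(assignments))
  means <- sapply(cl, function(k) {
    colMeans(df[assignments == k, params, drop = FALSE])
  })
  means <- matrix(means, nrow = length(params),
                  dimnames = list(params, paste0("C", cl)))
  flags <- means
  flags[] <- ""
  for (i in seq_len(nrow(means))) {
    v <- means[i, ]
    flags[i, which.max(v)] <- "highest"
    if (length(v) >= 2L) flags[i, which.min(v)] <- "lowest"
    if (length(v) >= 3L) flags[i, order(v, decreasing = TRUE)[2L]] <- "second"
  }
  out <- list(means = as.data.frame(means), flags = as.data.frame(flags))
  class(out) <- "cluster_profile"
  out
}

#' @export
print.cluster_profile <- function(x, digits = 2, ...) {
  cat("Cluster mean profiles:\n")
  m <- round(x$means, digits)
  for (j in seq_len(ncol(m))) {
    mark <- ifelse(x$flags[[j]] == "highest", "*",
                   ifelse(x$flags[[j]] == "second", "+", ""))
    m[[j]] <- paste0(m[[j]], mark)
  }
  print(m)
  cat("(* highest, + second-highest mean across clusters)\n")
  invisible(x)
}

#' Sneath's significance cut
#'
#' Number of clusters obtained by cutting the dendrogram where the linkage
#' quotient `(D_link / D_max) * 100` crosses a threshold: merges at or below
#' the threshold are performed, merges above it are not.
#'
#' @param result A [ward_cluster()] result.
#' @param threshold_percent Quotient threshold in percent.
#' @return Integer cluster count at that cut.
#' @export
sneath_significance <- function(result, threshold_percent) {
  stopifnot(inherits(result, "ward_cluster"))
  h <- threshold_percent / 100 * max(result$hclust$height)
  length(unique(stats::cutree(result$hclust, h = h)))
}
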