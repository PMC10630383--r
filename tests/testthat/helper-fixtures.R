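# Shared fixtures and independent oracles for the suite. Everything is built
# in code at test time; nothing is read from disk.

# one-row sample table with overridable chemistry (defaults are a plausible
# calcium-bicarbonate water)
water_row <- function(id = "G1", pH = 7.5, EC = 900, TDS = 576, TH = 250,
                      Ca = 60, Mg = 12, Na = 23, K = 2, HCO3 = 244,
                      Cl = 35.5, SO4 = 48, NO3 = 30, F = 0.5) {
  sample_table(data.frame(
    sample_id = id, pH = pH, EC = EC, TDS = TDS, TH = TH, Ca = Ca, Mg = Mg,
    Na = Na, K = K, HCO3 = HCO3, Cl = Cl, SO4 = SO4, NO3 = NO3, F = F,
    stringsAsFactors = FALSE))
}

# stack several water_row() calls into one table
water_rows <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$sample_id <- paste0("G", seq_len(nrow(df)))
  sample_table(df)
}

# independent Ward oracle: greedy exhaustive minimization of the increase in
# within-cluster error sum of squares; heights returned as 2 * delta-ESS, the
# convention of the Lance-Williams ward recurrence on squared distances
ess_ward_oracle <- function(x) {
  n <- nrow(x)
  cl <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(cl) > 1L) {
    k <- length(cl)
    best <- NULL
    bestd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ni <- length(cl[[i]]); nj <- length(cl[[j]])
      ci <- colMeans(x[cl[[i]], , drop = FALSE])
      cj <- colMeans(x[cl[[j]], , drop = FALSE])
      d <- ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, 2 * bestd)
    cl[[best[1]]] <- sort(c(cl[[best[1]]], cl[[best[2]]]))
    cl[[best[2]]] <- NULL
    partitions[[length(partitions) + 1L]] <-
      lapply(cl, identity)
  }
  list(heights = heights, partitions = partitions)
}

# independent eigenvalue oracle: power iteration with deflation on a symmetric
# positive semi-definite matrix
power_eigen_oracle <- function(R, tol = 1e-13, maxit = 100000L) {
  p <- ncol(R)
  vals <- numeric(p)
  M <- R
  for (k in seq_len(p)) {
    v <- seq_len(p); v <- v / sqrt(sum(v^2))
    for (i in seq_len(maxit)) {
      w <- drop(M %*% v)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      if (min(sum(abs(w - v)), sum(abs(w + v))) < tol) { v <- w; break }
      v <- w
    }
    lam <- drop(t(v) %*% M %*% v)
    vals[k] <- lam
    M <- M - lam * tcrossprod(v)
  }
  sort(vals, decreasing = TRUE)
}

# cluster partition at k groups from an hclust, as a canonical set of sorted
# index vectors (order-independent comparison with the oracle)
partition_sets <- function(assign) {
  unname(lapply(split(seq_along(assign), assign), sort))
}
canonical_partition <- function(sets) {
  sets[order(vapply(sets, function(s) s[1], numeric(1)))]
}
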