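# Sample table construction, validation, CSV round trip, and conversion of
# ion concentrations from mg/L to milliequivalents per litre.

#' Construct and validate a groundwater sample table
#'
#' A sample table is a data frame with a `sample_id` column and the 13
#' canonical physicochemical parameters (`pH`, `EC`, `TDS`, `TH`, `Ca`, `Mg`,
#' `Na`, `K`, `HCO3`, `Cl`, `SO4`, `NO3`, `F`) in registry units. Any further
#' columns are preserved as passthrough metadata. Validation enforces: all 13
#' parameters present and complete, ion and aggregate concentrations
#' non-negative, and pH strictly inside (0, 14).
#'
#' @param data A data frame holding at least `sample_id` and the 13 parameters.
#' @param season Optional season label attached as an attribute (e.g.
#'   `"premonsoon"`).
#' @return The validated data frame with class `"sample_table"` prepended and a
#'   `season` attribute.
#' @examples
#' tab <- sample_table(data.frame(
#'   sample_id = "G1", pH = 7.5, EC = 900, TDS = 580, TH = 250,
#'   Ca = 60, Mg = 12, Na = 23, K = 2, HCO3 = 244, Cl = 35.5,
#'   SO4 = 48, NO3 = 30, F = 0.5))
#' @export
sample_table <- function(data, season = NULL) {
  stopifnot(is.data.frame(data))
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- paste0("G", seq_len(nrow(data)))
  }
  data$sample_id <- as.character(data$sample_id)
  canon <- canonical_parameters()
  missing_cols <- setdiff(canon, names(data))
  if (length(missing_cols)) {
    stop("sample table is missing canonical parameter(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (p in canon) {
    v <- data[[p]]
    if (!is.numeric(v)) stop("parameter ", p, " is not numeric")
    if (anyNA(v)) {
      stop("missing values in parameter ", p, " (samples ",
           paste(data$sample_id[is.na(v)], collapse = ", "), ")")
    }
  }
  for (p in setdiff(canon, "pH")) {
    neg <- data[[p]] < 0
    if (any(neg)) {
      stop("negative concentration in ", p, " (samples ",
           paste(data$sample_id[neg], collapse = ", "), ")")
    }
  }
  bad_ph <- data$pH <= 0 | data$pH >= 14
  if (any(bad_ph)) {
    stop("pH outside (0, 14) in samples ",
         paste(data$sample_id[bad_ph], collapse = ", "))
  }
  data <- data[c("sample_id", canon, setdiff(names(data), c("sample_id", canon)))]
  class(data) <- c("sample_table", "data.frame")
  attr(data, "season") <- season
  data
}

#' Read a groundwater sample table from CSV
#'
#' Reads a comma-separated file with a header row naming the parameters and one
#' row per sample, then validates it with [sample_table()]. Unknown columns are
#' kept as passthrough metadata.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param season Optional season label.
#' @return A validated [sample_table()].
#' @seealso [write_samples()]
#' @export
read_samples <- function(path, season = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_table(raw, season = season)
}

#' Write a sample table to CSV
#'
#' Inverse of [read_samples()]: `read_samples(write_samples(tab, f))` is the
#' identity on validated tables.
#'
#' @param table A [sample_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Convert ion concentrations to milliequivalents per litre
#'
#' Divides each of the nine major-ion columns (mg/L) by its equivalent weight
#' (mg/meq) from [param_registry()]. The conversion is linear and preserves
#' non-negativity.
#'
#' @param table A [sample_table()], or a data frame carrying the ion columns.
#' @return A numeric matrix `[sample x ion]` in meq/L with the sample ids as
#'   row names.
#' @examples
#' # 40.08 mg/L Ca (eq. wt 20.04) is exactly 2 meq/L
#' @export
to_meq <- function(table) {
  ions <- ion_parameters()
  m <- as.matrix(as.data.frame(table)[, ions, drop = FALSE])
  m <- sweep(m, 2L, .EQ_WEIGHTS[ions], "/")
  rownames(m) <- if ("sample_id" %in% names(table)) table$sample_id else NULL
  m
}

#' Standards exceedance summary
#'
#' For every parameter with a defined limit, the count and percentage of
#' samples strictly above the acceptable limit (AL), the permissible limit (PL)
#' and the FAO usual irrigation range. "Above" is strict: a value exactly at
#' the limit is compliant. Parameters lacking a limit are reported as `NA`.
#'
#' @param table A [sample_table()].
#' @param standards A [standards_registry()] data frame.
#' @return A data frame with one row per parameter: `parameter`, `n`,
#'   `n_above_al`, `pct_above_al`, `n_above_pl`, `pct_above_pl`,
#'   `n_above_fao`, `pct_above_fao`.
#' @export
exceedance_summary <- function(table, standards = standards_registry()) {
  n <- nrow(table)
  res <- lapply(seq_len(nrow(standards)), function(i) {
    p <- standards$parameter[i]
    v <- as.data.frame(table)[[p]]
    if (is.null(v)) return(NULL)
    cnt <- function(limit) if (is.na(limit)) NA_integer_ else sum(v > limit)
    n_al <- cnt(standards$al[i])
    n_pl <- cnt(standards$pl[i])
    n_fao <- if (is.na(standards$fao_high[i])) NA_integer_ else
      sum(v > standards$fao_high[i] | v < standards$fao_low[i])
    data.frame(
      parameter = p, n = n,
      n_above_al = n_al, pct_above_al = 100 * n_al / n,
      n_above_pl = n_pl, pct_above_pl = 100 * n_pl / n,
      n_above_fao = n_fao, pct_above_fao = 100 * n_fao / n,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' @export
print.sample_table <- function(x, ...) {
  season <- attr(x, "season")
  cat("Groundwater sample table: ", nrow(x), " samples",
      if (!is.null(season)) paste0(" (", season, ")"), "\n", sep = "")
  print(as.data.frame(utils::head(x, 6L)), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Total hardness from calcium and magnesium
#'
#' Fallback computation of total hardness as CaCO3 equivalent,
#' `TH = 2.497 Ca + 4.115 Mg` (mg/L), for tables where TH was not measured.
#'
#' @param ca,mg Concentrations in mg/L.
#' @return TH in mg/L as CaCO3.
#' @export
compute_th <- function(ca, mg) 2.497 * ca + 4.115 * mg
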