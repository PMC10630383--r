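# Parameter and standards registries: the 13 canonical physicochemical
# parameters of a major-ion groundwater analysis, their units, ionic roles and
# equivalent weights, and the drinking/irrigation limits they are judged against.

# Equivalent weights (mg per meq) from standard atomic masses: molar mass / |charge|.
.EQ_WEIGHTS <- c(
  Ca = 20.04, Mg = 12.15, Na = 22.99, K = 39.10,
  HCO3 = 61.02, Cl = 35.45, SO4 = 48.03, NO3 = 62.00, F = 19.00
)

.CATIONS <- c("Ca", "Mg", "Na", "K")
.ANIONS  <- c("HCO3", "Cl", "SO4", "NO3", "F")

#' Canonical parameter registry
#'
#' Definitions of the 13 physicochemical parameters every [sample_table()] must
#' carry: field measurements (pH), aggregates (EC, TDS, TH) and the nine major
#' ions with their equivalent weights (mg per milliequivalent) and charges.
#'
#' @return A data frame with columns `name`, `unit`, `ion_role`
#'   (`"cation"`, `"anion"`, `"aggregate"` or `"field"`), `equivalent_weight`
#'   (mg/meq, `NA` for non-ions) and `charge` (signed, `NA` for non-ions).
#' @examples
#' param_registry()
#' @export
param_registry <- function() {
  data.frame(
    name = c("pH", "EC", "TDS", "TH", .CATIONS, .ANIONS),
    unit = c("pH units", "uS/cm", "mg/L", "mg/L as CaCO3", rep("mg/L", 9L)),
    ion_role = c("field", "aggregate", "aggregate", "aggregate",
                 rep("cation", 4L), rep("anion", 5L)),
    equivalent_weight = c(rep(NA_real_, 4L), .EQ_WEIGHTS[c(.CATIONS, .ANIONS)]),
    charge = c(rep(NA_integer_, 4L), 2L, 2L, 1L, 1L, -1L, -1L, -2L, -1L, -1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Drinking-water and irrigation standards registry
#'
#' Acceptable limits (AL) and permissible limits (PL) per parameter, with the
#' issuing standard (BIS drinking-water limits, supplemented by WHO guideline
#' values where BIS gives none) and the FAO usual range for irrigation use.
#' Nitrate carries the same 45 mg/L value as both AL and PL (no relaxation is
#' granted in the absence of an alternative source).
#'
#' @param overrides Optional named list of per-parameter replacement rows, each
#'   a list with any of `al`, `pl`, `fao_low`, `fao_high`.
#' @return A data frame with columns `parameter`, `al`, `pl`, `source`,
#'   `fao_low`, `fao_high`. `NA` means no limit is defined.
#' @examples
#' standards_registry()
#' @export
standards_registry <- function(overrides = NULL) {
  std <- data.frame(
    parameter = c("pH", "EC", "TDS", "TH", "Ca", "Mg", "Na", "K",
                  "HCO3", "Cl", "SO4", "NO3", "F"),
    al  = c(NA, 1500, 500, 200, 75, 30, 200, 12, 500, 250, 200, 45, 1.0),
    pl  = c(NA, NA, 2000, 600, 200, 100, NA, NA, NA, 1000, 400, 45, 1.5),
    source = c(NA, "WHO", "BIS", "BIS", "BIS", "BIS", "WHO", "WHO",
               "WHO", "BIS", "BIS", "BIS", "BIS"),
    fao_low  = c(NA, 0, 0, NA, 0, 0, 0, NA, 0, 0, 0, 0, 0),
    fao_high = c(NA, 3000, 2000, NA, 400, 60, 920, NA, 610, 1063, 960, 45, 2),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (p in names(overrides)) {
      i <- match(p, std$parameter)
      if (is.na(i)) stop("unknown parameter in standards overrides: ", p)
      for (f in names(overrides[[p]])) std[[f]][i] <- overrides[[p]][[f]]
    }
  }
  bad <- !is.na(std$al) & !is.na(std$pl) & std$al > std$pl
  if (any(bad)) {
    stop("acceptable limit exceeds permissible limit for: ",
         paste(std$parameter[bad], collapse = ", "))
  }
  std
}

canonical_parameters <- function() param_registry()$name

ion_parameters <- function() c(.CATIONS, .ANIONS)
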