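# Internal constants shared across the package.

# Equivalent weights of the major ions, mg per meq (molar mass / |charge|).
.EQ_WEIGHT <- c(
  ca = 20.04, mg = 12.15, na = 22.99, k = 39.10,
  hco3 = 61.02, cl = 35.45, so4 = 48.03
)

.CATIONS <- c("ca", "mg", "na", "k")
.ANIONS  <- c("hco3", "cl", "so4")

# Potentially harmful elements (PHEs) carried by every sample table.
.PHES <- c("ni", "mn", "cr", "cu", "cd", "pb", "co", "fe", "zn")

# Full measured-parameter set, in canonical column order.
.PARAMS <- c("ph", "ec", "temp", "depth", "tds",
             .CATIONS, .ANIONS, .PHES)

# Parameters required in an input file (depth, temp and coordinates are optional).
.REQUIRED <- c("ph", "ec", "tds", .CATIONS, .ANIONS, .PHES)

.STRATA <- c("shallow", "mid", "deep", "mine")

.WATER_TYPES <- c("CaHCO3", "CaMgCl", "NaCl", "NaHCO3")

.GIBBS_ZONES <- c("rock_weathering", "evaporation", "precipitation", "outside")

extdata_path <- function(file) {
  system.file("extdata", file, package = "hydrorisk", mustWork = TRUE)
}

read_packaged <- function(file) {
  utils::read.csv(extdata_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged default tables
#'
#' Accessors for the plain-text default tables shipped with the package:
#' drinking-water guideline limits used for exceedance screening, the effective
#' single-value standards used by the Nemerow pollution index, oral toxicity
#' values (reference doses and cancer slope factors), cohort exposure profiles,
#' Gibbs-zone boundary polygons, per-stratum distributional targets for the
#' synthetic generator, and the latent source membership table.
#'
#' Each file carries a commented header documenting units and provenance; all
#' can be replaced by user files of the same shape in [run_pipeline()].
#'
#' @return A data frame (see the corresponding file under `inst/extdata` for
#'   column documentation).
#' @name defaults
NULL

#' @rdname defaults
#' @export
default_guidelines <- function() read_packaged("who_guidelines.csv")

#' @rdname defaults
#' @export
default_npi_standards <- function() read_packaged("npi_standards.csv")

#' @rdname defaults
#' @export
default_toxicity <- function() read_packaged("toxicity.csv")

#' @rdname defaults
#' @export
default_exposure_profiles <- function() read_packaged("exposure_profiles.csv")

#' @rdname defaults
#' @export
default_gibbs_polygons <- function() read_packaged("gibbs_polygons.csv")

#' @rdname defaults
#' @export
default_stratum_targets <- function() read_packaged("stratum_targets.csv")

#' @rdname defaults
#' @export
default_source_profiles <- function() read_packaged("source_profiles.csv")

# standards data frame -> named vector, validating positivity
standards_vector <- function(standards, needed) {
  if (is.data.frame(standards)) {
    col <- intersect(c("standard", "limit"), names(standards))[1]
    s <- stats::setNames(standards[[col]], standards$parameter)
  } else {
    s <- standards
  }
  missing <- setdiff(needed, names(s)[!is.na(s)])
  if (length(missing) > 0) {
    stop("no standard/guideline entry for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- s[needed]
  if (any(s <= 0)) {
    stop("standards must be positive; offending parameter(s): ",
         paste(needed[s <= 0], collapse = ", "), call. = FALSE)
  }
  s
}
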