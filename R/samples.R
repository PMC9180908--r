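#' Construct a validated sample table
#'
#' A sample table is a data frame with one row per groundwater or mine-water
#' sample, holding the field/lab measurements the rest of the package consumes:
#' `sample_id`, `stratum` (one of `"shallow"`, `"mid"`, `"deep"`, `"mine"`),
#' optional `depth` (m), `temp` (degC), `easting`/`northing`, and the measured
#' parameters `ph`, `ec` (uS/cm), `tds` and the major ions `ca`, `mg`, `k`,
#' `na`, `hco3`, `cl`, `so4` and trace elements `ni`, `mn`, `cr`, `cu`, `cd`,
#' `pb`, `co`, `fe`, `zn` (all mg/L).
#'
#' Validation enforces: unique non-empty sample ids, at least one sample,
#' non-negative concentrations, pH strictly inside (0, 14), positive depth
#' where present, and consistency between stratum and depth (shallow <= 40 m,
#' mid 41--80 m, deep > 80 m; mine samples are exempt).
#'
#' @param x A data frame with the columns described above.
#' @param provenance Free-text provenance note stored as an attribute.
#' @return `x`, validated, with class `"sample_table"`.
#' @export
sample_table <- function(x, provenance = "unspecified") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "stratum", .REQUIRED), names(x))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) < 1) stop("a sample table needs at least one sample", call. = FALSE)
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_stratum <- setdiff(unique(x$stratum), .STRATA)
  if (length(bad_stratum) > 0) {
    stop("unknown stratum value(s): ", paste(bad_stratum, collapse = ", "),
         "; expected one of ", paste(.STRATA, collapse = ", "), call. = FALSE)
  }
  conc <- intersect(c("ec", "tds", .CATIONS, .ANIONS, .PHES), names(x))
  for (p in conc) {
    if (any(x[[p]] < 0, na.rm = TRUE)) {
      stop("negative values in column '", p, "'", call. = FALSE)
    }
  }
  if (any(x$ph <= 0 | x$ph >= 14, na.rm = TRUE)) {
    stop("ph values must lie strictly inside (0, 14)", call. = FALSE)
  }
  if ("depth" %in% names(x)) {
    if (any(x$depth <= 0, na.rm = TRUE)) stop("depth must be > 0", call. = FALSE)
    chk <- !is.na(x$depth) & x$stratum != "mine"
    expected <- ifelse(x$depth <= 40, "shallow",
                       ifelse(x$depth <= 80, "mid", "deep"))
    off <- chk & expected != x$stratum
    if (any(off)) {
      stop("stratum/depth mismatch for sample(s): ",
           paste(x$sample_id[off], collapse = ", "),
           " (shallow <= 40 m, mid 41-80 m, deep > 80 m)", call. = FALSE)
    }
  }
  attr(x, "provenance") <- provenance
  class(x) <- c("sample_table", "data.frame")
  x
}

# header normalisation: lower-case, strip units in (), [] and surrounding space
.ALIASES <- c(
  id = "sample_id", sample = "sample_id", sampleid = "sample_id",
  well = "sample_id", temperature = "temp", conductivity = "ec",
  bicarbonate = "hco3", sulfate = "so4", sulphate = "so4",
  chloride = "cl", calcium = "ca", magnesium = "mg", sodium = "na",
  potassium = "k", nickel = "ni", manganese = "mn", chromium = "cr",
  copper = "cu", cadmium = "cd", lead = "pb", cobalt = "co",
  iron = "fe", zinc = "zn", x = "easting", y = "northing",
  lon = "easting", lat = "northing"
)

normalise_header <- function(nm) {
  nm <- tolower(trimws(nm))
  nm <- sub("\\s*[\\(\\[].*$", "", nm)      # drop trailing unit annotations
  nm <- gsub("[^a-z0-9_]+", "_", nm)
  nm <- gsub("^_+|_+$", "", nm)
  hit <- match(nm, names(.ALIASES))
  nm[!is.na(hit)] <- .ALIASES[hit[!is.na(hit)]]
  nm
}

#' Read a sample table from delimited text
#'
#' Reads a delimiter-separated file with a header row into a validated
#' [sample_table()]. Header matching is case-insensitive, tolerates unit
#' annotations such as `"Ca (mg/L)"`, and understands common aliases
#' (`temperature`, `conductivity`, `sulfate`, element names, ...).
#'
#' @param path Path to the file.
#' @param dialect List with elements `sep` (default `","`) and `dec`
#'   (default `"."`).
#' @param stratum Optional stratum label applied to every row when the file has
#'   no `stratum` column (e.g. a separate mine-water file).
#' @return A [sample_table()] with rows in file order.
#' @export
read_samples <- function(path, dialect = list(sep = ",", dec = "."),
                         stratum = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE,
                           sep = dialect$sep %||% ",",
                           dec = dialect$dec %||% ".",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  names(raw) <- normalise_header(names(raw))
  if (!is.null(stratum) && !"stratum" %in% names(raw)) raw$stratum <- stratum
  missing <- setdiff(c("sample_id", "stratum", .REQUIRED), names(raw))
  if (length(missing) > 0) {
    stop("input file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), c("sample_id", "stratum"))
  for (p in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(is.na(v) & !is.na(raw[[p]]) & trimws(raw[[p]]) != "" &
                   toupper(trimws(raw[[p]])) != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", p, "', data row ", bad[1],
           " ('", raw[[p]][bad[1]], "')", call. = FALSE)
    }
    raw[[p]] <- v
  }
  raw$stratum <- tolower(trimws(raw$stratum))
  sample_table(raw, provenance = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert concentrations between mg/L and meq/L
#'
#' Conversion uses packaged equivalent weights (molar mass divided by absolute
#' ionic charge) for the seven major ions: Ca 20.04, Mg 12.15, Na 22.99,
#' K 39.10, HCO3 61.02, Cl 35.45, SO4 48.03 mg/meq.
#'
#' @param conc Numeric vector of concentrations (mg/L for `mgl_to_meq`,
#'   meq/L for `meq_to_mgl`); must be non-negative.
#' @param species Ion identifier: one of `"ca"`, `"mg"`, `"na"`, `"k"`,
#'   `"hco3"`, `"cl"`, `"so4"` (case-insensitive; charge decorations such as
#'   `"Ca2+"` or `"SO4^2-"` are tolerated).
#' @return Numeric vector in the target unit.
#' @export
mgl_to_meq <- function(conc, species) {
  ew <- equivalent_weight(species)
  stopifnot(all(conc >= 0, na.rm = TRUE))
  conc / ew
}

#' @rdname mgl_to_meq
#' @export
meq_to_mgl <- function(conc, species) {
  ew <- equivalent_weight(species)
  stopifnot(all(conc >= 0, na.rm = TRUE))
  conc * ew
}

equivalent_weight <- function(species) {
  key <- gsub("[^a-z0-9]", "", tolower(species))
  key <- sub("^(ca|mg|na|k|hco3|cl|so4).*$", "\\1", key)
  if (length(key) != 1 || !key %in% names(.EQ_WEIGHT)) {
    stop("unsupported species '", species, "'; supported: ",
         paste(names(.EQ_WEIGHT), collapse = ", "), call. = FALSE)
  }
  .EQ_WEIGHT[[key]]
}

#' Charge-balance (ion-balance) error in percent
#'
#' For each sample, the major-ion charge balance
#' `100 * (sum(cations) - sum(anions)) / (sum(cations) + sum(anions))`
#' with all seven major ions expressed in meq/L. The sign is preserved: a
#' positive value means a cation surplus. Samples with `|error|` beyond the
#' conventional +/-5 % analytical threshold should be flagged for review (see
#' [flag_charge_balance()]) but are not dropped.
#'
#' @param table A [sample_table()] (or data frame with the major-ion columns,
#'   mg/L).
#' @return Numeric vector of percent errors, one per sample.
#' @export
charge_balance_error <- function(table) {
  ion_sum <- function(ions) {
    m <- vapply(ions, function(p) mgl_to_meq(table[[p]], p),
                numeric(nrow(table)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rowSums(m)
  }
  cat_meq <- ion_sum(.CATIONS)
  an_meq  <- ion_sum(.ANIONS)
  tot <- cat_meq + an_meq
  if (any(tot == 0, na.rm = TRUE)) {
    stop("charge balance undefined: all major ions zero for sample(s) ",
         paste(table$sample_id[which(tot == 0)], collapse = ", "),
         call. = FALSE)
  }
  100 * (cat_meq - an_meq) / tot
}

#' @rdname charge_balance_error
#' @param threshold Absolute acceptance threshold in percent (default 5).
#' @return `flag_charge_balance`: a data frame with `sample_id`, `cbe_pct`
#'   and logical `acceptable`.
#' @export
flag_charge_balance <- function(table, threshold = 5) {
  cbe <- charge_balance_error(table)
  data.frame(sample_id = table$sample_id, cbe_pct = cbe,
             acceptable = abs(cbe) <= threshold,
             stringsAsFactors = FALSE)
}

#' Per-stratum descriptive statistics
#'
#' Minimum, maximum, mean and sample standard deviation (n-1 denominator) of
#' each parameter within each stratum, over non-missing values. A stratum with
#' no samples is omitted with a warning; a parameter observed once reports
#' `sd = 0` with `n = 1` so the degenerate case is visible.
#'
#' @param table A [sample_table()].
#' @param params Parameters to summarise (default: all measured parameters
#'   present).
#' @return Long data frame: `stratum`, `parameter`, `n`, `min`, `max`, `mean`,
#'   `sd`.
#' @export
descriptive_stats <- function(table, params = NULL) {
  params <- params %||% intersect(.PARAMS, names(table))
  strata <- intersect(.STRATA, unique(table$stratum))
  empty <- setdiff(unique(table$stratum), strata)
  out <- list()
  for (s in strata) {
    sub <- table[table$stratum == s, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      if (length(v) == 0) {
        warning("stratum '", s, "' has no values for '", p, "'; omitted")
        next
      }
      out[[length(out) + 1]] <- data.frame(
        stratum = s, parameter = p, n = length(v),
        min = min(v), max = max(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Guideline exceedance percentages
#'
#' Percent of samples whose value strictly exceeds the guideline limit, per
#' parameter, over samples with a value. pH is screened against an interval:
#' a sample exceeds when its pH falls outside `[lower, limit]`.
#'
#' @param table A [sample_table()].
#' @param guidelines Guideline table as returned by [default_guidelines()]
#'   (columns `parameter`, `lower`, `limit`).
#' @param params Parameters to screen (default: all parameters with a
#'   guideline entry that are present in `table`).
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
guideline_exceedance <- function(table, guidelines = default_guidelines(),
                                 params = NULL) {
  params <- params %||% intersect(guidelines$parameter, names(table))
  missing <- setdiff(params, guidelines$parameter)
  if (length(missing) > 0) {
    stop("parameter(s) absent from the guideline table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vapply(params, function(p) {
    g <- guidelines[guidelines$parameter == p, ]
    v <- table[[p]][!is.na(table[[p]])]
    if (length(v) == 0) return(NA_real_)
    exceed <- if (!is.na(g$lower)) v < g$lower | v > g$limit else v > g$limit
    100 * sum(exceed) / length(v)
  }, numeric(1))
  out
}

#' Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between the requested parameters.
#' Constant columns are reported as `NA` in their row and column (undefined,
#' not zero) with a warning naming the parameter.
#'
#' @param table A [sample_table()] (at least 3 samples).
#' @param params Parameters to correlate (default: all measured parameters
#'   present).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, params = NULL) {
  params <- params %||% intersect(.PARAMS, names(table))
  x <- as.matrix(as.data.frame(table)[params])
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- names(sds)[!is.na(sds) & sds == 0]
  if (length(constant) > 0) {
    warning("constant parameter(s) have undefined correlations: ",
            paste(constant, collapse = ", "))
  }
  m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- ifelse(colnames(m) %in% constant, NA_real_, 1)
  m
}

#' Normal Q-Q straightness as a squared correlation
#'
#' Measures how closely a sample follows a normal distribution as the squared
#' Pearson correlation between the sorted observations and standard-normal
#' quantiles at plotting positions `(i - a) / (n + 1 - 2a)`; the default
#' `a = 0.375` is the Blom convention.
#'
#' @param values Numeric vector with at least 4 finite, not-all-equal values.
#' @param a Plotting-position offset (default 0.375).
#' @return Squared correlation in `[0, 1]`.
#' @export
qq_normal_r2 <- function(values, a = 0.375) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values", call. = FALSE)
  if (stats::sd(v) == 0) {
    stop("normality measure undefined for constant input", call. = FALSE)
  }
  n <- length(v)
  q <- stats::qnorm((seq_len(n) - a) / (n + 1 - 2 * a))
  stats::cor(sort(v), q)^2
}
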