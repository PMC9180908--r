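#' Nemerow pollution index
#'
#' The single-parameter Nemerow (Row's) pollution index `NPI = C_n / S_n`,
#' the concentration divided by its standard limit. `NPI > 1` flags
#' contamination. pH is handled as a plain ratio against its effective
#' single-value standard (8.5 in the packaged [default_npi_standards()]).
#'
#' @param conc Non-negative concentration(s), same units as the standard.
#' @param standard Positive standard limit `S_n`.
#' @return `conc / standard`.
#' @export
nemerow_index <- function(conc, standard) {
  if (any(standard <= 0)) stop("NPI standard must be positive", call. = FALSE)
  stopifnot(all(conc >= 0, na.rm = TRUE))
  conc / standard
}

#' Per-stratum NPI summary
#'
#' Per-sample Nemerow indices summarised per stratum and parameter: min, max,
#' mean and sample sd of the per-sample index, and the percent of samples with
#' `NPI > 1`. The stratum mean is the mean of per-sample ratios (not the ratio
#' of the stratum mean), matching how campaign tables are usually compiled.
#'
#' @param table A [sample_table()].
#' @param standards NPI standards table ([default_npi_standards()]) or named
#'   vector.
#' @param params Parameters to index (default: all with a standard present in
#'   `table`).
#' @return Long data frame: `stratum`, `parameter`, `n`, `min`, `max`, `mean`,
#'   `sd`, `frac_npi_gt_1` (percent).
#' @export
npi_summary <- function(table, standards = default_npi_standards(),
                        params = NULL) {
  avail <- if (is.data.frame(standards)) standards$parameter else names(standards)
  params <- params %||% intersect(avail, names(table))
  s <- standards_vector(standards, params)
  strata <- intersect(.STRATA, unique(table$stratum))
  out <- list()
  for (st in strata) {
    sub <- table[table$stratum == st, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      if (length(v) == 0) next
      npi <- nemerow_index(v, s[[p]])
      out[[length(out) + 1]] <- data.frame(
        stratum = st, parameter = p, n = length(npi),
        min = min(npi), max = max(npi), mean = mean(npi),
        sd = if (length(npi) > 1) stats::sd(npi) else 0,
        frac_npi_gt_1 = 100 * mean(npi > 1),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Aggregate pollution index per parameter
#'
#' Two variants of the aggregate pollution index over samples are available:
#' `"sum_excess"` (the literal summed relative excess
#' `PI_p = sum_i (C_i - S_p) / S_p`, the default) and `"mean_ratio"`
#' (`PI_p = mean_i (C_i / S_p)`). The chosen variant is recorded on the
#' result; the two coincide only in degenerate cases, so downstream use must
#' track which was computed.
#'
#' @param table A [sample_table()].
#' @param standards Standards table or named vector (positive).
#' @param variant `"sum_excess"` or `"mean_ratio"`.
#' @param params Parameters to aggregate (default: the nine trace elements).
#' @return Data frame `parameter`, `pi` with attribute `variant`.
#' @export
pollution_index <- function(table, standards = default_npi_standards(),
                            variant = c("sum_excess", "mean_ratio"),
                            params = .PHES) {
  variant <- match.arg(variant)
  s <- standards_vector(standards, params)
  pi <- vapply(params, function(p) {
    v <- table[[p]][!is.na(table[[p]])]
    if (variant == "sum_excess") sum((v - s[[p]]) / s[[p]]) else mean(v / s[[p]])
  }, numeric(1))
  out <- data.frame(parameter = params, pi = unname(pi),
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- variant
  out
}

#' Per-sample pollution load
#'
#' The per-sample pollution load used as the dependent variable of the
#' source-apportionment regression: the mean concentration-to-standard ratio
#' across the trace elements (the per-sample form of the `"mean_ratio"`
#' pollution index).
#'
#' @inheritParams pollution_index
#' @return Numeric vector, one load per sample, named by `sample_id`.
#' @export
sample_pollution_load <- function(table, standards = default_npi_standards(),
                                  params = .PHES) {
  s <- standards_vector(standards, params)
  ratios <- sapply(params, function(p) table[[p]] / s[[p]])
  if (nrow(table) == 1) ratios <- matrix(ratios, nrow = 1)
  stats::setNames(rowMeans(ratios), table$sample_id)
}
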