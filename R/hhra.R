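#' Exposure profile
#'
#' Bundle of cohort-specific drinking-water exposure parameters for the
#' chronic-daily-intake model: ingestion rate `R` (L/day), body weight `BW`
#' (kg), exposure frequency `EF` (days/year, at most 366), exposure duration
#' `ED` (years) and averaging time `AT` (days). With the packaged defaults
#' ([default_exposure_profiles()]) `AT = 365 * ED`, so the bracketed exposure
#' factor `EF * ED / AT` equals 1 and `CDI = CW * R / BW`.
#'
#' @param cohort Cohort label.
#' @param ingestion_rate,body_weight,exposure_frequency,exposure_duration,averaging_time
#'   Positive scalars as described above.
#' @return A list with class `"exposure_profile"`.
#' @export
exposure_profile <- function(cohort, ingestion_rate, body_weight,
                             exposure_frequency = 365,
                             exposure_duration = 30,
                             averaging_time = 365 * exposure_duration) {
  vals <- c(ingestion_rate, body_weight, exposure_frequency,
            exposure_duration, averaging_time)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all exposure parameters must be positive", call. = FALSE)
  }
  if (exposure_frequency > 366) {
    stop("exposure_frequency cannot exceed 366 days/year", call. = FALSE)
  }
  structure(list(cohort = cohort, ingestion_rate = ingestion_rate,
                 body_weight = body_weight,
                 exposure_frequency = exposure_frequency,
                 exposure_duration = exposure_duration,
                 averaging_time = averaging_time),
            class = "exposure_profile")
}

profiles_from_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    exposure_profile(df$cohort[i], df$ingestion_rate[i], df$body_weight[i],
                     df$exposure_frequency[i], df$exposure_duration[i],
                     df$averaging_time[i])
  })
}

#' Chronic daily intake
#'
#' `CDI = CW * R * EF * ED / (BW * AT)` in mg/kg-day, for a dissolved
#' concentration `CW` (mg/L) ingested under an [exposure_profile()].
#'
#' @param cw Concentration(s) in water, mg/L, non-negative.
#' @param profile An [exposure_profile()].
#' @return Intake in mg/kg-day.
#' @export
chronic_daily_intake <- function(cw, profile) {
  stopifnot(inherits(profile, "exposure_profile"), all(cw >= 0, na.rm = TRUE))
  cw * profile$ingestion_rate * profile$exposure_frequency *
    profile$exposure_duration / (profile$body_weight * profile$averaging_time)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD`; the exposed population is conventionally assumed safe
#' when `HQ < 1`.
#'
#' @param cdi Chronic daily intake, mg/kg-day.
#' @param rfd Oral reference dose, mg/kg-day, positive.
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(is.na(rfd)) || any(rfd <= 0)) {
    stop("hazard quotient needs a positive oral reference dose", call. = FALSE)
  }
  cdi / rfd
}

#' Cancer risk
#'
#' `CR = CDI * CSF`, the incremental lifetime cancer risk for a cancer slope
#' factor in (mg/kg-day)^-1.
#'
#' @param cdi Chronic daily intake, mg/kg-day.
#' @param csf Cancer slope factor, non-negative.
#' @return Dimensionless excess lifetime risk.
#' @export
cancer_risk <- function(cdi, csf) {
  if (any(is.na(csf)) || any(csf < 0)) {
    stop("cancer risk needs a non-negative slope factor", call. = FALSE)
  }
  cdi * csf
}

#' Total hazard index
#'
#' Sum of per-element hazard quotients (non-carcinogenic branch) or cancer
#' risks (carcinogenic branch) for one cohort.
#'
#' @param values Non-empty numeric vector of per-element HQ or CR values.
#' @return Their sum.
#' @export
total_hazard_index <- function(values) {
  stopifnot(length(values) > 0)
  sum(values)
}

#' Run the full health-risk assessment
#'
#' For every cohort and trace element, computes per-sample chronic daily
#' intakes and either hazard quotients (elements classified non-carcinogenic)
#' or cancer risks (carcinogenic), pooling all samples, and summarises each as
#' min/max/mean/sd. Per-sample total hazard indices (the sum over the branch's
#' elements within a sample) are summarised the same way and appear as
#' `element = "THI"` rows.
#'
#' @param table A [sample_table()].
#' @param profiles Data frame of cohort exposure parameters
#'   ([default_exposure_profiles()]) or a list of [exposure_profile()]s.
#' @param tox Toxicity table ([default_toxicity()]): columns `element`,
#'   `rfd`, `csf`, `classification`.
#' @return Long data frame: `cohort`, `risk_type` (`"HQ"` or `"CR"`),
#'   `element`, `n`, `min`, `max`, `mean`, `sd`.
#' @export
run_hhra <- function(table, profiles = default_exposure_profiles(),
                     tox = default_toxicity()) {
  if (is.data.frame(profiles)) profiles <- profiles_from_table(profiles)
  need <- setdiff(.PHES, tox$element)
  if (length(need) > 0) {
    stop("toxicity table is missing element(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  summarise <- function(v) {
    c(n = length(v), min = min(v), max = max(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0)
  }
  out <- list()
  for (prof in profiles) {
    for (branch in c("noncarcinogenic", "carcinogenic")) {
      elems <- tox$element[tox$classification == branch]
      risk_type <- if (branch == "carcinogenic") "CR" else "HQ"
      per_sample <- matrix(NA_real_, nrow(table), length(elems),
                           dimnames = list(NULL, elems))
      for (el in elems) {
        row <- tox[tox$element == el, ]
        cdi <- chronic_daily_intake(table[[el]], prof)
        per_sample[, el] <- if (risk_type == "HQ") {
          hazard_quotient(cdi, row$rfd)
        } else {
          cancer_risk(cdi, row$csf)
        }
      }
      for (el in elems) {
        v <- per_sample[, el][!is.na(per_sample[, el])]
        out[[length(out) + 1]] <- data.frame(
          cohort = prof$cohort, risk_type = risk_type, element = el,
          t(summarise(v)), stringsAsFactors = FALSE)
      }
      thi <- rowSums(per_sample)
      thi <- thi[!is.na(thi)]
      out[[length(out) + 1]] <- data.frame(
        cohort = prof$cohort, risk_type = risk_type, element = "THI",
        t(summarise(thi)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
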