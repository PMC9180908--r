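#' Gibbs ratios
#'
#' The two Gibbs diagram ordinates for each sample: the cation ratio
#' `Na/(Na + Ca)` and the anion ratio `Cl/(Cl + HCO3)`, both computed on mg/L
#' concentrations by default (the convention of the ratio-vs-TDS diagram; set
#' `units = "meq"` to compare with literature that uses equivalents), together
#' with `log10(TDS)`.
#'
#' @param table A [sample_table()] with positive `tds`.
#' @param units `"mg"` (default) or `"meq"`.
#' @return Data frame: `sample_id`, `cation_ratio`, `anion_ratio`, `log_tds`.
#' @export
gibbs_ratios <- function(table, units = c("mg", "meq")) {
  units <- match.arg(units)
  na <- table$na; ca <- table$ca; cl <- table$cl; hco3 <- table$hco3
  if (units == "meq") {
    na <- mgl_to_meq(na, "na"); ca <- mgl_to_meq(ca, "ca")
    cl <- mgl_to_meq(cl, "cl"); hco3 <- mgl_to_meq(hco3, "hco3")
  }
  if (any(table$tds <= 0, na.rm = TRUE)) {
    stop("tds must be positive for log10(TDS)", call. = FALSE)
  }
  bad <- which(na + ca == 0 | cl + hco3 == 0)
  if (length(bad) > 0) {
    stop("Gibbs ratio undefined (zero denominator) for sample(s): ",
         paste(table$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = table$sample_id,
             cation_ratio = na / (na + ca),
             anion_ratio = cl / (cl + hco3),
             log_tds = log10(table$tds),
             stringsAsFactors = FALSE)
}

#' Chadha coordinates
#'
#' The Chadha classification plane: with all seven major ions in meq/L,
#' `x = 100 * ((Ca + Mg) - (Na + K)) / (Ca + Mg + Na + K)` and
#' `y = 100 * (HCO3 - (Cl + SO4)) / (HCO3 + Cl + SO4)`. Both coordinates are
#' percentages bounded by +/-100 and are invariant to a common rescaling of
#' all ion concentrations.
#'
#' @param table A [sample_table()].
#' @return Data frame: `sample_id`, `chadha_x`, `chadha_y`.
#' @export
chadha_coordinates <- function(table) {
  meq <- lapply(c(.CATIONS, .ANIONS), function(p) mgl_to_meq(table[[p]], p))
  names(meq) <- c(.CATIONS, .ANIONS)
  hard <- meq$ca + meq$mg
  alk  <- meq$na + meq$k
  cat_tot <- hard + alk
  an_tot  <- meq$hco3 + meq$cl + meq$so4
  bad <- which(cat_tot == 0 | an_tot == 0)
  if (length(bad) > 0) {
    stop("Chadha coordinates undefined (zero ion total) for sample(s): ",
         paste(table$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = table$sample_id,
             chadha_x = 100 * (hard - alk) / cat_tot,
             chadha_y = 100 * (meq$hco3 - (meq$cl + meq$so4)) / an_tot,
             stringsAsFactors = FALSE)
}

#' Classify water type from Chadha coordinates
#'
#' Quadrant rule: `(x > 0, y > 0)` Ca-HCO3 (weathering/recharge);
#' `(x > 0, y < 0)` Ca-Mg-Cl (reverse ion exchange); `(x < 0, y < 0)` Na-Cl
#' (evaporation/salinity); `(x < 0, y > 0)` Na-HCO3 (ion exchange). Boundary
#' points are assigned deterministically: `x = 0` is treated as the negative-x
#' side and `y = 0` as the positive-y side, so `(0, 0)` maps to Na-HCO3.
#'
#' @param x,y Chadha coordinates in percent (finite).
#' @return Character vector with values in
#'   `c("CaHCO3", "CaMgCl", "NaCl", "NaHCO3")`.
#' @export
classify_chadha <- function(x, y) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), length(x) == length(y))
  pos_x <- x > 0
  pos_y <- y >= 0
  ifelse(pos_x & pos_y, "CaHCO3",
         ifelse(pos_x & !pos_y, "CaMgCl",
                ifelse(!pos_x & !pos_y, "NaCl", "NaHCO3")))
}

# even-odd (crossing number) point-in-polygon test
in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Classify the Gibbs zone of a sample
#'
#' Point-in-polygon assignment of each `(ratio, log10 TDS)` point to one of
#' the Gibbs mechanism zones (`rock_weathering`, `evaporation`,
#' `precipitation`). The zone boundaries are data, not code: the packaged
#' defaults ([default_gibbs_polygons()]) approximate the conventional
#' boomerang envelope and can be overridden. Points inside no polygon are
#' `"outside"`.
#'
#' @param ratio Gibbs ratio in `[0, 1]` (cation or anion panel).
#' @param log_tds `log10` of TDS in mg/L.
#' @param polygons Polygon table (columns `zone`, `ratio`, `log_tds`).
#' @return Character vector of zone labels.
#' @export
classify_gibbs <- function(ratio, log_tds, polygons = default_gibbs_polygons()) {
  stopifnot(all(ratio >= 0 & ratio <= 1, na.rm = TRUE),
            all(is.finite(log_tds)))
  if (!is.data.frame(polygons) ||
      !all(c("zone", "ratio", "log_tds") %in% names(polygons))) {
    stop("malformed polygon table: need columns zone, ratio, log_tds",
         call. = FALSE)
  }
  zone <- rep("outside", length(ratio))
  for (z in unique(polygons$zone)) {
    poly <- polygons[polygons$zone == z, ]
    if (nrow(poly) < 3) stop("polygon '", z, "' has fewer than 3 vertices",
                             call. = FALSE)
    hit <- in_polygon(ratio, log_tds, poly$ratio, poly$log_tds)
    zone[zone == "outside" & hit] <- z
  }
  zone
}

#' Facies assignment table
#'
#' Convenience wrapper producing one row per sample with Gibbs ratios,
#' Chadha coordinates, the Chadha water type and the Gibbs zone (cation
#' panel).
#'
#' @inheritParams gibbs_ratios
#' @param polygons Gibbs zone polygons (see [classify_gibbs()]).
#' @return Data frame: `sample_id`, `cation_ratio`, `anion_ratio`, `log_tds`,
#'   `chadha_x`, `chadha_y`, `water_type`, `gibbs_zone`.
#' @export
assign_facies <- function(table, units = c("mg", "meq"),
                          polygons = default_gibbs_polygons()) {
  g <- gibbs_ratios(table, units = units)
  ch <- chadha_coordinates(table)
  out <- merge(g, ch, by = "sample_id", sort = FALSE)
  out <- out[match(table$sample_id, out$sample_id), ]
  out$water_type <- classify_chadha(out$chadha_x, out$chadha_y)
  out$gibbs_zone <- classify_gibbs(out$cation_ratio, out$log_tds, polygons)
  rownames(out) <- NULL
  out
}
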