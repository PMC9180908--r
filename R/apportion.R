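#' Varimax-rotated principal component analysis
#'
#' Eigen-decomposition of the Pearson correlation matrix of standardised
#' variables (zero mean, unit n-1 variance), retaining `n_factors` components
#' whose loadings are varimax-rotated (Kaiser-normalised, tolerance 1e-8).
#' Each rotated loading column is sign-flipped so its largest-magnitude entry
#' is positive. Scores are the standardised samples projected onto the
#' rotated component directions. Variance percentages are
#' `eigenvalue / p * 100` since standardised variables carry unit variance.
#'
#' @param table A [sample_table()] or data frame.
#' @param params Variables to analyse (default: all measured parameters
#'   present).
#' @param n_factors Number of retained factors (default 3); `"kaiser"`
#'   retains eigenvalues greater than 1.
#' @return List with `eigenvalues` (all p), `variance_pct`, `cumulative_pct`,
#'   `loadings` (variable x factor), `scores` (sample x factor), `n_factors`,
#'   and `rotmat`.
#' @export
varimax_pca <- function(table, params = NULL, n_factors = 3) {
  params <- params %||% intersect(.PARAMS, names(table))
  x <- as.matrix(as.data.frame(table)[params])
  if (anyNA(x)) stop("PCA requires complete data for the chosen parameters",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(params[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  z <- scale(x)
  C <- stats::cor(x)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (identical(n_factors, "kaiser")) n_factors <- sum(ev > 1)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1 || n_factors > length(params)) {
    stop("n_factors must be between 1 and the number of variables",
         call. = FALSE)
  }
  if (nrow(x) < n_factors + 1) {
    stop("need at least n_factors + 1 samples", call. = FALSE)
  }
  V <- eig$vectors[, seq_len(n_factors), drop = FALSE]
  L <- V %*% diag(sqrt(ev[seq_len(n_factors)]), n_factors)
  rot <- if (n_factors > 1) {
    stats::varimax(L, normalize = TRUE, eps = 1e-8)$rotmat
  } else {
    matrix(1, 1, 1)
  }
  Lr <- L %*% rot
  flip <- apply(Lr, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  Lr <- sweep(Lr, 2, flip, `*`)
  scores <- (z %*% V %*% rot) %*% diag(flip, n_factors)
  fnames <- paste0("F", seq_len(n_factors))
  dimnames(Lr) <- list(params, fnames)
  dimnames(scores) <- list(rownames(x) %||% table$sample_id, fnames)
  list(eigenvalues = ev,
       variance_pct = 100 * ev / length(params),
       cumulative_pct = cumsum(100 * ev / length(params)),
       loadings = Lr, scores = scores,
       n_factors = n_factors, rotmat = rot)
}

#' Source contributions by the R-squared-difference regression recipe
#'
#' The percent-contribution procedure used with PCA-MLR source apportionment:
#' the per-sample pollution load is regressed on all factor scores to obtain
#' `R2_full`; each factor is then removed in turn and the model refitted,
#' giving `R2_without[k]`; the increment `R2_diff[k] = max(0, R2_full -
#' R2_without[k])` (negative increments, possible with correlated scores, are
#' clamped to zero) is normalised so the contributions sum to 100 percent.
#'
#' @param scores Sample-by-factor score matrix (columns named, at least
#'   `ncol + 2` rows).
#' @param load Per-sample pollution load aligned with `scores` rows (see
#'   [sample_pollution_load()]).
#' @return List: `r2_full`, `r2_without`, `r2_diff`, `contribution_pct`.
#' @export
apcs_mlr_contributions <- function(scores, load) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (length(load) != nrow(scores)) {
    stop("scores and load must be aligned by sample", call. = FALSE)
  }
  if (nrow(scores) < k + 2) stop("need at least n_factors + 2 samples",
                                 call. = FALSE)
  if (stats::sd(load) == 0) {
    stop("degenerate fit: pollution load is constant; contributions undefined",
         call. = FALSE)
  }
  if (is.null(colnames(scores))) colnames(scores) <- paste0("F", seq_len(k))
  r2 <- function(m) suppressWarnings(summary(m)$r.squared)
  full <- stats::lm(load ~ scores)
  r2_full <- r2(full)
  r2_without <- vapply(seq_len(k), function(j) {
    r2(stats::lm(load ~ scores[, -j, drop = FALSE]))
  }, numeric(1))
  names(r2_without) <- colnames(scores)
  r2_diff <- stats::setNames(pmax(0, r2_full - r2_without),
                             names(r2_without))
  if (sum(r2_diff) == 0) {
    stop("degenerate fit: no factor changes R-squared; contributions undefined",
         call. = FALSE)
  }
  list(r2_full = r2_full, r2_without = r2_without, r2_diff = r2_diff,
       contribution_pct = 100 * r2_diff / sum(r2_diff))
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of standardised samples with Ward's
#' minimum-variance linkage on Euclidean distances, cut into `k` clusters.
#' The within/between-class variance split is computed from the cluster
#' assignments on the standardised data (they sum to 100 percent).
#'
#' @param table A [sample_table()] or data frame.
#' @param params Variables to cluster on (default: all measured parameters
#'   present).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return List: `labels` (factor `C1..Ck` per sample), `merge_heights`,
#'   `within_class_pct`, `between_class_pct`, `centroid_distances`
#'   (inter-centroid Euclidean distances), `hclust`.
#' @export
ward_clusters <- function(table, params = NULL, k = 3) {
  params <- params %||% intersect(.PARAMS, names(table))
  x <- as.matrix(as.data.frame(table)[params])
  if (anyNA(x)) stop("clustering requires complete data", call. = FALSE)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples",
                           call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  z <- scale(x[, sds > 0, drop = FALSE])
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  tot <- sum(scale(z, scale = FALSE)^2)
  within <- sum(vapply(split(seq_len(n), labels), function(idx) {
    sum(scale(z[idx, , drop = FALSE], scale = FALSE)^2)
  }, numeric(1)))
  within_pct <- if (tot > 0) 100 * within / tot else 100
  centroids <- do.call(rbind, lapply(split(seq_len(n), labels), function(idx) {
    colMeans(z[idx, , drop = FALSE])
  }))
  list(labels = factor(paste0("C", labels), levels = paste0("C", seq_len(k))),
       merge_heights = hc$height,
       within_class_pct = within_pct,
       between_class_pct = 100 - within_pct,
       centroid_distances = stats::dist(centroids),
       hclust = hc)
}

#' Full source-apportionment run
#'
#' Varimax PCA on the chosen variables, per-sample pollution load over the
#' trace elements, and the R-squared-difference contribution recipe, bundled.
#'
#' @inheritParams varimax_pca
#' @param standards Standards used for the pollution load
#'   ([default_npi_standards()]).
#' @param load_params Elements entering the load (default: the nine trace
#'   elements).
#' @return List combining the [varimax_pca()] fields with `load` and the
#'   [apcs_mlr_contributions()] fields.
#' @export
apportion_sources <- function(table, params = NULL, n_factors = 3,
                              standards = default_npi_standards(),
                              load_params = .PHES) {
  pca <- varimax_pca(table, params = params, n_factors = n_factors)
  load <- sample_pollution_load(table, standards, load_params)
  c(pca, list(load = load),
    apcs_mlr_contributions(pca$scores, load))
}
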