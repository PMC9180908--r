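# plain data frames with measured-parameter names double as PCA input
param_frame <- function(cols) {
  as.data.frame(cols, stringsAsFactors = FALSE)
}

test_that("uncorrelated variables give unit eigenvalues and equal variance", {
  set.seed(31)
  raw <- matrix(stats::rnorm(200), 50, 4)
  pcs <- stats::prcomp(raw)$x  # exactly uncorrelated columns
  x <- param_frame(list(ni = pcs[, 1], mn = pcs[, 2], cr = pcs[, 3],
                        cu = pcs[, 4]))
  res <- varimax_pca(x, params = c("ni", "mn", "cr", "cu"), n_factors = 2)
  expect_no_mismatch(res$eigenvalues, rep(1, 4))
  expect_no_mismatch(res$variance_pct, rep(25, 4))
})

test_that("a two-group latent design separates and matches the eigen-oracle", {
  set.seed(32)
  n <- 60
  za <- stats::rnorm(n); zb <- stats::rnorm(n)
  x <- param_frame(list(
    ni = za + stats::rnorm(n, 0, 0.1),
    mn = za + stats::rnorm(n, 0, 0.1),
    cr = zb + stats::rnorm(n, 0, 0.1),
    cu = zb + stats::rnorm(n, 0, 0.1),
    cd = zb + stats::rnorm(n, 0, 0.1)
  ))
  params <- c("ni", "mn", "cr", "cu", "cd")
  res <- varimax_pca(x, params = params, n_factors = 2)

  # brute-force oracle: correlation by explicit two-pass formula, then eigen
  xm <- as.matrix(x)
  zc <- apply(xm, 2, function(v) (v - mean(v)) / stats::sd(v))
  C <- crossprod(zc) / (n - 1)
  ev_oracle <- eigen(C, symmetric = TRUE)$values
  expect_no_mismatch(res$eigenvalues, ev_oracle, 1e-8)

  dominant <- apply(abs(res$loadings), 1, which.max)
  expect_equal(length(unique(dominant[c("ni", "mn")])), 1)
  expect_equal(length(unique(dominant[c("cr", "cu", "cd")])), 1)
  expect_false(dominant[["ni"]] == dominant[["cr"]])
})

test_that("duplicated variables receive identical loadings", {
  set.seed(33)
  n <- 40
  base <- list(ni = stats::rnorm(n), mn = stats::rnorm(n),
               cr = stats::rnorm(n))
  base$cu <- base$cr
  res <- varimax_pca(param_frame(base), params = c("ni", "mn", "cr", "cu"),
                     n_factors = 2)
  expect_no_mismatch(res$loadings["cr", ], res$loadings["cu", ], 1e-8)
})

test_that("eigen trace and varimax communalities are conserved", {
  for (seed in 1:3) {
    tab <- random_table(25, seed)
    params <- c("ph", "ec", "tds", "ca", "na", "hco3", "so4", "fe", "cd")
    res <- varimax_pca(tab, params = params, n_factors = 3)
    expect_equal(sum(res$eigenvalues), length(params), tolerance = 1e-8)
    # rotation must preserve per-variable communality
    eigv <- eigen(stats::cor(as.data.frame(tab)[params]), symmetric = TRUE)
    L <- eigv$vectors[, 1:3] %*% diag(sqrt(eigv$values[1:3]))
    expect_no_mismatch(rowSums(res$loadings^2), rowSums(L^2), 1e-8)
  }
  flat <- param_frame(list(ni = stats::rnorm(10), mn = stats::rnorm(10),
                           cr = stats::rnorm(10), cu = rep(1, 10)))
  expect_error(varimax_pca(flat, params = c("ni", "mn", "cr", "cu")),
               "constant")
})

test_that("contribution recipe recovers exact single-source and symmetric designs", {
  set.seed(34)
  n <- 30
  raw <- matrix(stats::rnorm(n * 3), n, 3)
  scores <- qr.Q(qr(cbind(1, raw)))[, -1]  # orthonormal, centred
  colnames(scores) <- paste0("F", 1:3)

  res1 <- apcs_mlr_contributions(scores, 2 * scores[, 1])
  expect_no_mismatch(res1$contribution_pct, c(100, 0, 0), 1e-8)

  res3 <- apcs_mlr_contributions(scores, rowSums(scores))
  expect_no_mismatch(res3$contribution_pct, rep(100 / 3, 3), 1e-8)
  expect_equal(unname(res3$r2_full), 1, tolerance = 1e-10)

  # relabelling factors permutes contributions identically
  perm <- c(2, 3, 1)
  resp <- apcs_mlr_contributions(scores[, perm], rowSums(scores))
  expect_no_mismatch(sort(resp$contribution_pct),
                     sort(res3$contribution_pct), 1e-8)

  expect_error(apcs_mlr_contributions(scores, rep(1, n)), "degenerate")
})

test_that("contribution recipe matches an all-subset regression oracle", {
  # oracle: R^2 for every factor subset via explicit least squares
  oracle_r2 <- function(X, y) {
    X1 <- cbind(1, X)
    beta <- qr.solve(X1, y)
    rss <- sum((y - X1 %*% beta)^2)
    1 - rss / sum((y - mean(y))^2)
  }
  set.seed(35)
  for (rep in 1:5) {
    n <- 20
    scores <- matrix(stats::rnorm(n * 3), n, 3,
                     dimnames = list(NULL, paste0("F", 1:3)))
    scores[, 2] <- scores[, 2] + 0.4 * scores[, 1]  # correlated scores
    load <- 0.7 * scores[, 1] + 0.3 * scores[, 2] + stats::rnorm(n, 0, 0.2)
    res <- apcs_mlr_contributions(scores, load)
    r2_full <- oracle_r2(scores, load)
    expect_equal(unname(res$r2_full), r2_full, tolerance = 1e-10)
    for (j in 1:3) {
      expect_equal(unname(res$r2_without[j]),
                   oracle_r2(scores[, -j, drop = FALSE], load),
                   tolerance = 1e-10)
    }
    diff <- pmax(0, r2_full - vapply(1:3, function(j) {
      oracle_r2(scores[, -j, drop = FALSE], load)
    }, numeric(1)))
    expect_no_mismatch(res$contribution_pct, 100 * diff / sum(diff), 1e-8)
    # dominant / minor / nil ordering
    expect_true(which.max(res$contribution_pct) == 1)
    expect_true(res$contribution_pct[2] > res$contribution_pct[3])
  }
})

test_that("ward clustering recovers well-separated clouds and handles edges", {
  set.seed(36)
  n_per <- 10
  centres <- c(0, 10, 20)
  truth <- rep(1:3, each = n_per)
  mk <- function() centres[truth] + stats::rnorm(3 * n_per, 0, 0.1)
  x <- param_frame(list(fe = mk(), zn = mk(), cu = mk()))
  res <- ward_clusters(x, params = c("fe", "zn", "cu"), k = 3)
  expect_equal(length(unique(table(res$labels, truth)[table(res$labels, truth) > 0])),
               1)  # perfect block structure
  expect_lt(res$within_class_pct, 1)
  expect_equal(res$within_class_pct + res$between_class_pct, 100)

  one <- ward_clusters(x, params = c("fe", "zn", "cu"), k = 1)
  expect_equal(one$within_class_pct, 100)

  dup <- param_frame(list(fe = c(1, 1, 5, 9), zn = c(2, 2, 6, 8)))
  resd <- ward_clusters(dup, params = c("fe", "zn"), k = 2)
  expect_equal(resd$labels[1], resd$labels[2])

  expect_error(ward_clusters(x, params = c("fe", "zn"), k = 0), "between")
  expect_error(ward_clusters(x, params = c("fe", "zn"), k = 99), "between")
})
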