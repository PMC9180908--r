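test_that("read_samples round-trips a well-formed file and preserves order", {
  tab <- toy_table(3)
  path <- write_sample_csv(tab)
  got <- read_samples(path)
  expect_s3_class(got, "sample_table")
  expect_equal(got$sample_id, c("S01", "S02", "S03"))
  expect_equal(got$ca, tab$ca)
})

test_that("read_samples reports schema, parse and duplicate-id errors", {
  tab <- as.data.frame(toy_table(3))
  path <- write_sample_csv(sample_table(tab))

  no_cd <- tab[setdiff(names(tab), "cd")]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(no_cd, p2, row.names = FALSE)
  expect_error(read_samples(p2), "cd")

  txt <- readLines(path)
  txt[3] <- sub("0.06", "oops", txt[3], fixed = TRUE)
  p3 <- tempfile(fileext = ".csv")
  writeLines(txt, p3)
  expect_error(read_samples(p3), "row 2")

  dup <- tab; dup$sample_id <- c("A", "A", "B")
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(dup, p4, row.names = FALSE)
  expect_error(read_samples(p4), "duplicate")
})

test_that("headers are matched case-insensitively with unit annotations", {
  tab <- as.data.frame(toy_table(2))
  names(tab)[names(tab) == "ca"] <- "Ca (mg/L)"
  names(tab)[names(tab) == "temp"] <- "Temperature"
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  got <- read_samples(path)
  expect_equal(got$ca, c(40, 40))
})

test_that("a stratified campaign file yields the expected strata counts", {
  cfg <- synthetic_config()
  tab <- simulate_samples(cfg, seed = 3)
  gw <- write_sample_csv(sample_table(as.data.frame(tab)[tab$stratum != "mine", ]))
  mine_df <- as.data.frame(tab)[tab$stratum == "mine", ]
  mine_df$stratum <- NULL
  mw <- tempfile(fileext = ".csv")
  utils::write.csv(mine_df, mw, row.names = FALSE)
  combined <- rbind(as.data.frame(read_samples(gw)),
                    as.data.frame(read_samples(mw, stratum = "mine")))
  counts <- table(combined$stratum)
  expect_equal(unname(counts[c("shallow", "mid", "deep", "mine")]),
               c(24L, 14L, 12L, 7L), ignore_attr = TRUE)
})

test_that("validation enforces the physical invariants", {
  tab <- as.data.frame(toy_table(2))
  bad <- tab; bad$cd[1] <- -0.1
  expect_error(sample_table(bad), "negative")
  bad <- tab; bad$ph[2] <- 14.2
  expect_error(sample_table(bad), "ph")
  bad <- tab; bad$depth <- c(30, 95)  # deep depth labelled shallow
  expect_error(sample_table(bad), "mismatch")
  ok <- tab; ok$depth <- c(30, 38)
  expect_s3_class(sample_table(ok), "sample_table")
})

test_that("meq conversion matches hand-computed equivalents and round-trips", {
  expect_equal(mgl_to_meq(40.08, "ca"), 2.0, tolerance = 1e-6)
  expect_equal(mgl_to_meq(96.06, "so4"), 2.0, tolerance = 1e-3)
  expect_equal(mgl_to_meq(0, "cl"), 0)
  expect_equal(mgl_to_meq(61.02, "HCO3^-"), 1.0)
  expect_error(mgl_to_meq(1, "po4"), "unsupported")

  set.seed(42)
  for (sp in c("ca", "mg", "na", "k", "hco3", "cl", "so4")) {
    x <- stats::runif(20, 0, 500)
    expect_no_mismatch(meq_to_mgl(mgl_to_meq(x, sp), sp) / x - 1, 0, 1e-9)
  }
})

test_that("charge balance error has the documented sign, symmetry and bounds", {
  expect_equal(charge_balance_error(balance_table(10, 10)), 0)
  expect_equal(charge_balance_error(balance_table(10.5, 9.5)), 5.0)
  expect_equal(charge_balance_error(balance_table(10, 0)), 100)
  # antisymmetry under swapping totals
  set.seed(7)
  a <- stats::runif(10, 0.1, 20); b <- stats::runif(10, 0.1, 20)
  expect_no_mismatch(charge_balance_error(balance_table(a, b)),
                     -charge_balance_error(balance_table(b, a)))
  expect_error(charge_balance_error(balance_table(0, 0)), "undefined")
  flags <- flag_charge_balance(balance_table(c(10.5, 12), c(9.5, 9)))
  expect_equal(flags$acceptable, c(TRUE, FALSE))
})

test_that("descriptive stats agree with brute-force two-pass formulas", {
  tab <- conc_table(c(2, 4), "fe")
  st <- descriptive_stats(tab, "fe")
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)

  one <- descriptive_stats(conc_table(5, "fe"), "fe")
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1)

  five <- descriptive_stats(conc_table(c(1, 2, 3, 4, 5), "fe"), "fe")
  expect_equal(c(five$min, five$max, five$mean), c(1, 5, 3))

  # brute force property on random tables
  for (seed in 1:3) {
    tab <- random_table(15, seed)
    st <- descriptive_stats(tab)
    for (i in seq_len(nrow(st))) {
      v <- tab[[st$parameter[i]]][tab$stratum == st$stratum[i]]
      m <- sum(v) / length(v)
      s2 <- sum((v - m)^2) / (length(v) - 1)
      expect_equal(st$mean[i], m)
      expect_equal(st$sd[i], sqrt(s2), tolerance = 1e-12)
    }
  }
})

test_that("guideline exceedance counts strict exceedances and pH intervals", {
  tab <- conc_table(c(0.2, 0.2, 0.4, 0.4), "fe")  # limit 0.3
  expect_equal(unname(guideline_exceedance(tab, params = "fe")), 50)
  expect_equal(unname(guideline_exceedance(conc_table(c(0.1, 0.2), "fe"),
                                           params = "fe")), 0)
  expect_equal(unname(guideline_exceedance(conc_table(c(0.5, 0.9), "fe"),
                                           params = "fe")), 100)
  # exactly at the limit does not exceed
  expect_equal(unname(guideline_exceedance(conc_table(0.3, "fe"),
                                           params = "fe")), 0)
  # pH outside [6.5, 9.2] in either direction counts
  ph_tab <- conc_table(c(6.0, 7.0, 9.5, 8.0), "ph")
  expect_equal(unname(guideline_exceedance(ph_tab, params = "ph")), 50)
  expect_error(guideline_exceedance(tab, params = "unobtainium"), "absent")
})

test_that("pearson matrix matches brute-force covariance over sigma products", {
  tab <- as.data.frame(toy_table(3))
  tab$fe <- c(1, 2, 3); tab$zn <- c(2, 4, 6); tab$cu <- c(3, 2, 1)
  tab$cd <- c(1, 3, 2)
  m <- pearson_matrix(sample_table(tab), c("fe", "zn", "cu", "cd"))
  expect_equal(m["fe", "zn"], 1)
  expect_equal(m["fe", "cu"], -1)
  expect_equal(m["fe", "cd"], 0.5)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 4))

  tab2 <- random_table(12, seed = 5)
  params <- c("ca", "na", "fe", "cd", "so4")
  m2 <- pearson_matrix(tab2, params)
  brute <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in seq_along(params)) for (j in seq_along(params)) {
    expect_equal(m2[i, j], brute(tab2[[params[i]]], tab2[[params[j]]]),
                 tolerance = 1e-12)
  }

  tab3 <- as.data.frame(tab2); tab3$ni <- 0.2  # constant
  expect_warning(mc <- pearson_matrix(sample_table(tab3), c("ca", "ni")),
                 "ni")
  expect_true(all(is.na(mc["ni", ])))
})

test_that("qq normality statistic behaves like a straightness measure", {
  n <- 30
  q <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  expect_equal(qq_normal_r2(5 + 2 * q), 1, tolerance = 1e-12)

  v <- 1:20
  # independent oracle: Pearson formula applied to (sorted data, quantiles)
  qs <- stats::qnorm((1:20 - 0.375) / (20 + 0.25))
  r <- sum((v - mean(v)) * (qs - mean(qs))) /
    sqrt(sum((v - mean(v))^2) * sum((qs - mean(qs))^2))
  expect_equal(qq_normal_r2(v), r^2, tolerance = 1e-12)

  set.seed(11)
  base <- stats::rnorm(40)
  expect_lt(qq_normal_r2(c(base, 25)), qq_normal_r2(base))
  expect_error(qq_normal_r2(rep(1, 10)), "constant")
  expect_error(qq_normal_r2(c(1, 2, 3)), "at least 4")
})
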