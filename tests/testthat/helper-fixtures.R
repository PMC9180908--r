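# Fixtures built in code; no data files.

# a small complete sample table with hand-set chemistry
toy_table <- function(n = 3, stratum = "shallow") {
  base <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    stratum = stratum,
    ph = 7.5, ec = 700, tds = 450,
    ca = 40, mg = 24, k = 8, na = 150,
    hco3 = 300, cl = 110, so4 = 160,
    ni = 0.2, mn = 0.3, cr = 0.08, cu = 0.4, cd = 0.06,
    pb = 0.06, co = 0.07, fe = 0.8, zn = 0.2,
    stringsAsFactors = FALSE
  )
  sample_table(base)
}

# table whose concentrations are free parameters for a single element
conc_table <- function(values, element, stratum = "shallow") {
  tab <- as.data.frame(toy_table(length(values), stratum))
  tab[[element]] <- values
  sample_table(tab)
}

# random full table for property tests
random_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  tab <- as.data.frame(toy_table(n))
  for (p in c("ec", "tds", "ca", "mg", "k", "na", "hco3", "cl", "so4",
              "ni", "mn", "cr", "cu", "cd", "pb", "co", "fe", "zn")) {
    tab[[p]] <- tab[[p]] * exp(stats::rnorm(n, 0, 0.4))
  }
  tab$ph <- pmin(13.5, pmax(0.5, tab$ph + stats::rnorm(n, 0, 0.3)))
  sample_table(tab)
}

# a table whose major ions produce prescribed cation/anion meq totals using
# single carriers (ca for cations, cl for anions)
balance_table <- function(cat_meq, an_meq) {
  tab <- as.data.frame(toy_table(length(cat_meq)))
  tab$mg <- tab$k <- tab$na <- 0
  tab$hco3 <- tab$so4 <- 0
  tab$ca <- cat_meq * 20.04
  tab$cl <- an_meq * 35.45
  sample_table(tab)
}

write_sample_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  path
}

expect_no_mismatch <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
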