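test_that("descriptors reproduce the textbook identities", {
  d <- formula_descriptors(data.frame(c = c(6, 1, 1), h = c(12, 4, 0),
                                      o = c(6, 0, 2)))
  # glucose
  expect_equal(d$neutral_mass[1], 180.063388, tolerance = 1e-6)
  expect_equal(d$theoretical_mz[1], 180.063388 - 1.00727646688,
               tolerance = 1e-6)
  expect_equal(d$hc[1], 2)
  expect_equal(d$oc[1], 1)
  expect_equal(d$dbe[1], 1)
  expect_equal(d$nosc[1], 0)
  expect_equal(d$series[1], "CHO")
  # the fully reduced and fully oxidized carbon limits
  expect_equal(d$nosc[2], -4)   # CH4
  expect_equal(d$nosc[3], 4)    # CO2
  # heteroatom series from element presence
  ser <- formula_descriptors(data.frame(c = 10, h = 14, n = c(0, 1, 0, 2),
                                        o = 4, s = c(0, 0, 1, 1)))$series
  expect_equal(ser, c("CHO", "CHNO", "CHOS", "CHNOS"))
})

test_that("theoretical m/z round-trips through candidate enumeration at 0 ppm", {
  set.seed(11)
  g <- oracle_full_grid()
  ok <- g$hc >= 0.3 & g$hc <= 2.5 & g$oc <= 1.2 &
    g$dbe >= 0 & g$dbe <= 25 & abs(g$dbe - round(g$dbe)) < 1e-9 &
    g$nosc >= -4 & g$nosc <= 4 & g$mass > 150 & g$mass < 750
  pick <- g[sample(which(ok), 25), ]
  for (i in seq_len(nrow(pick))) {
    mz <- pick$mass[i] - 1.00727646688
    cand <- candidate_formulas(mz, assignment_config())
    self <- cand[cand$c == pick$c[i] & cand$h == pick$h[i] &
                   cand$n == pick$n[i] & cand$o == pick$o[i] &
                   cand$s == pick$s[i], ]
    expect_equal(nrow(self), 1L)
    expect_lt(abs(self$ppm_error), 1e-6)
  }
})

test_that("candidate enumeration matches the brute-force oracle", {
  set.seed(7)
  mzs <- runif(30, 120, 780)
  cfg <- assignment_config()
  grid <- cesdyn:::candidate_base_grid(cfg)
  for (mz in mzs) {
    mine <- candidate_formulas(mz, cfg, grid = grid)
    orc <- oracle_candidates(mz, 1)
    expect_equal(nrow(mine), nrow(orc))
    if (nrow(orc)) {
      key <- function(d) sort(paste(d$c, d$h, d$n, d$o, d$s))
      expect_equal(key(mine), key(orc))
    }
  }
  # zero-width tolerance window at an arbitrary mass finds nothing
  expect_equal(nrow(candidate_formulas(100.0, assignment_config(tolerance_ppm = 0))),
               0L)
  # results sorted by |ppm error|
  cand <- candidate_formulas(451.1234, cfg, grid = grid)
  if (nrow(cand) > 1) expect_true(!is.unsorted(abs(cand$ppm_error)))
})

test_that("assignment recovers noiseless truth and merges duplicate formulas", {
  dx <- gen_dom_peaklists(tiny_dom_scenario())
  pk <- dx$peaklists[[1]]
  tr <- dx$truth$samples[[1]]
  asn <- assign_peaklist(pk)
  expect_equal(nrow(asn$unassigned), 0L)
  hit <- merge(asn$assigned[, c("mz", "formula")],
               data.frame(mz = tr$mz, truth = tr$formula), by = "mz")
  expect_equal(mean(hit$formula == hit$truth), 1)

  # two peaks resolving to the same formula merge by summing intensity
  mz_g <- 180.063388 - 1.00727646688
  two <- data.frame(mz = c(mz_g, mz_g * (1 + 2e-7)), intensity = c(3, 7))
  m <- assign_peaklist(two)
  expect_equal(nrow(m$assigned), 1L)
  expect_equal(m$assigned$intensity, 10)
  expect_equal(m$assigned$n_peaks, 2L)
})

test_that("van Krevelen classification follows the scheme with first-match wins", {
  expect_equal(classify_formula(1.2, 0.4), "lignin/CRAM-like")
  expect_equal(classify_formula(1.8, 0.1), "lipids")
  expect_equal(classify_formula(2.6, 0.5), "unclassified")
  # boundary conventions: lipid O/C upper bound is exclusive
  expect_equal(classify_formula(1.8, 0.3), "aliphatic/peptides")
  expect_equal(classify_formula(c(2.0, 0.6, 0.4), c(0.8, 0.1, 0.3)),
               c("carbohydrates", "aromatic structures", "aromatic structures"))
  # scheme order decides overlapping rules
  custom <- class_scheme(label = c("a", "b"), hc_lo = c(0, 0), hc_hi = c(2, 2),
                         oc_lo = c(0, 0), oc_hi = c(1, 1))
  expect_equal(classify_formula(1, 0.5, custom), "a")
})

test_that("class abundance fractions sum to one under both weightings", {
  a <- data.frame(
    compound_class = c("lipids", "lipids", "tannins", "tannins", "tannins"),
    intensity = c(10, 20, 30, 30, 10)
  )
  by_int <- class_abundance(a, "intensity")
  by_cnt <- class_abundance(a, "count")
  expect_equal(sum(by_int), 1)
  expect_equal(sum(by_cnt), 1)
  expect_equal(unname(by_int[["lipids"]]), 0.3)
  expect_equal(unname(by_int[["tannins"]]), 0.7)
  expect_equal(unname(by_cnt[["lipids"]]), 0.4)
  expect_equal(unname(by_cnt[["tannins"]]), 0.6)
  expect_error(class_abundance(a[0, ]), "no assigned")
})

test_that("chemodiversity is the Shannon index of intensity shares", {
  expect_equal(chemodiversity(rep(2, 4)), log(4))
  expect_equal(chemodiversity(5), 0)
  expect_equal(chemodiversity(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_error(chemodiversity(c(1, 0)), "positive")
  # bounded by log richness
  set.seed(3)
  x <- rlnorm(50)
  expect_lte(chemodiversity(x), log(50))
})

test_that("formula set comparison partitions shared and unique formulas", {
  a <- data.frame(formula = c("C6H12O6", "C10H14O4"),
                  compound_class = c("carbohydrates", "lignin/CRAM-like"),
                  intensity = c(1, 2))
  b <- data.frame(formula = "C6H12O6", compound_class = "carbohydrates",
                  intensity = 3)
  cmp <- compare_formula_sets(a, b)
  expect_equal(cmp$shared$formula, "C6H12O6")
  expect_equal(cmp$unique_a$formula, "C10H14O4")
  expect_equal(nrow(cmp$unique_b), 0L)
  ident <- compare_formula_sets(a, a)
  expect_equal(nrow(ident$shared), 2L)
  expect_equal(nrow(ident$unique_a), 0L)
  disj <- compare_formula_sets(
    a, data.frame(formula = "C5H10O5", compound_class = "carbohydrates",
                  intensity = 1))
  expect_equal(nrow(disj$shared), 0L)
})

test_that("assignment recovery degrades monotonically with mass noise", {
  recov <- vapply(c(0.2, 2), function(sd_ppm) {
    dx <- gen_dom_peaklists(dom_scenario(
      time_points = "d1", n_cho = 150, n_chno = 100, n_chos = 50,
      n_replicates = 1, ppm_noise_sd = sd_ppm, seed = 9
    ))
    pk <- dx$peaklists[[1]]
    tr <- dx$truth$samples[[1]]
    asn <- assign_peaklist(pk)
    hit <- merge(asn$assigned[, c("mz", "formula")],
                 data.frame(mz = tr$mz, truth = tr$formula), by = "mz")
    sum(hit$formula == hit$truth) / nrow(tr)
  }, 0)
  expect_gte(recov[1], 0.99)
  expect_lte(recov[2], recov[1])
})
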