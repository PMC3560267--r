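make_table <- function(n11, n12, n21, n22, p0 = 0.5) {
  structure(list(n11 = n11, n12 = n12, n21 = n21, n22 = n22, p0 = p0,
                 e = outer(c(n11 + n12, n21 + n22), c(n11 + n21, n12 + n22)) /
                   (n11 + n12 + n21 + n22),
                 high_risk_cells = integer(0),
                 degenerate = (n11 + n12 == 0) || (n21 + n22 == 0)),
            class = "predisposing_table")
}

test_that("raw statistics match closed-form hand evaluation", {
  st <- raw_statistics(make_table(20, 10, 10, 20))
  expect_equal(st$or, 4)
  expect_equal(st$rr, 2)
  expect_equal(st$chi, 100 / 15)

  st2 <- raw_statistics(make_table(15, 15, 15, 15))
  expect_equal(st2$or, 1)
  expect_equal(st2$rr, 1)
  expect_equal(st2$chi, 0)
})

test_that("zero cells trigger the +0.5 correction for OR and RR", {
  st <- raw_statistics(make_table(20, 0, 10, 20))
  expect_equal(st$or, (20.5 * 20.5) / (0.5 * 10.5))
  expect_equal(st$rr, (20.5 / 21) / (10.5 / 31))
  # chi still uses the uncorrected counts
  o <- oracle_raw_stats(20, 0, 10, 20)
  expect_equal(st$chi, o$chi)
})

test_that("degenerate tables yield NA statistics", {
  st <- raw_statistics(make_table(0, 0, 30, 30))
  expect_true(all(is.na(unlist(st))))
})

test_that("the order-statistic ecdf and inverse agree with their definitions", {
  s <- c(1, 2, 3, 4)
  expect_equal(amdr:::ecdf_value(s, 2.5), 0.5)
  expect_equal(amdr:::ecdf_value(s, 4), 1)
  expect_equal(amdr:::quantile_inf(s, 0.5), 2)
  expect_equal(amdr:::quantile_inf(s, 1), 4)
  # mutual consistency on samples
  withr::with_seed(2, x <- rnorm(37))
  for (v in x) {
    expect_lte(amdr:::quantile_inf(x, amdr:::ecdf_value(x, v)), v)
  }
  # agreement with the loop oracle at arbitrary probabilities
  for (p in c(0.025, 0.31, 0.5, 0.975)) {
    expect_equal(amdr:::quantile_inf(x, p), oracle_quantile(x, p))
  }
})

test_that("calibration returns 1 when null and alternative CDFs coincide", {
  withr::with_seed(7, s <- rgamma(200, 2))
  for (x in s[1:20]) {
    expect_equal(corrected_statistic(x, s, s), 1)
  }
  # x above every null sample divides by the null maximum
  expect_equal(corrected_statistic(10, c(1, 2, 4), c(5, 9, 10)), 10 / 4)
})

test_that("permutation p-values count the strict upper tail", {
  expect_equal(permutation_pvalue(5, c(1, 2, 3, 6)), 0.25)
  expect_equal(permutation_pvalue(7, c(1, 2, 3, 6)), 0)
  expect_equal(permutation_pvalue(0, c(1, 2, 3, 6)), 1)
  expect_equal(permutation_pvalue(5, c(1, 2, 3, 6), conservative = TRUE), 2 / 5)
})

test_that("percentile confidence intervals follow the inf-quantile rule", {
  expect_equal(confidence_interval(1:100), c(low = 3, high = 98))
  expect_warning(ci <- confidence_interval(rep(2, 10)), "resamples")
  expect_equal(unname(ci), c(2, 2))
  withr::with_seed(3, z <- rlnorm(200))
  ci2 <- confidence_interval(z)
  expect_lte(ci2["low"], ci2["high"])
})

test_that("Benjamini-Hochberg adjustment matches hand computation", {
  # spot-check the adjustment convention used for the fdr columns
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  d <- make_toy_data(50, 4, seed = 61)
  ia <- amdr_interactions(d, k = 2, B = 60, B_j = 40, seed = 5)
  expect_equal(ia$por_fdr, p.adjust(ia$por_pvalue, "BH"))
  expect_true(all(ia$por_fdr >= ia$por_pvalue, na.rm = TRUE))
})

test_that("analyze-all returns one calibrated row per pair, sorted", {
  d <- make_toy_data(60, 5, seed = 71)
  ia <- amdr_interactions(d, k = 2, B = 50, B_j = 40, seed = 5)
  expect_s3_class(ia, "amdr_interactions")
  expect_equal(nrow(ia), 10L)
  expect_false(is.unsorted(ia$por_pvalue, na.rm = TRUE))
  expect_true(all(ia$por >= 0 & ia$prr >= 0 & ia$pchi >= 0, na.rm = TRUE))
  expect_true(all(ia$por_ci_low <= ia$por_ci_high, na.rm = TRUE))
  expect_equal(attr(ia, "p0"), mean(d$Class))
  expect_error(amdr_interactions(d, k = 9), "exceeds")
})

test_that("fixed seeds reproduce the full analysis bit for bit", {
  d <- make_toy_data(50, 4, seed = 81)
  ia1 <- amdr_interactions(d, k = 2, B = 40, B_j = 30, seed = 12)
  ia2 <- amdr_interactions(d, k = 2, B = 40, B_j = 30, seed = 12)
  expect_identical(ia1, ia2)
  nul1 <- permutation_null(d, c(1, 2), B = 25, seed = 12)
  nul2 <- permutation_null(d, c(1, 2), B = 25, seed = 12)
  expect_identical(nul1, nul2)
})

test_that("p-values are invariant to subject order and unrelated SNP columns", {
  d <- make_toy_data(40, 4, seed = 91)
  d$id <- sprintf("P%03d", seq_len(nrow(d)))
  ia1 <- amdr_interactions(d, k = 2, B = 40, B_j = 30, seed = 2,
                           id_column = "id")
  withr::with_seed(4, d2 <- d[sample(nrow(d)), ])
  ia2 <- amdr_interactions(d2, k = 2, B = 40, B_j = 30, seed = 2,
                           id_column = "id")
  expect_equal(ia1$por_pvalue, ia2$por_pvalue)
  expect_equal(ia1$pchi, ia2$pchi)
})

test_that("raw null statistics carry the selection bias the calibration removes", {
  d <- make_toy_data(200, 3, seed = 101)
  withr::with_seed(6, d$Class <- sample(rep(0:1, 100)))
  nul <- permutation_null(d, c(1, 2), B = 400, seed = 3)
  # high-risk cells are picked from the same (permuted) data, so even null
  # odds ratios sit above 1 -- the reason the calibrated statistics exist
  expect_gt(median(nul$or), 1)
  expect_gt(median(nul$rr), 1)
  # calibrating each null draw against null/alt CDFs from the same null
  # distribution centres it at 1
  alt <- jackknife_alt(d, c(1, 2), B_j = 200, seed = 3)
  z <- corrected_statistic(nul$or, nul$or, alt$or)
  expect_lt(abs(median(z) - 1), 0.25)
})

test_that("jackknife subsamples honour the fraction and concentrate under signal", {
  d <- make_toy_data(300, 3, seed = 111)
  alt <- jackknife_alt(d, c(1, 2), B_j = 5, fraction = 0.9, seed = 1)
  expect_equal(nrow(alt), 5L)
  # subsample size contract: 270 of 300 subjects
  des <- amdr:::resampling_design(d$Class, B = 1, B_j = 20, fraction = 0.9,
                                  seed = 1)
  expect_true(all(colSums(des$S) == 270))

  withr::with_seed(5, {
    g <- matrix(sample(0:2, 200 * 3, replace = TRUE), 200, 3)
    sig <- as.data.frame(g)
    names(sig) <- paste0("SNP", 1:3)
    sig$Class <- as.integer((g[, 1] + g[, 2]) %% 2 == 1)
  })
  sig <- tibble::as_tibble(sig)
  alt_s <- jackknife_alt(sig, c(1, 2), B_j = 50, seed = 2)
  nul_s <- permutation_null(sig, c(1, 2), B = 50, seed = 2)
  expect_gt(min(alt_s$chi), max(nul_s$chi))
})

test_that("brute-force resampling oracle matches the implementation exactly", {
  d <- make_toy_data(28, 4, seed = 121)
  B <- 40
  seed <- 17
  ia <- amdr_interactions(d, k = 2, B = B, B_j = 30, seed = seed,
                          sort_by = "none")
  for (srow in c(1, 4)) {
    loci <- ia$loci[[srow]]
    o_null <- oracle_null_samples(d, loci, B, seed)
    nul <- permutation_null(d, loci, B = B, seed = seed)
    expect_identical(as.numeric(nul$or), as.numeric(o_null[, "or"]))
    expect_identical(as.numeric(nul$chi), as.numeric(o_null[, "chi"]))

    tb <- oracle_predisposing(d, loci)
    st <- oracle_raw_stats(tb$n11, tb$n12, tb$n21, tb$n22)
    expect_identical(ia$or_raw[srow], st$or)
    expect_identical(ia$chi_raw[srow], st$chi)
    # p-value: strict upper-tail count against the oracle nulls
    expect_identical(ia$por_pvalue[srow],
                     mean(st$or < o_null[, "or"]))
    expect_identical(ia$pchi_pvalue[srow],
                     mean(st$chi < o_null[, "chi"]))
  }
})
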