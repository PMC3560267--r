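test_that("interaction enumeration is lexicographic and complete", {
  e <- enumerate_interactions(5, 2)
  expect_equal(nrow(e), 10L)
  expect_equal(e$loci[[1]], c(1L, 2L))
  expect_equal(e$loci[[10]], c(4L, 5L))
  expect_equal(nrow(enumerate_interactions(34, 2)), choose(34, 2))
  e3 <- enumerate_interactions(3, 3)
  expect_equal(nrow(e3), 1L)
  expect_equal(e3$loci[[1]], 1:3)
  expect_error(enumerate_interactions(3, 4), "k")
  # strictly increasing indices, no duplicates
  expect_true(all(vapply(e$loci, function(l) all(diff(l) > 0), logical(1))))
  expect_false(anyDuplicated(e$interaction) > 0)
})

test_that("cell partition conserves subjects and maps tuples correctly", {
  d <- tibble::tibble(SNP1 = c(0L, 0L, 0L, 0L), SNP2 = c(0L, 0L, 0L, 0L),
                      Class = c(1L, 0L, 1L, 0L))
  ct <- partition_cells(d, c(1, 2))
  expect_equal(ct$X[1], 2)
  expect_equal(ct$Y[1], 2)
  expect_equal(sum(ct$X) + sum(ct$Y), 4)
  expect_true(all(ct$X[-1] == 0 & ct$Y[-1] == 0))

  d2 <- make_toy_data(300, 5, seed = 21)
  ct2 <- partition_cells(d2, c(2, 4))
  expect_equal(sum(ct2$X), sum(d2$Class))
  expect_equal(sum(ct2$Y), sum(1 - d2$Class))
  # encoding agrees with cell_genotypes round-trip
  gt <- cell_genotypes(seq_len(9), 2)
  expect_equal(gt[1, ], c(0L, 0L))
  expect_equal(gt[9, ], c(2L, 2L))
  j <- 1 + gt[, 1] + 3 * gt[, 2]
  expect_equal(j, seq_len(9))
})

test_that("the naive Bayes threshold is the case fraction, spec-independent", {
  d <- make_toy_data(104, 5, seed = 8)
  d$Class <- c(rep(1L, 59), rep(0L, 45))
  th <- vapply(list(c(1, 2), c(2, 5), c(1, 3, 4)), function(l) {
    naive_bayes_threshold(partition_cells(d, l))
  }, numeric(1))
  expect_equal(th, rep(59 / 104, 3))
  expect_equal(round(th[1], 4), 0.5673)
  d$Class <- c(rep(1L, 52), rep(0L, 52))
  expect_equal(naive_bayes_threshold(partition_cells(d, c(1, 2))), 0.5)
})

test_that("the predisposing table implements the indicator sums", {
  ct <- structure(list(X = c(30, 20), Y = c(10, 40), k = 1, loci = 1L),
                  class = "cell_counts")
  tb <- build_predisposing_table(ct, 0.5)
  expect_equal(c(tb$n11, tb$n12, tb$n21, tb$n22), c(30, 10, 20, 40))
  expect_equal(tb$e[1, 1], 40 * 50 / 100)
  expect_equal(tb$high_risk_cells, 1L)
  expect_false(tb$degenerate)

  # a cell exactly at the threshold is low risk
  ct2 <- structure(list(X = c(25, 25), Y = c(25, 25), k = 1, loci = 1L),
                   class = "cell_counts")
  tb2 <- build_predisposing_table(ct2, 0.5)
  expect_equal(tb2$n11, 0)
  expect_true(tb2$degenerate)

  # empty cells are low risk
  ct3 <- structure(list(X = c(10, 0), Y = c(5, 0), k = 1, loci = 1L),
                   class = "cell_counts")
  tb3 <- build_predisposing_table(ct3, 0.5)
  expect_false(2L %in% tb3$high_risk_cells)
})

test_that("table margins always reconcile with the class totals", {
  for (seed in 1:5) {
    d <- make_toy_data(60, 4, seed = seed)
    p0 <- mean(d$Class)
    for (loci in list(c(1, 2), c(2, 3), c(1, 3, 4))) {
      tb <- build_predisposing_table(partition_cells(d, loci), p0)
      expect_equal(tb$n11 + tb$n21, sum(d$Class))
      expect_equal(tb$n12 + tb$n22, sum(1 - d$Class))
      expect_equal(tb$n11 + tb$n12 + tb$n21 + tb$n22, nrow(d))
    }
  }
})

test_that("brute-force enumeration reproduces the predisposing table", {
  for (seed in c(2, 13)) {
    d <- make_toy_data(25, 4, seed = seed)
    p0 <- mean(d$Class)
    for (loci in list(c(1, 2), c(1, 4), c(3, 4))) {
      tb <- build_predisposing_table(partition_cells(d, loci), p0)
      o <- oracle_predisposing(d, loci)
      expect_equal(
        as.numeric(c(tb$n11, tb$n12, tb$n21, tb$n22)),
        as.numeric(c(o$n11, o$n12, o$n21, o$n22)))
      expect_identical(as.integer(tb$high_risk_cells), as.integer(o$high))
    }
  }
})

test_that("original MDR recovers a noiseless parity (XOR-like) signal", {
  withr::with_seed(5, {
    g <- matrix(sample(0:2, 200 * 4, replace = TRUE), 200, 4)
    d <- as.data.frame(g)
    names(d) <- paste0("SNP", 1:4)
    d$Class <- as.integer((g[, 1] + g[, 2]) %% 2 == 1)
  })
  res <- run_original_mdr(tibble::as_tibble(d), k = 2, seed = 3)
  expect_equal(res$interaction, "1:2")
  expect_equal(res$test_accuracy, 1)
  expect_equal(res$cvc, 10L)
})

test_that("original MDR testing accuracy is near chance on pure noise", {
  d <- make_toy_data(200, 4, seed = 31)
  withr::with_seed(17, d$Class <- sample(rep(0:1, 100)))
  res <- run_original_mdr(d, k = 2, seed = 4)
  expect_lt(abs(res$test_accuracy - 0.5), 0.1)
})

test_that("stratified folds balance classes to within one subject", {
  d <- make_toy_data(104, 3, seed = 41)
  d$Class <- c(rep(1L, 59), rep(0L, 45))
  g <- amdr:::as_geno(d)
  fold <- amdr:::make_folds(g$pheno, g$ids, 10, seed = 1)
  for (cls in 0:1) {
    sizes <- table(fold[g$pheno == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(amdr:::make_folds(c(rep(0L, 5), rep(1L, 50)),
                                 sprintf("S%02d", 1:55), 10, 1),
               "per class")
})

test_that("MDR results are invariant to subject row order", {
  d <- make_toy_data(80, 4, seed = 51)
  d$id <- sprintf("P%03d", seq_len(nrow(d)))
  res1 <- run_original_mdr(d, k = 2, permutations = 30, seed = 9,
                           id_column = "id")
  withr::with_seed(1, d2 <- d[sample(nrow(d)), ])
  res2 <- run_original_mdr(d2, k = 2, permutations = 30, seed = 9,
                           id_column = "id")
  expect_equal(res1, res2)
})

test_that("the MDR permutation test behaves at the extremes", {
  withr::with_seed(5, {
    g <- matrix(sample(0:2, 150 * 3, replace = TRUE), 150, 3)
    d <- as.data.frame(g)
    names(d) <- paste0("SNP", 1:3)
    d$Class <- as.integer((g[, 1] + g[, 2]) %% 2 == 1)
  })
  p <- permutation_test_mdr(tibble::as_tibble(d), k = 2, B = 100, seed = 2)
  expect_equal(p, 0)
  expect_error(permutation_test_mdr(tibble::as_tibble(d), B = 0), "B")
})
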