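signal_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(5, {
        # MAF-0.5 HWE genotypes make the parity trait marginal-effect free
        g <- matrix(sample(0:2, 200 * 4, replace = TRUE,
                           prob = c(0.25, 0.5, 0.25)), 200, 4)
        d <- as.data.frame(g)
        names(d) <- paste0("SNP", 1:4)
        d$Class <- as.integer((g[, 1] + g[, 2]) %% 2 == 1)
      })
      d <- tibble::as_tibble(d)
      cache <<- list(data = d,
                     ia = amdr_interactions(d, k = 2, B = 100, B_j = 50,
                                            seed = 3))
    }
    cache
  }
})

test_that("risk scores count high-risk membership over significant pairs", {
  sf <- signal_fit()
  # no significant interaction -> all scores zero
  sc0 <- risk_scores(sf$data, sf$ia, alpha = 0)
  expect_true(all(sc0$score == 0))
  # with the parity pair significant, cases score 1, controls 0
  sc1 <- risk_scores(sf$data, sf$ia, alpha = 0.05)
  expect_true(all(sc1$score[sc1$phenotype == 1] >= 1))
  expect_lte(max(sc1$score), sum(sf$ia$por_pvalue < 0.05))
})

test_that("scores are monotone in the admission threshold", {
  sf <- signal_fit()
  alphas <- c(0.001, 0.01, 0.05)
  mats <- lapply(alphas, function(a) risk_scores(sf$data, sf$ia, a)$score)
  expect_true(all(mats[[1]] <= mats[[2]]))
  expect_true(all(mats[[2]] <= mats[[3]]))
  # bounded by the number of significant interactions
  for (i in seq_along(alphas)) {
    expect_true(all(mats[[i]] <=
                      sum(sf$ia$por_pvalue < alphas[i], na.rm = TRUE)))
  }
})

test_that("AUC follows the rank formula with tie credit", {
  expect_equal(roc_auc(c(0, 1, 2, 3), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(2, 2, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(3, 2, 1, 0), c(0, 0, 1, 1))$auc, 0)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  withr::with_seed(9, {
    s <- sample(0:6, 60, replace = TRUE)
    ph <- sample(rep(0:1, 30))
  })
  expect_equal(roc_auc(s, ph)$auc, oracle_auc(s, ph))
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(s, ph)$auc,
               as.numeric(suppressMessages(
                 pROC::auc(ph, s, direction = "<", levels = c(0, 1)))))
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(10, {
    s <- sample(0:9, 50, replace = TRUE)
    ph <- sample(rep(0:1, 25))
  })
  a1 <- roc_auc(s, ph)$auc
  expect_equal(roc_auc(exp(s), ph)$auc, a1)
  expect_equal(roc_auc(2 * s + 7, ph)$auc, a1)
})

test_that("ROC endpoints span (0,0) to (1,1)", {
  sf <- signal_fit()
  pr <- amdr_risk_profile(sf$data, sf$ia, alpha = 0.05)
  expect_equal(pr$roc$fpr[1], 0)
  expect_equal(pr$roc$tpr[1], 0)
  expect_equal(pr$roc$fpr[nrow(pr$roc)], 1)
  expect_equal(pr$roc$tpr[nrow(pr$roc)], 1)
})

test_that("alpha selection maximises AUC and prefers sparser models", {
  sf <- signal_fit()
  a <- select_alpha(sf$data, sf$ia)
  grid <- attr(a, "grid")
  expect_true(all(grid$auc <= grid$auc[grid$alpha == as.numeric(a)][1]))
  expect_lte(as.numeric(a), 0.05)
  # brute-force scan over a fine grid cannot beat the selected alpha
  fine <- seq(0.0005, 0.05, by = 0.0005)
  fine_auc <- vapply(fine, function(al) {
    roc_auc(risk_scores(sf$data, sf$ia, al))$auc
  }, numeric(1))
  expect_gte(grid$auc[grid$alpha == as.numeric(a)][1], max(fine_auc))
})

test_that("a diluting noise interaction is excluded by alpha selection", {
  sf <- signal_fit()
  ia <- sf$ia
  # construct a two-candidate situation: the parity pair (small p) plus one
  # noise pair forced to p = 0.04 whose high-risk cells are arbitrary
  noise_row <- which.max(ia$por_pvalue)
  ia$por_pvalue[noise_row] <- 0.04
  ia$high_risk_cells[[noise_row]] <- 1:4
  a <- select_alpha(sf$data, ia)
  expect_lt(as.numeric(a), 0.04)
  expect_equal(attr(a, "grid")$n_significant[1], 1L)
})

test_that("alpha is undefined when nothing approaches significance", {
  sf <- signal_fit()
  ia <- sf$ia
  ia$por_pvalue <- pmax(ia$por_pvalue, 0.3)
  expect_warning(a <- select_alpha(sf$data, ia), "undefined|no interaction")
  expect_true(is.na(as.numeric(a)))
  expect_warning(pr <- amdr_risk_profile(sf$data, ia), "no interaction")
  expect_true(all(pr$scores$score == 0))
})

test_that("the classification cutoff maximises accuracy", {
  bc <- best_cutoff(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(bc$cutoff, 0.5)
  expect_equal(bc$accuracy, 1)
  # all-equal scores fall back to the majority class
  bc2 <- best_cutoff(rep(3, 10), c(rep(1, 7), rep(0, 3)))
  expect_equal(bc2$accuracy, 0.7)
  # constructed overlap: exhaustive scan agrees
  s <- c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5)
  ph <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
  bc3 <- best_cutoff(s, ph)
  o <- oracle_best_cutoff(s, ph)
  expect_equal(bc3$accuracy, o$accuracy)
  expect_equal(bc3$accuracy, 0.8)
  expect_equal(bc3$cutoff, 1.5)
})

test_that("the profile object summarises and plots", {
  sf <- signal_fit()
  pr <- amdr_risk_profile(sf$data, sf$ia)
  expect_s3_class(pr, "amdr_profile")
  gl <- glance(pr)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$auc, 0.9)
  td <- tidy(pr)
  expect_equal(nrow(td), nrow(sf$data))
  expect_s3_class(autoplot(pr), "ggplot")
  expect_output(print(pr), "risk profile")
})
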