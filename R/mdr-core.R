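#' Enumerate k-way locus combinations
#'
#' All `choose(M, k)` sets of `k` distinct SNP indices, in lexicographic
#' order with strictly increasing indices.
#'
#' @param M Number of SNPs.
#' @param k Interaction order (`1 <= k <= M`).
#' @return A tibble with list-column `loci` (integer vectors) and an
#'   `interaction` label column (1-based indices joined by `:`).
#' @examples
#' enumerate_interactions(5, 2)
#' @export
enumerate_interactions <- function(M, k) {
  stopifnot(M >= 1)
  if (k < 1 || k > M) abort(sprintf("k must be in [1, %d], got %s", M, k))
  cmb <- combn(M, k)
  tibble::tibble(
    loci = lapply(seq_len(ncol(cmb)), function(i) as.integer(cmb[, i])),
    interaction = apply(cmb, 2, paste, collapse = ":")
  )
}

# Map each subject to one of the 3^k genotype cells of a locus set.
# Cell j (1-based) encodes the genotype tuple in base 3, first locus fastest:
# j = 1 + g1 + 3 g2 + 9 g3 + ...
cell_index_of <- function(geno, loci) {
  k <- length(loci)
  idx <- rep(1L, nrow(geno))
  for (i in seq_len(k)) idx <- idx + geno[, loci[i]] * 3L^(i - 1L)
  idx
}

#' Genotype tuple of a cell index
#'
#' Inverse of the cell encoding used by [partition_cells()]: cell `j` of a
#' k-way interaction corresponds to the genotype tuple returned here.
#'
#' @param j Cell index (1-based, in `1:3^k`), vectorised.
#' @param k Interaction order.
#' @return An integer matrix, `length(j)` rows by `k` columns, entries 0/1/2.
#' @export
cell_genotypes <- function(j, k) {
  stopifnot(all(j >= 1 & j <= 3^k))
  out <- matrix(0L, length(j), k)
  x <- as.integer(j) - 1L
  for (i in seq_len(k)) {
    out[, i] <- x %% 3L
    x <- x %/% 3L
  }
  out
}

#' Partition subjects into the 3^k genotype cells of a locus combination
#'
#' @param data Genotype tibble (see [read_genotype_table()]).
#' @param loci Integer vector of `k` distinct SNP indices (columns, in
#'   genotype-column order).
#' @param class_column,id_column Column naming, as in [amdr_interactions()].
#' @return An object of class `cell_counts`: list with `X` (case counts per
#'   cell), `Y` (control counts), `k`, `loci`, and `cell_index` (per-subject
#'   cell assignment).
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 100, seed = 1)
#' partition_cells(d, c(1, 2))
#' @export
partition_cells <- function(data, loci, class_column = "Class", id_column = NULL) {
  g <- as_geno(data, class_column, id_column)
  loci <- as.integer(loci)
  stopifnot(length(loci) >= 1, !anyDuplicated(loci),
            all(loci >= 1 & loci <= ncol(g$geno)))
  k <- length(loci)
  n_cells <- 3L^k
  cidx <- cell_index_of(g$geno, loci)
  X <- tabulate(cidx[g$pheno == 1L], nbins = n_cells)
  Y <- tabulate(cidx[g$pheno == 0L], nbins = n_cells)
  structure(list(X = X, Y = Y, k = k, loci = loci, cell_index = cidx),
            class = "cell_counts")
}

#' Naive Bayes disease-risk threshold
#'
#' The overall case fraction of the dataset: genotype cells whose case ratio
#' strictly exceeds it are classified as high predisposing risk.  Identical
#' for every locus combination on the same dataset.
#'
#' @param cells A `cell_counts` object, or a genotype tibble.
#' @param ... Passed to [partition_cells()] when `cells` is a tibble.
#' @return The threshold, in (0, 1).
#' @export
naive_bayes_threshold <- function(cells, ...) {
  if (is.data.frame(cells)) cells <- partition_cells(cells, loci = 1L, ...)
  n_case <- sum(cells$X)
  n_ctrl <- sum(cells$Y)
  if (n_case + n_ctrl == 0) abort("empty dataset")
  if (n_case == 0 || n_ctrl == 0) abort("both classes must be present")
  n_case / (n_case + n_ctrl)
}

#' Build the 2x2 predisposing risk table
#'
#' Cross-classifies subjects by high/low predisposing risk (cell case ratio
#' strictly above / at-or-below the threshold) and case/control status.
#' Empty cells (no observed subjects) have ratio 0/0, defined as 0, and are
#' therefore low risk; ties at the threshold are low risk.
#'
#' @param cells A `cell_counts` object from [partition_cells()].
#' @param p0 Threshold in (0, 1), normally [naive_bayes_threshold()].
#' @return An object of class `predisposing_table`: counts `n11` (high-risk
#'   cases), `n12` (high-risk controls), `n21`, `n22`, the threshold `p0`,
#'   expected counts `e` (2x2, row/column margin products over N), the
#'   `high_risk_cells` indices, and a `degenerate` flag (TRUE when a whole
#'   risk stratum is empty).
#' @examples
#' ct <- structure(list(X = c(30, 20), Y = c(10, 40), k = 1, loci = 1L),
#'                 class = "cell_counts")
#' build_predisposing_table(ct, 0.5)
#' @export
build_predisposing_table <- function(cells, p0) {
  stopifnot(inherits(cells, "cell_counts"), p0 > 0, p0 < 1)
  tot <- cells$X + cells$Y
  ratio <- ifelse(tot > 0, cells$X / pmax(tot, 1), 0)
  high <- ratio > p0
  n11 <- sum(cells$X[high]); n12 <- sum(cells$Y[high])
  n21 <- sum(cells$X[!high]); n22 <- sum(cells$Y[!high])
  N <- n11 + n12 + n21 + n22
  rows <- c(n11 + n12, n21 + n22)
  cols <- c(n11 + n21, n12 + n22)
  e <- outer(rows, cols) / N
  dimnames(e) <- list(risk = c("high", "low"), status = c("case", "control"))
  structure(list(
    n11 = n11, n12 = n12, n21 = n21, n22 = n22, p0 = p0, e = e,
    high_risk_cells = which(high),
    degenerate = (n11 + n12 == 0) || (n21 + n22 == 0)
  ), class = "predisposing_table")
}

#' @export
print.predisposing_table <- function(x, ...) {
  cat(sprintf("2x2 predisposing risk table (threshold %.4f%s)\n", x$p0,
              if (x$degenerate) ", degenerate" else ""))
  m <- matrix(c(x$n11, x$n21, x$n12, x$n22), 2, 2,
              dimnames = list(c("high risk", "low risk"), c("case", "control")))
  print(m)
  invisible(x)
}

# Stratified fold assignment, canonicalised by sorted subject id so the
# assignment is invariant to row order.  Errors when a class has fewer
# subjects than folds (a fold would be single-class).
make_folds <- function(pheno, ids, folds, seed) {
  stopifnot(folds >= 2)
  tab <- table(factor(pheno, levels = c(0, 1)))
  if (any(tab < folds)) {
    abort(sprintf("need at least %d subjects per class for %d-fold stratified CV",
                  folds, folds))
  }
  ord <- order(ids)
  fold <- integer(length(pheno))
  with_seed(derive_seed(seed %||% 0L, "folds"), {
    for (cls in c(0L, 1L)) {
      idx <- ord[pheno[ord] == cls]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# Core cross-validated MDR evaluation for one locus set over R phenotype
# columns (column 1 is usually the observed phenotype, the rest permuted).
# P is an N x R 0/1 matrix.  Returns per-fold training/testing accuracy
# matrices (folds x R).
mdr_cv_eval <- function(cidx, fold, P, n_cells) {
  N <- length(cidx)
  folds <- max(fold)
  R <- ncol(P)
  Z <- matrix(0, N, n_cells)
  Z[cbind(seq_len(N), cidx)] <- 1
  Xall <- crossprod(Z, P)                      # n_cells x R case counts
  Tall <- tabulate(cidx, nbins = n_cells)      # fixed cell sizes
  cases_all <- colSums(P)
  train_acc <- matrix(0, folds, R)
  test_acc <- matrix(0, folds, R)
  for (f in seq_len(folds)) {
    in_f <- fold == f
    nf <- sum(in_f)
    Zf <- Z[in_f, , drop = FALSE]
    Xf <- crossprod(Zf, P[in_f, , drop = FALSE])
    Tf <- tabulate(cidx[in_f], nbins = n_cells)
    Xtr <- Xall - Xf
    Ttr <- Tall - Tf
    ntr <- N - nf
    p0 <- (cases_all - colSums(P[in_f, , drop = FALSE])) / ntr
    ratio <- Xtr / ifelse(Ttr > 0, Ttr, 1)
    ratio[Ttr == 0, ] <- 0
    high <- ratio > rep(p0, each = n_cells)
    test_acc[f, ] <- colSums(Xf * high + (Tf - Xf) * !high) / nf
    train_acc[f, ] <- colSums(Xtr * high + (Ttr - Xtr) * !high) / ntr
  }
  list(train = train_acc, test = test_acc)
}

#' Run original multifactor dimensionality reduction
#'
#' Exhaustive search over all k-way locus combinations with stratified
#' 10-fold cross-validation.  Within each training fold, genotype cells are
#' classified high/low risk against the training-fold case fraction; a
#' subject is predicted a case when its cell is high risk.  Following the
#' original MDR convention, the best model per order is the combination
#' selected most often across training folds -- maximal cross-validation
#' consistency (CVC, the number of folds in which the combination is the
#' training-fold winner by training accuracy) -- with ties broken by higher
#' mean testing accuracy, then lexicographically.
#'
#' @param data Genotype tibble.
#' @param k Interaction order(s) to search, e.g. `2` or `1:3`.
#' @param folds Number of CV folds (default 10).
#' @param permutations If `> 0`, also run a permutation test: the phenotype
#'   is reshuffled this many times, the full CV search (including the
#'   CVC-based model selection) re-run on each replicate, and the p-value
#'   is the proportion of permuted selected-model testing accuracies that
#'   reach or exceed the observed one.
#' @param seed Master seed (folds and permutations derive substreams).
#' @param class_column,id_column Column naming.
#' @return A tibble with one row per order: `k`, `loci` (list), the
#'   `interaction` label, `train_accuracy`, `test_accuracy`, `cvc`, `folds`,
#'   and `p_value` (NA unless `permutations > 0`).
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 200, seed = 1)
#' run_original_mdr(d, k = 2, seed = 1)
#' @export
run_original_mdr <- function(data, k = 2, folds = 10, permutations = 0,
                             seed = NULL, class_column = "Class",
                             id_column = NULL) {
  g <- as_geno(data, class_column, id_column)
  stopifnot(all(k >= 1), all(k <= ncol(g$geno)), folds >= 2,
            length(g$pheno) >= folds)
  # canonical subject order: all seeded draws see subjects sorted by id
  ord <- order(g$ids)
  geno <- g$geno[ord, , drop = FALSE]
  pheno <- g$pheno[ord]
  ids <- g$ids[ord]
  fold <- make_folds(pheno, ids, folds, seed)

  P <- matrix(as.numeric(pheno), ncol = 1)
  if (permutations > 0) {
    Pp <- with_seed(derive_seed(seed %||% 0L, "mdr-permutation"), {
      vapply(seq_len(permutations), function(b) sample(as.numeric(pheno)),
             numeric(length(pheno)))
    })
    P <- cbind(P, Pp)
  }

  out <- lapply(sort(unique(as.integer(k))), function(kk) {
    specs <- enumerate_interactions(ncol(geno), kk)
    n_cells <- 3L^kk
    S <- nrow(specs)
    R <- ncol(P)
    mean_test <- matrix(0, S, R)
    train_fold <- array(0, c(folds, S, R))
    train_obs <- numeric(S)
    for (s in seq_len(S)) {
      cidx <- cell_index_of(geno, specs$loci[[s]])
      ev <- mdr_cv_eval(cidx, fold, P, n_cells)
      mean_test[s, ] <- colMeans(ev$test)
      train_fold[, s, ] <- ev$train
      train_obs[s] <- mean(ev$train[, 1])
    }
    # classic selection, applied identically to every phenotype column:
    # per-fold training winner (lexicographically first on ties) -> CVC;
    # best model = max CVC, ties by mean testing accuracy, then index
    select_col <- function(r) {
      winner <- apply(train_fold[, , r, drop = FALSE][, , 1], 1, which.max)
      cvc_all <- tabulate(winner, nbins = S)
      cand <- which(cvc_all == max(cvc_all))
      best <- cand[order(-mean_test[cand, r], cand)][1]
      c(best = best, cvc = cvc_all[best])
    }
    sel <- vapply(seq_len(R), select_col, c(best = 0, cvc = 0))
    best <- sel["best", 1]
    p_val <- NA_real_
    if (permutations > 0) {
      stat_perm <- mean_test[cbind(sel["best", -1], seq_len(R)[-1])]
      p_val <- mean(stat_perm >= mean_test[best, 1])
    }
    tibble::tibble(
      k = kk, loci = specs$loci[best], interaction = specs$interaction[best],
      train_accuracy = train_obs[best], test_accuracy = mean_test[best, 1],
      cvc = as.integer(sel["cvc", 1]), folds = folds, p_value = p_val
    )
  })
  dplyr::bind_rows(out)
}

#' Permutation test for the best original-MDR model
#'
#' Convenience wrapper around [run_original_mdr()] that returns just the
#' permutation p-value for one interaction order.
#'
#' @inheritParams run_original_mdr
#' @param B Number of phenotype permutations (`>= 1`).
#' @return The p-value: proportion of permuted replicates whose best mean
#'   testing accuracy is at least the observed best.
#' @export
permutation_test_mdr <- function(data, k = 2, folds = 10, B = 1000,
                                 seed = NULL, class_column = "Class",
                                 id_column = NULL) {
  if (B < 1) abort("B must be >= 1")
  res <- run_original_mdr(data, k = k, folds = folds, permutations = B,
                          seed = seed, class_column = class_column,
                          id_column = id_column)
  res$p_value[1]
}
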