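# Independent brute-force oracles: explicit loops, no shared code with the
# package internals beyond the public seed-derivation contract.

# Small random genotype dataset with both classes guaranteed.
make_toy_data <- function(n, m, seed, maf = 0.3) {
  withr::with_seed(seed, {
    probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    g <- matrix(sample(0:2, n * m, replace = TRUE, prob = probs), n, m)
    ph <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    d <- as.data.frame(g)
    names(d) <- paste0("SNP", seq_len(m))
    d$Class <- ph
    tibble::as_tibble(d)
  })
}

# Cell partition + predisposing table by explicit subject loops.
oracle_predisposing <- function(data, loci, p0 = NULL) {
  geno <- as.matrix(data[setdiff(names(data), "Class")])
  ph <- data$Class
  k <- length(loci)
  n_cells <- 3^k
  X <- Y <- rep(0, n_cells)
  for (i in seq_len(nrow(geno))) {
    j <- 1
    for (a in seq_len(k)) j <- j + geno[i, loci[a]] * 3^(a - 1)
    if (ph[i] == 1) X[j] <- X[j] + 1 else Y[j] <- Y[j] + 1
  }
  if (is.null(p0)) p0 <- sum(X) / (sum(X) + sum(Y))
  n11 <- n12 <- n21 <- n22 <- 0
  high <- integer(0)
  for (j in seq_len(n_cells)) {
    tot <- X[j] + Y[j]
    ratio <- if (tot == 0) 0 else X[j] / tot
    if (ratio > p0) {
      n11 <- n11 + X[j]; n12 <- n12 + Y[j]; high <- c(high, j)
    } else {
      n21 <- n21 + X[j]; n22 <- n22 + Y[j]
    }
  }
  list(X = X, Y = Y, p0 = p0, n11 = n11, n12 = n12, n21 = n21, n22 = n22,
       high = high)
}

# Raw statistics of one table, replicating the documented conventions.
oracle_raw_stats <- function(n11, n12, n21, n22) {
  zero <- n11 == 0 || n12 == 0 || n21 == 0 || n22 == 0
  a <- n11 + 0.5 * zero; b <- n12 + 0.5 * zero
  cc <- n21 + 0.5 * zero; d <- n22 + 0.5 * zero
  or <- a * d / (b * cc)
  rr <- (a / (a + b)) / (cc / (cc + d))
  N <- n11 + n12 + n21 + n22
  chi <- 0
  obs <- c(n11, n12, n21, n22)
  rows <- c(n11 + n12, n11 + n12, n21 + n22, n21 + n22)
  cols <- c(n11 + n21, n12 + n22, n11 + n21, n12 + n22)
  for (i in 1:4) {
    e <- rows[i] * cols[i] / N
    if (e > 0) chi <- chi + (obs[i] - e)^2 / e
  }
  list(or = or, rr = rr, chi = chi)
}

# The exact permutation matrix the package draws for a given master seed.
oracle_permutations <- function(pheno, B, seed) {
  out <- matrix(0, length(pheno), B)
  withr::with_seed(amdr::derive_seed(seed, "permutation"), {
    for (b in seq_len(B)) out[, b] <- sample(as.numeric(pheno))
  })
  out
}

# Null raw-statistic samples for one locus set by explicit loops.
oracle_null_samples <- function(data, loci, B, seed) {
  P <- oracle_permutations(data$Class, B, seed)
  p0 <- mean(data$Class)
  out <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    d2 <- data
    d2$Class <- as.integer(P[, b])
    tb <- oracle_predisposing(d2, loci, p0 = p0)
    st <- oracle_raw_stats(tb$n11, tb$n12, tb$n21, tb$n22)
    out[b, ] <- c(st$or, st$rr, st$chi)
  }
  colnames(out) <- c("or", "rr", "chi")
  out
}

oracle_ecdf <- function(samples, x) {
  n <- 0
  for (s in samples) if (s <= x) n <- n + 1
  n / length(samples)
}

oracle_quantile <- function(samples, p) {
  s <- sort(samples)
  for (v in s) {
    if (oracle_ecdf(samples, v) >= p) return(v)
  }
  s[length(s)]
}

oracle_corrected <- function(x, null_samples, alt_samples) {
  q <- oracle_quantile(null_samples, oracle_ecdf(alt_samples, x))
  if (q <= 0) {
    pos <- null_samples[null_samples > 0]
    q <- min(pos)
  }
  x / q
}

# Rank-formula AUC by explicit pair counting with 0.5 tie credit.
oracle_auc <- function(scores, pheno) {
  cases <- scores[pheno == 1]
  ctrls <- scores[pheno == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(ctrls))
}

# Exhaustive accuracy scan over a fine cutoff grid.
oracle_best_cutoff <- function(scores, pheno) {
  cand <- sort(unique(c(scores - 0.5, scores + 0.5,
                        (head(sort(unique(scores)), -1) +
                         tail(sort(unique(scores)), -1)) / 2)))
  best_acc <- -1; best_cut <- NA
  for (ct in cand) {
    acc <- mean((scores > ct) == (pheno == 1))
    if (acc > best_acc) { best_acc <- acc; best_cut <- ct }
  }
  list(cutoff = best_cut, accuracy = best_acc)
}
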