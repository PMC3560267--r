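# Vectorised raw association statistics of 2x2 predisposing tables.
# Inputs are parallel vectors of counts (one element per resample).
# OR and RR receive the Haldane-Anscombe +0.5 continuity correction in all
# four cells whenever any cell is zero, keeping resampled statistics finite
# so the empirical CDFs are well defined.  Chi uses the raw counts, with
# terms whose expected count is 0 contributing 0.
stats_from_tables <- function(n11, n12, n21, n22) {
  zero <- n11 == 0 | n12 == 0 | n21 == 0 | n22 == 0
  a <- n11 + 0.5 * zero
  b <- n12 + 0.5 * zero
  cc <- n21 + 0.5 * zero
  d <- n22 + 0.5 * zero
  or <- a * d / (b * cc)
  rr <- (a / (a + b)) / (cc / (cc + d))
  N <- n11 + n12 + n21 + n22
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  term <- function(n, e) ifelse(e > 0, (n - e)^2 / e, 0)
  chi <- term(n11, r1 * c1 / N) + term(n12, r1 * c2 / N) +
    term(n21, r2 * c1 / N) + term(n22, r2 * c2 / N)
  list(or = or, rr = rr, chi = chi)
}

# Collapse per-cell case counts into 2x2 predisposing tables, vectorised
# over resamples.  Xc: cells x R case counts; Tc: cell totals (vector, or
# cells x R matrix for subsamples); p0: threshold (scalar, or length R).
# Empty cells have ratio 0 and fall in the low-risk stratum; ties at the
# threshold are low risk.
predisposing_vec <- function(Xc, Tc, p0) {
  n_cells <- nrow(Xc)
  TcM <- if (is.matrix(Tc)) Tc else matrix(Tc, n_cells, ncol(Xc))
  ratio <- Xc / ifelse(TcM > 0, TcM, 1)
  ratio[TcM == 0] <- 0
  high <- ratio > rep(p0, each = if (length(p0) > 1) n_cells else length(ratio))
  n11 <- colSums(Xc * high)
  n12 <- colSums((TcM - Xc) * high)
  list(n11 = n11, n12 = n12,
       n21 = colSums(Xc) - n11, n22 = colSums(TcM - Xc) - n12)
}

#' Raw odds ratio, relative risk and chi-square of a predisposing table
#'
#' The uncorrected numerators of the calibrated statistics: OR =
#' n11 n22 / (n12 n21), RR = (n11/(n11+n12)) / (n21/(n21+n22)), and the
#' 2x2 chi-square sum over (observed - expected)^2 / expected.  When any
#' cell is 0, OR and RR use the Haldane-Anscombe +0.5 correction in all
#' four cells; chi-square terms with expected count 0 contribute 0.
#'
#' @param table A `predisposing_table` from [build_predisposing_table()].
#' @return A named list `or`, `rr`, `chi` (all `NA` for a degenerate table,
#'   i.e. one with an empty risk stratum).
#' @examples
#' ct <- structure(list(X = c(20, 10), Y = c(10, 20), k = 1, loci = 1L),
#'                 class = "cell_counts")
#' raw_statistics(build_predisposing_table(ct, 0.5))
#' @export
raw_statistics <- function(table) {
  stopifnot(inherits(table, "predisposing_table"))
  if (table$degenerate) return(list(or = NA_real_, rr = NA_real_, chi = NA_real_))
  stats_from_tables(table$n11, table$n12, table$n21, table$n22)
}

# Draw the shared resampling design for one dataset: a phenotype permutation
# matrix (N x B) and a jackknife inclusion matrix (N x B_j, each column a
# without-replacement subsample of round(fraction * N) subjects retaining
# both classes; degenerate draws are retried up to 100 times).
resampling_design <- function(pheno, B, B_j, fraction, seed) {
  N <- length(pheno)
  P <- with_seed(derive_seed(seed %||% 0L, "permutation"), {
    vapply(seq_len(B), function(b) sample(as.numeric(pheno)), numeric(N))
  })
  m <- round(fraction * N)
  stopifnot(m >= 2)
  S <- with_seed(derive_seed(seed %||% 0L, "jackknife"), {
    vapply(seq_len(B_j), function(b) {
      for (try in seq_len(100L)) {
        pick <- sample.int(N, m)
        if (length(unique(pheno[pick])) == 2L) {
          col <- numeric(N); col[pick] <- 1
          return(col)
        }
      }
      abort("could not draw a jackknife subsample containing both classes")
    }, numeric(N))
  })
  list(P = P, S = S)
}

#' Null-distribution samples of the raw statistics by phenotype permutation
#'
#' Estimates the null CDF F0 of OR/RR/Chi for one locus combination by
#' reshuffling the phenotype while keeping each subject's SNP vector intact.
#' The risk threshold and the high/low cell classification are recomputed
#' per permutation (the threshold is invariant: the case count is
#' preserved).
#'
#' @param data Genotype tibble.
#' @param loci Integer vector of SNP indices.
#' @param B Number of permutations (`>= 1`).
#' @param seed Master seed (substream `"permutation"`).
#' @param fraction Unused here; present for interface symmetry.
#' @param class_column,id_column Column naming.
#' @return A tibble with `B` rows and columns `or`, `rr`, `chi`.
#' @export
permutation_null <- function(data, loci, B = 1000, seed = NULL,
                             fraction = 0.9, class_column = "Class",
                             id_column = NULL) {
  if (B < 1) abort("B must be >= 1")
  g <- canonical_geno(data, class_column, id_column)
  des <- resampling_design(g$pheno, B = B, B_j = 1, fraction = fraction, seed = seed)
  spec_resamples(g, as.integer(loci), des)$null
}

#' Alternative-distribution samples of the raw statistics by jackknife
#'
#' Estimates the alternative CDF F of OR/RR/Chi for one locus combination
#' from random subsamples of the data (default 90% of subjects, without
#' replacement), keeping each subject's SNP-phenotype vector intact so the
#' association is preserved.  Threshold and cell classification are
#' recomputed per subsample.
#'
#' @inheritParams permutation_null
#' @param B_j Number of jackknife subsamples (`>= 1`).
#' @param fraction Subsample proportion; the conventional range is 0.8-0.9.
#' @return A tibble with `B_j` rows and columns `or`, `rr`, `chi`.
#' @export
jackknife_alt <- function(data, loci, B_j = 200, fraction = 0.9, seed = NULL,
                          class_column = "Class", id_column = NULL) {
  if (B_j < 1) abort("B_j must be >= 1")
  g <- canonical_geno(data, class_column, id_column)
  des <- resampling_design(g$pheno, B = 1, B_j = B_j, fraction = fraction, seed = seed)
  spec_resamples(g, as.integer(loci), des)$alt
}

# Reorder a dataset into canonical (sorted subject id) order so that every
# seeded draw is invariant to the caller's row order.
canonical_geno <- function(data, class_column = "Class", id_column = NULL) {
  g <- as_geno(data, class_column, id_column)
  ord <- order(g$ids)
  list(geno = g$geno[ord, , drop = FALSE], pheno = g$pheno[ord],
       snps = g$snps, ids = g$ids[ord], unorder = order(ord))
}

# Observed table plus null/alt raw-statistic samples for one locus set,
# given a shared resampling design.
spec_resamples <- function(g, loci, des) {
  n_cells <- 3L^length(loci)
  N <- nrow(g$geno)
  cidx <- cell_index_of(g$geno, loci)
  Z <- matrix(0, N, n_cells)
  Z[cbind(seq_len(N), cidx)] <- 1
  Tall <- tabulate(cidx, nbins = n_cells)
  p0 <- mean(g$pheno)

  W <- cbind(des$P, g$pheno * des$S, des$S)
  M <- crossprod(Z, W)
  B <- ncol(des$P); B_j <- ncol(des$S)
  Xp <- M[, seq_len(B), drop = FALSE]
  Xj <- M[, B + seq_len(B_j), drop = FALSE]
  Tj <- M[, B + B_j + seq_len(B_j), drop = FALSE]

  tb_null <- predisposing_vec(Xp, Tall, p0)
  p0j <- colSums(g$pheno * des$S) / colSums(des$S)
  tb_alt <- predisposing_vec(Xj, Tj, p0j)

  obs_cells <- structure(
    list(X = tabulate(cidx[g$pheno == 1L], nbins = n_cells),
         Y = tabulate(cidx[g$pheno == 0L], nbins = n_cells),
         k = length(loci), loci = loci, cell_index = cidx),
    class = "cell_counts")
  table <- build_predisposing_table(obs_cells, p0)

  list(
    table = table,
    obs = raw_statistics(table),
    null = tibble::as_tibble(stats_from_tables(tb_null$n11, tb_null$n12,
                                               tb_null$n21, tb_null$n22)),
    alt = tibble::as_tibble(stats_from_tables(tb_alt$n11, tb_alt$n12,
                                              tb_alt$n21, tb_alt$n22)),
    cidx = cidx
  )
}

#' Calibrate a raw statistic against its null and alternative CDFs
#'
#' The calibrated statistic is `x / F0^{-1}(F(x))`: the raw value divided by
#' the null-distribution quantile matching its rank under the alternative
#' distribution.  Under the null hypothesis F and F0 coincide, so the
#' calibrated value centres at 1.  F is the order-statistic empirical CDF of
#' `alt_samples` (jackknife), F0^{-1} the order-statistic inverse CDF of
#' `null_samples` (permutation).  When the matched null quantile is not
#' positive (e.g. `F(x) = 0`), the denominator is clamped to the smallest
#' positive null sample.
#'
#' @param x Raw statistic value(s); vectorised.
#' @param null_samples Numeric vector of null-distribution samples.
#' @param alt_samples Numeric vector of alternative-distribution samples.
#' @return Calibrated value(s), same length as `x`.
#' @export
corrected_statistic <- function(x, null_samples, alt_samples) {
  stopifnot(length(null_samples) >= 1, length(alt_samples) >= 1)
  Fx <- ecdf_value(alt_samples, x)
  q <- quantile_inf(null_samples, Fx)
  if (any(q <= 0, na.rm = TRUE)) {
    pos <- null_samples[null_samples > 0]
    q[q <= 0] <- if (length(pos)) min(pos) else NA_real_
  }
  x / q
}

#' Permutation p-value of a calibrated statistic
#'
#' `p = B^{-1} * #\{i : z < z_i\}`: the strict upper-tail proportion of the
#' permutation reference values that exceed the observed calibrated
#' statistic.
#'
#' @param z Observed calibrated statistic.
#' @param z_perm Calibrated statistics of the `B` phenotype permutations.
#' @param conservative If `TRUE`, use the add-one variant
#'   `(1 + #\{z < z_i\}) / (B + 1)`, which can never be exactly 0.
#' @return The p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(z, z_perm, conservative = FALSE) {
  if (!length(z_perm)) abort("z_perm must be non-empty")
  hits <- sum(z < z_perm)
  if (conservative) (1 + hits) / (length(z_perm) + 1) else hits / length(z_perm)
}

#' Percentile confidence interval from resampled calibrated statistics
#'
#' The 2.5th and 97.5th order-statistic percentiles of the resampled
#' values.  Because the interval describes the resampling distribution of
#' the calibrated statistic, it is not guaranteed to bracket the observed
#' point estimate, only `low <= high`.
#'
#' @param z_resamples Calibrated statistics from jackknife (default) or
#'   permutation resamples.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
confidence_interval <- function(z_resamples, level = 0.95) {
  stopifnot(length(z_resamples) >= 1)
  if (length(z_resamples) < 40) {
    warn("fewer than 40 resamples: percentile CI will be coarse")
  }
  a <- (1 - level) / 2
  c(low = quantile_inf(z_resamples, a),
    high = quantile_inf(z_resamples, 1 - a))
}

#' Analyse all k-way interactions of a dataset
#'
#' The detection stage: for every combination of `k` SNPs, builds the
#' predisposing risk table, computes the raw OR/RR/Chi, calibrates them into
#' pOR/pRR/pChi via permutation-estimated null CDFs and jackknife-estimated
#' alternative CDFs, and reports permutation p-values, 95% resampling
#' confidence intervals (percentile intervals of the calibrated resamples,
#' centred on the observed statistic and scaled by `sqrt(f/(1-f))` to undo
#' the reduced spread of f-fraction subsamples, so that null interactions'
#' intervals cross 1 at close to nominal rate) and Benjamini-Hochberg
#' FDR-adjusted p-values (computed across all `choose(M, k)` tests,
#' separately per statistic).
#' One shared permutation and jackknife design is used for the whole
#' dataset.  Interactions whose predisposing table is degenerate (an empty
#' risk stratum) are flagged and carry `NA` statistics.
#'
#' @param data Genotype tibble (see [read_genotype_table()]).
#' @param k Interaction order, default 2.
#' @param B Number of phenotype permutations (null CDF and p-values).
#' @param B_j Number of jackknife subsamples (alternative CDF and CIs).
#' @param fraction Jackknife subsample proportion (conventionally 0.8-0.9).
#' @param seed Master seed; permutation and jackknife draws use named
#'   substreams, and subjects are canonicalised by id so results are
#'   invariant to row order.
#' @param ci_source `"jackknife"` (default) or `"permutation"`: which
#'   resamples feed the percentile CIs.
#' @param sort_by Order of the output rows: by the permutation p-value of
#'   one statistic, or `"none"` for enumeration order.
#' @param class_column,id_column Column naming.
#' @return A tibble of class `amdr_interactions`, one row per combination:
#'   `interaction`, `loci` (list-column), observed counts `n11..n22`,
#'   `or_raw`/`rr_raw`/`chi_raw`, calibrated `por`/`prr`/`pchi` with
#'   `*_ci_low`/`*_ci_high`, `*_pvalue`, `*_fdr`, a `degenerate` flag and
#'   the `high_risk_cells` list-column.  Attributes: `p0`, `k`, `B`, `B_j`,
#'   `fraction`, `snp_labels`.
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 200, seed = 1)
#' amdr_interactions(d, k = 2, B = 100, B_j = 50, seed = 1)
#' @export
amdr_interactions <- function(data, k = 2, B = 1000, B_j = 200,
                              fraction = 0.9, seed = NULL,
                              ci_source = c("jackknife", "permutation"),
                              sort_by = c("pOR", "pRR", "pChi", "none"),
                              class_column = "Class", id_column = NULL) {
  ci_source <- match.arg(ci_source)
  sort_by <- match.arg(sort_by)
  if (B < 1 || B_j < 1) abort("B and B_j must be >= 1")
  g <- canonical_geno(data, class_column, id_column)
  M <- ncol(g$geno)
  if (k > M) abort(sprintf("k = %d exceeds the number of SNPs (%d)", k, M))
  specs <- enumerate_interactions(M, k)
  des <- resampling_design(g$pheno, B, B_j, fraction, seed)
  p0 <- mean(g$pheno)

  rows <- purrr::map(seq_len(nrow(specs)), function(s) {
    loci <- specs$loci[[s]]
    rs <- spec_resamples(g, loci, des)
    one_stat <- function(name) {
      x_obs <- rs$obs[[name]]
      nul <- rs$null[[name]]
      alt <- rs$alt[[name]]
      if (is.na(x_obs)) {
        return(list(z = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_)))
      }
      z <- corrected_statistic(x_obs, nul, alt)
      # The permutation p-value is computed on the raw-statistic scale.
      # The calibration x -> x / F0^{-1}(F(x)) holds F and F0 fixed, so
      # wherever it is increasing the two scales give identical strict
      # upper-tail counts; comparing raw values avoids the denominator
      # clamp turning small permuted statistics into huge calibrated ones.
      p <- permutation_pvalue(x_obs, nul)
      # Percentile CI of the calibrated statistic.  Jackknife deviations are
      # centred on the observed value and inflated by sqrt(f/(1-f)) -- the
      # m-out-of-n subsampling scale-up; an f = 0.9 subsample explores only
      # ~1/3 of the full sampling spread, and the raw percentile band
      # undercovers badly (about 68% instead of 95% under the null).
      if (ci_source == "jackknife") {
        z_res <- corrected_statistic(alt, nul, alt)
        s <- sqrt(fraction / (1 - fraction))
      } else {
        z_res <- corrected_statistic(nul, nul, alt)
        s <- 1
      }
      ci <- unname(suppressWarnings(
        confidence_interval(pmax(z + s * (z_res - z), 0))))
      list(z = z, p = p, ci = ci)
    }
    o <- one_stat("or"); r <- one_stat("rr"); h <- one_stat("chi")
    tibble::tibble(
      interaction = paste(g$snps[loci], collapse = ":"),
      loci = list(loci),
      n11 = rs$table$n11, n12 = rs$table$n12,
      n21 = rs$table$n21, n22 = rs$table$n22,
      or_raw = rs$obs$or, rr_raw = rs$obs$rr, chi_raw = rs$obs$chi,
      por = o$z, por_ci_low = o$ci[1], por_ci_high = o$ci[2], por_pvalue = o$p,
      prr = r$z, prr_ci_low = r$ci[1], prr_ci_high = r$ci[2], prr_pvalue = r$p,
      pchi = h$z, pchi_ci_low = h$ci[1], pchi_ci_high = h$ci[2], pchi_pvalue = h$p,
      degenerate = rs$table$degenerate,
      high_risk_cells = list(rs$table$high_risk_cells)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$por_fdr <- p.adjust(out$por_pvalue, method = "BH")
  out$prr_fdr <- p.adjust(out$prr_pvalue, method = "BH")
  out$pchi_fdr <- p.adjust(out$pchi_pvalue, method = "BH")
  if (sort_by != "none") {
    key <- switch(sort_by, pOR = out$por_pvalue, pRR = out$prr_pvalue,
                  pChi = out$pchi_pvalue)
    out <- out[order(key, out$interaction, na.last = TRUE), ]
  }
  structure(out,
            p0 = p0, k = k, B = B, B_j = B_j, fraction = fraction,
            snp_labels = g$snps,
            class = c("amdr_interactions", class(out)))
}

# Column-name triplet for one statistic choice.
stat_columns <- function(statistic = c("pOR", "pRR", "pChi")) {
  statistic <- match.arg(statistic)
  pre <- switch(statistic, pOR = "por", pRR = "prr", pChi = "pchi")
  list(value = pre, pvalue = paste0(pre, "_pvalue"), fdr = paste0(pre, "_fdr"))
}
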