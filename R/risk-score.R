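#' Epistasis-enriched risk scores
#'
#' For each subject, counts the significant interactions (permutation
#' p-value strictly below `alpha` for the chosen statistic) in which the
#' subject's genotype combination falls in a high-risk cell.  Genotype
#' combinations never observed in the analysis data have no high-risk
#' label and contribute 0.
#'
#' @param data Genotype tibble the `results` were computed on (or new
#'   subjects with the same SNP columns).
#' @param results An `amdr_interactions` tibble.
#' @param alpha Significance threshold; interactions with p-value `< alpha`
#'   (strict) contribute.
#' @param statistic Which calibrated statistic's p-value gates inclusion.
#' @param class_column,id_column Column naming.
#' @return A tibble `subject_id`, `score` (integer), `phenotype`, in the
#'   input row order.
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 200, seed = 1)
#' ia <- amdr_interactions(d, B = 100, B_j = 50, seed = 1)
#' risk_scores(d, ia, alpha = 0.05)
#' @export
risk_scores <- function(data, results, alpha,
                        statistic = c("pOR", "pRR", "pChi"),
                        class_column = "Class", id_column = NULL) {
  stopifnot(inherits(results, "amdr_interactions"))
  cols <- stat_columns(match.arg(statistic))
  g <- as_geno(data, class_column, id_column)
  pv <- results[[cols$pvalue]]
  sig <- which(!is.na(pv) & pv < alpha)
  score <- integer(length(g$pheno))
  for (s in sig) {
    cidx <- cell_index_of(g$geno, results$loci[[s]])
    score <- score + (cidx %in% results$high_risk_cells[[s]])
  }
  tibble::tibble(subject_id = g$ids, score = as.integer(score),
                 phenotype = g$pheno)
}

#' ROC curve and AUC of a score against a binary phenotype
#'
#' AUC is computed by the rank (concordance) formula with 0.5 credit for
#' ties; ROC points come from all distinct score thresholds (predict case
#' when `score > threshold`).
#'
#' @param scores Numeric vector, higher = more case-like. May also be the
#'   tibble returned by [risk_scores()], in which case `phenotype` is taken
#'   from it.
#' @param phenotype 0/1 vector; both classes must be present.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`, descending
#'   thresholds from `Inf`) and `auc`.
#' @examples
#' roc_auc(c(0, 1, 2, 3), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, phenotype = NULL) {
  if (is.data.frame(scores)) {
    phenotype <- scores$phenotype
    scores <- scores$score
  }
  stopifnot(length(scores) == length(phenotype))
  n1 <- sum(phenotype == 1); n0 <- sum(phenotype == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[phenotype == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = ths,
    tpr = vapply(ths, function(t) mean(scores[phenotype == 1] >= t), numeric(1)),
    fpr = vapply(ths, function(t) mean(scores[phenotype == 0] >= t), numeric(1))
  )
  list(roc = roc, auc = auc)
}

# Candidate alpha grid from observed p-values: for each distinct p <= 0.05
# the smallest threshold that admits it under the strict "<" rule, i.e. a
# boundary nudged just past p (capped at 0.05).
alpha_candidates <- function(pvalues, cap = 0.05) {
  p <- sort(unique(pvalues[!is.na(pvalues) & pvalues < cap]))
  if (!length(p)) return(numeric(0))
  upper <- c(p[-1], cap)
  pmin((p + upper) / 2, cap)
}

#' Select the significance threshold maximising risk-score AUC
#'
#' Scans a grid of candidate thresholds in `[0, 0.05]` (by default, one
#' boundary just past each distinct observed p-value below 0.05, so every
#' realisable set of significant interactions is tried), computes the risk
#' scores and their AUC at each, and returns the threshold with maximal
#' AUC.  Ties are broken toward the smallest threshold (fewest
#' interactions), favouring the strongest interactions over diluting the
#' score with weak ones.
#'
#' @inheritParams risk_scores
#' @param grid Optional explicit candidate thresholds.
#' @return The selected threshold, with attribute `"grid"`: a tibble of
#'   `alpha`, `n_significant`, `auc` for every candidate.  `NA` (with a
#'   warning) when no p-value is below 0.05.
#' @export
select_alpha <- function(data, results, grid = NULL,
                         statistic = c("pOR", "pRR", "pChi"),
                         class_column = "Class", id_column = NULL) {
  stopifnot(inherits(results, "amdr_interactions"), nrow(results) > 0)
  statistic <- match.arg(statistic)
  cols <- stat_columns(statistic)
  if (is.null(grid)) grid <- alpha_candidates(results[[cols$pvalue]])
  if (!length(grid)) {
    warn("no interaction has p-value < 0.05; alpha is undefined")
    return(structure(NA_real_, grid = tibble::tibble(
      alpha = numeric(0), n_significant = integer(0), auc = numeric(0))))
  }
  stopifnot(all(grid >= 0 & grid <= 0.05))
  grid <- sort(unique(grid))
  scan <- purrr::map_dfr(grid, function(a) {
    sc <- risk_scores(data, results, alpha = a, statistic = statistic,
                      class_column = class_column, id_column = id_column)
    tibble::tibble(alpha = a,
                   n_significant = sum(results[[cols$pvalue]] < a, na.rm = TRUE),
                   auc = roc_auc(sc$score, sc$phenotype)$auc)
  })
  best <- scan$alpha[which.max(scan$auc)]  # which.max takes the first (smallest)
  structure(best, grid = scan)
}

#' Accuracy-maximising classification cutoff for a score
#'
#' Scans all midpoints between adjacent distinct scores (plus one boundary
#' below the minimum and one above the maximum) and returns the cutoff with
#' the highest overall classification accuracy for the rule
#' `score > cutoff` predicts case.  Ties go to the lower cutoff.
#'
#' @inheritParams roc_auc
#' @return A list `cutoff`, `accuracy`.
#' @examples
#' best_cutoff(c(0, 0, 1, 1), c(0, 0, 1, 1))
#' @export
best_cutoff <- function(scores, phenotype = NULL) {
  if (is.data.frame(scores)) {
    phenotype <- scores$phenotype
    scores <- scores$score
  }
  if (!sum(phenotype == 1) || !sum(phenotype == 0)) {
    abort("both classes must be present")
  }
  u <- sort(unique(scores))
  cuts <- c(u[1] - 0.5, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 0.5)
  acc <- vapply(cuts, function(ct) mean((scores > ct) == (phenotype == 1)),
                numeric(1))
  best <- which.max(acc)  # first index = lowest cutoff on ties
  list(cutoff = cuts[best], accuracy = acc[best])
}

#' Build the aggregated risk-score profile
#'
#' Runs the aggregation stage end to end: selects the significance
#' threshold by AUC maximisation (unless `alpha` is given), computes the
#' epistasis-enriched risk scores, the ROC curve and AUC, and the
#' accuracy-maximising classification cutoff.  All quantities are evaluated
#' in-sample on the analysis dataset.
#'
#' @inheritParams select_alpha
#' @param alpha Optional fixed threshold in `[0, 0.05]`; `NULL` (default)
#'   selects it by AUC maximisation.
#' @return An object of class `amdr_profile`: a list with `scores` (tibble
#'   `subject_id`, `score`, `phenotype`), `alpha_hat`, `statistic`,
#'   `n_significant`, `roc`, `auc`, `cutoff`, `accuracy`, `alpha_grid`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
amdr_risk_profile <- function(data, results, alpha = NULL,
                              statistic = c("pOR", "pRR", "pChi"),
                              grid = NULL, class_column = "Class",
                              id_column = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(alpha)) {
    alpha <- select_alpha(data, results, grid = grid, statistic = statistic,
                          class_column = class_column, id_column = id_column)
  }
  alpha_grid <- attr(alpha, "grid")
  alpha <- as.numeric(alpha)
  cols <- stat_columns(statistic)
  if (is.na(alpha)) {
    g <- as_geno(data, class_column, id_column)
    sc <- tibble::tibble(subject_id = g$ids, score = 0L, phenotype = g$pheno)
    n_sig <- 0L
  } else {
    sc <- risk_scores(data, results, alpha = alpha, statistic = statistic,
                      class_column = class_column, id_column = id_column)
    n_sig <- sum(results[[cols$pvalue]] < alpha, na.rm = TRUE)
  }
  ra <- roc_auc(sc$score, sc$phenotype)
  bc <- best_cutoff(sc$score, sc$phenotype)
  structure(list(
    scores = sc, alpha_hat = alpha, statistic = statistic,
    n_significant = n_sig, roc = ra$roc, auc = ra$auc,
    cutoff = bc$cutoff, accuracy = bc$accuracy, alpha_grid = alpha_grid
  ), class = "amdr_profile")
}

#' @export
print.amdr_profile <- function(x, ...) {
  cat(sprintf(
    "Epistasis-enriched risk profile (%s, alpha-hat = %s)\n  %d significant interaction(s); scores in [%d, %d]\n  AUC = %.3f; accuracy %.3f at score cutoff %.1f\n",
    x$statistic, format(x$alpha_hat, digits = 3), x$n_significant,
    min(x$scores$score), max(x$scores$score), x$auc, x$accuracy, x$cutoff))
  invisible(x)
}

#' @rdname amdr_risk_profile
#' @param x An `amdr_profile` object.
#' @param ... Unused.
#' @export
tidy.amdr_profile <- function(x, ...) x$scores

#' @rdname amdr_risk_profile
#' @export
glance.amdr_profile <- function(x, ...) {
  tibble::tibble(alpha_hat = x$alpha_hat, statistic = x$statistic,
                 n_significant = x$n_significant, auc = x$auc,
                 cutoff = x$cutoff, accuracy = x$accuracy)
}

#' @rdname amdr_risk_profile
#' @param object An `amdr_profile` object.
#' @export
autoplot.amdr_profile <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Epistasis-enriched risk score ROC (AUC = %.2f)",
                      object$auc)) +
    ggplot2::theme_minimal()
}
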