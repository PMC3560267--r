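#' Power and type-I-error study
#'
#' Monte-Carlo harness: simulates `reps` balanced case-control datasets
#' under a scenario, analyses each with the calibrated pairwise statistics
#' (pOR/pRR/pChi) and/or original MDR, and summarises rejection rates.
#'
#' Rejection rules:
#' * calibrated statistics -- a pair is declared significant when its
#'   FDR-adjusted permutation p-value (default; `rule = "pvalue"` uses the
#'   unadjusted one) is below `alpha`;
#' * original MDR -- the pair must be selected as the best cross-validated
#'   model *and* the permutation test of that model must reject at `alpha`,
#'   so under heterogeneity the weaker pair can only be detected if it wins
#'   the model search.
#'
#' Power for a causal pair is the fraction of replicates in which that pair
#' is declared significant.  The type-I error is the rejection fraction
#' averaged over the simulated-null pairs.  By default these are the pairs
#' of loci that are unrelated to the outcome (neither locus enters the
#' susceptibility function), matching the simulation design in which the
#' remaining loci carry no signal; `null_pairs = "all-non-causal"` instead
#' averages over every pair except the causal pair(s), which in models with
#' marginal locus effects mixes main-effect signal into the "null" pairs.
#'
#' @param scenario A [simulation_scenario()].
#' @param n_total Total subjects per replicate (half cases).
#' @param reps Number of simulated datasets.
#' @param methods Subset of `c("pOR", "pRR", "pChi", "MDR")`.
#' @param alpha Nominal significance level.
#' @param B,B_j,fraction Calibration resampling controls
#'   (see [amdr_interactions()]).
#' @param rule `"fdr"` (default) or `"pvalue"` rejection rule for the
#'   calibrated statistics.
#' @param folds,mdr_permutations Original-MDR controls.
#' @param null_pairs Which pairs count as null for the type-I error (see
#'   Details): `"null-loci"` (default) or `"all-non-causal"`.
#' @param seed Master seed; each replicate derives its own simulation and
#'   analysis substreams.
#' @param progress Print a dot every 10 replicates.
#' @return A tibble with one row per method: `method`, `scenario`, `model`,
#'   `n`, `reps`, `power_pair12`, `power_pair45` (NA for single-pair
#'   scenarios), `type1`.
#' @examples
#' sc <- simulation_scenario("single-pair", "model1")
#' power_study(sc, 200, reps = 2, methods = "pOR", B = 100, B_j = 50, seed = 1)
#' @export
power_study <- function(scenario, n_total, reps = 100,
                        methods = c("pOR", "pRR", "pChi", "MDR"),
                        alpha = 0.05, B = 1000, B_j = 200, fraction = 0.9,
                        rule = c("fdr", "pvalue"),
                        folds = 10, mdr_permutations = 200,
                        null_pairs = c("null-loci", "all-non-causal"),
                        seed = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "simulation_scenario"), reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  rule <- match.arg(rule)
  null_pairs <- match.arg(null_pairs)
  amdr_methods <- setdiff(methods, "MDR")

  specs <- enumerate_interactions(scenario$n_snps, 2)
  n_pairs <- nrow(specs)
  pair_id <- vapply(specs$loci, paste, character(1), collapse = ":")
  causal <- paste(scenario$loci1, collapse = ":")
  two_pair <- scenario$type != "single-pair"
  if (two_pair) causal <- c(causal, paste(scenario$loci2, collapse = ":"))
  causal_loci <- c(scenario$loci1, if (two_pair) scenario$loci2)
  null_set <- if (null_pairs == "null-loci") {
    pair_id[vapply(specs$loci, function(l) !any(l %in% causal_loci), logical(1))]
  } else {
    setdiff(pair_id, causal)
  }

  reject <- array(FALSE, c(length(methods), n_pairs, reps),
                  dimnames = list(methods, pair_id, NULL))

  for (r in seq_len(reps)) {
    d <- simulate_dataset(scenario, n_total, seed = derive_seed(seed %||% 0L, "powerrep", r))
    if (length(amdr_methods)) {
      ia <- amdr_interactions(d, k = 2, B = B, B_j = B_j, fraction = fraction,
                              seed = derive_seed(seed %||% 0L, "poweramdr", r),
                              sort_by = "none")
      key <- vapply(ia$loci, paste, character(1), collapse = ":")
      for (m in amdr_methods) {
        cols <- stat_columns(m)
        crit <- ia[[if (rule == "fdr") cols$fdr else cols$pvalue]]
        rej <- !is.na(crit) & crit < alpha
        reject[m, match(key, pair_id), r] <- rej
      }
    }
    if ("MDR" %in% methods) {
      mres <- run_original_mdr(d, k = 2, folds = folds,
                               permutations = mdr_permutations,
                               seed = derive_seed(seed %||% 0L, "powermdr", r))
      if (mres$p_value[1] < alpha) {
        reject["MDR", match(mres$interaction[1], pair_id), r] <- TRUE
      }
    }
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")

  per_pair <- apply(reject, c(1, 2), mean)
  model_label <- paste(c(scenario$model1$name,
                         if (two_pair) scenario$model2$name), collapse = "+")
  tibble::tibble(
    method = methods,
    scenario = scenario$type,
    model = model_label,
    n = n_total,
    reps = reps,
    power_pair12 = unname(per_pair[, causal[1]]),
    power_pair45 = if (two_pair) unname(per_pair[, causal[2]]) else NA_real_,
    type1 = if (length(null_set)) rowMeans(per_pair[, null_set, drop = FALSE])
            else NA_real_
  )
}
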