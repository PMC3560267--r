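# Built-in two-locus penetrance models used throughout the power study.
# Rows index the first locus (AA, Aa, aa = codes 0/1/2), columns the second
# (BB, Bb, bb).  Models 1-2 are pure-epistasis checkerboards at MAF 0.5
# (no marginal effects); models 3-4 are noisier interactions at MAF 0.25.
builtin_penetrance <- function() {
  gt <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
  list(
    model1 = list(maf = 0.5, table = matrix(c(
      0, 0.1, 0,
      0.1, 0, 0.1,
      0, 0.1, 0), 3, 3, byrow = TRUE, dimnames = gt)),
    model2 = list(maf = 0.5, table = matrix(c(
      0, 0, 0.1,
      0, 0.05, 0,
      0.1, 0, 0), 3, 3, byrow = TRUE, dimnames = gt)),
    model3 = list(maf = 0.25, table = matrix(c(
      0.08, 0.07, 0.05,
      0.1, 0, 0.1,
      0.03, 0.1, 0.04), 3, 3, byrow = TRUE, dimnames = gt)),
    model4 = list(maf = 0.25, table = matrix(c(
      0.09, 0.05, 0.02,
      0.08, 0.09, 0.01,
      0.03, 0.01, 0.03), 3, 3, byrow = TRUE, dimnames = gt))
  )
}

#' Two-locus penetrance model
#'
#' Either one of the built-in models (`"model1"`..`"model4"`) or a custom
#' 3x3 penetrance table `P(D = 1 | g1, g2)` indexed by genotype codes
#' 0 (common homozygote), 1 (heterozygote), 2 (rare homozygote) on each
#' axis, with a minor allele frequency for genotype generation.
#'
#' @param model Built-in name, or `"custom"` with `table` and `maf` given.
#' @param table Optional 3x3 matrix of penetrances in `[0, 1]`.
#' @param maf Minor allele frequency in `(0, 0.5]`.
#' @return An object of class `penetrance_model`: list `name`, `table`,
#'   `maf`.
#' @examples
#' penetrance_model("model1")
#' @export
penetrance_model <- function(model = c("model1", "model2", "model3", "model4",
                                       "custom"),
                             table = NULL, maf = NULL) {
  if (inherits(model, "penetrance_model")) return(model)
  model <- match.arg(model)
  if (model == "custom") {
    stopifnot(!is.null(table), !is.null(maf))
  } else {
    b <- builtin_penetrance()[[model]]
    table <- table %||% b$table
    maf <- maf %||% b$maf
  }
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(3, 3)), all(table >= 0 & table <= 1),
            maf > 0, maf <= 0.5)
  structure(list(name = model, table = table, maf = maf),
            class = "penetrance_model")
}

#' Hardy-Weinberg genotype probabilities
#'
#' For minor allele frequency `q`: `((1-q)^2, 2q(1-q), q^2)` for genotype
#' codes 0 (common homozygote), 1, 2.
#'
#' @param q Minor allele frequency in `(0, 0.5]`.
#' @return Numeric length-3 probability vector.
#' @examples
#' hwe_genotype_probs(0.25)
#' @export
hwe_genotype_probs <- function(q) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 0.5) {
    abort("minor allele frequency must be in (0, 0.5]")
  }
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Penetrance lookup
#'
#' @param model A `penetrance_model`.
#' @param g1,g2 Genotype codes 0/1/2 (vectorised).
#' @return `P(D = 1 | g1, g2)`.
#' @export
penetrance <- function(model, g1, g2) {
  model <- penetrance_model(model)
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  model$table[cbind(g1 + 1L, g2 + 1L)]
}

#' Simulation scenario for the case-control generator
#'
#' Three designs over five Hardy-Weinberg, linkage-equilibrium SNPs:
#' * `"single-pair"`: only loci 1 and 2 interact,
#'   `P(D=1) = p12(g1, g2)`;
#' * `"heterogeneity"`: a latent-source mixture -- a fraction `gamma1` of
#'   the affected subjects acquire disease through loci 1x2 and the rest
#'   (`gamma2 = 1 - gamma1`) through loci 4x5.  Each subject carries a
#'   latent source label `C` and is affected with probability given by that
#'   source's penetrance; the case sample is constrained to the
#'   `gamma1 : gamma2` source split, as in the classic heterogeneity
#'   simulations this design follows;
#' * `"additive"`: both pairs contribute jointly (union of two independent
#'   disease routes), `P(D=1) = p12 + p45 - p12 p45`.
#'
#' Locus 3 (and any extra SNPs) never enters the susceptibility.
#'
#' @param type Scenario type (see above).
#' @param model1 Penetrance model (name or object) for loci 1x2.
#' @param model2 Penetrance model for loci 4x5 (two-pair scenarios only).
#' @param gamma1 Mixture weight of the loci-1x2 route (heterogeneity only);
#'   `gamma2 = 1 - gamma1`.
#' @param n_snps Number of simulated SNPs (`>= 5` for two-pair scenarios).
#' @return An object of class `simulation_scenario`.
#' @examples
#' simulation_scenario("heterogeneity", "model1", "model2", gamma1 = 0.5)
#' @export
simulation_scenario <- function(type = c("single-pair", "heterogeneity",
                                         "additive"),
                                model1 = "model1", model2 = NULL,
                                gamma1 = 0.5, n_snps = 5) {
  type <- match.arg(type)
  model1 <- penetrance_model(model1)
  if (type != "single-pair") {
    if (is.null(model2)) abort("two-pair scenarios need model2 for loci 4x5")
    model2 <- penetrance_model(model2)
    if (n_snps < 5) abort("two-pair scenarios need at least 5 SNPs")
  } else if (!is.null(model2)) {
    model2 <- penetrance_model(model2)
  }
  stopifnot(gamma1 >= 0, gamma1 <= 1, n_snps >= 2)
  structure(list(type = type, model1 = model1, model2 = model2,
                 gamma1 = gamma1, gamma2 = 1 - gamma1,
                 loci1 = c(1L, 2L), loci2 = c(4L, 5L),
                 n_snps = as.integer(n_snps)),
            class = "simulation_scenario")
}

#' Disease susceptibility of genotype vectors under a scenario
#'
#' Evaluates the scenario's susceptibility formula exactly (see
#' [simulation_scenario()]).
#'
#' @param scenario A `simulation_scenario`.
#' @param genotypes Integer matrix (subjects x SNPs, codes 0/1/2) or a
#'   single genotype vector.
#' @return Vector of `P(D = 1 | genotype)`.
#' @examples
#' sc <- simulation_scenario("additive", "model1", "model2")
#' susceptibility(sc, c(0, 1, 0, 0, 2))
#' @export
susceptibility <- function(scenario, genotypes) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (is.vector(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  need <- if (scenario$type == "single-pair") max(scenario$loci1) else
    max(scenario$loci1, scenario$loci2)
  stopifnot(ncol(genotypes) >= need)
  p1 <- penetrance(scenario$model1, genotypes[, scenario$loci1[1]],
                   genotypes[, scenario$loci1[2]])
  switch(scenario$type,
    "single-pair" = p1,
    "heterogeneity" = {
      p2 <- penetrance(scenario$model2, genotypes[, scenario$loci2[1]],
                       genotypes[, scenario$loci2[2]])
      scenario$gamma1 * p1 + scenario$gamma2 * p2
    },
    "additive" = {
      p2 <- penetrance(scenario$model2, genotypes[, scenario$loci2[1]],
                       genotypes[, scenario$loci2[2]])
      p1 + p2 - p1 * p2
    })
}

# Per-locus MAF vector: causal pairs carry their model's MAF, background
# loci the MAF of model 1 (all built-in pairings share one MAF anyway).
scenario_mafs <- function(scenario) {
  mafs <- rep(scenario$model1$maf, scenario$n_snps)
  if (!is.null(scenario$model2)) mafs[scenario$loci2] <- scenario$model2$maf
  mafs
}

#' Simulate a balanced case-control genotype dataset
#'
#' Rejection sampling: candidate subjects receive independent
#' Hardy-Weinberg genotypes at every locus, disease status is drawn with
#' probability given by the scenario's susceptibility, and sampling
#' continues until `n_total / 2` cases and `n_total / 2` controls are
#' collected (cases first in the output).  Deterministic under `seed`.
#'
#' @param scenario A `simulation_scenario`.
#' @param n_total Even total number of subjects (half cases).
#' @param seed Master seed (substream `"simulate"`).
#' @param keep_latent For heterogeneity scenarios, add a `.source` column
#'   recording which locus pair generated each case (1 = loci 1x2,
#'   2 = loci 4x5, NA for controls).
#' @param max_draws Safety cap on candidate draws.
#' @return A genotype tibble: columns `SNP1..SNPm` (integer 0/1/2) and
#'   `Class` (1 = case).  For heterogeneity scenarios the case sample
#'   contains `round(gamma1 * n_total / 2)` loci-1x2-sourced cases and the
#'   complement from loci 4x5.
#' @examples
#' simulate_dataset(simulation_scenario("single-pair", "model1"), 100, seed = 1)
#' @export
simulate_dataset <- function(scenario, n_total, seed = NULL,
                             keep_latent = FALSE, max_draws = 1e7) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            n_total >= 2, n_total %% 2 == 0)
  mafs <- scenario_mafs(scenario)
  n_half <- n_total / 2
  het <- scenario$type == "heterogeneity"
  # per-source case quotas: the gamma split applies to the affected sample
  quota <- if (het) {
    q1 <- round(scenario$gamma1 * n_half)
    c(q1, n_half - q1)
  } else n_half
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "simulate"), {
    cases <- vector("list", length(quota))
    controls <- NULL
    case_src <- integer(0)
    drawn <- 0
    batch <- max(1000L, n_total * 2L)
    enough_cases <- function() {
      all(vapply(seq_along(quota), function(i) {
        !is.null(cases[[i]]) && nrow(cases[[i]]) >= quota[i]
      }, logical(1)))
    }
    while ((!enough_cases() || is.null(controls) || nrow(controls) < n_half) &&
           drawn < max_draws) {
      g <- vapply(mafs, function(q) {
        sample.int(3L, batch, replace = TRUE, prob = hwe_genotype_probs(q)) - 1L
      }, integer(batch))
      if (het) {
        src <- 1L + (runif(batch) >= scenario$gamma1)
        p1 <- penetrance(scenario$model1, g[, scenario$loci1[1]],
                         g[, scenario$loci1[2]])
        p2 <- penetrance(scenario$model2, g[, scenario$loci2[1]],
                         g[, scenario$loci2[2]])
        p <- ifelse(src == 1L, p1, p2)
      } else {
        src <- rep(1L, batch)
        p <- susceptibility(scenario, g)
      }
      d <- runif(batch) < p
      drawn <- drawn + batch
      for (i in seq_along(quota)) {
        new <- g[d & src == i, , drop = FALSE]
        cases[[i]] <- if (is.null(cases[[i]])) new else rbind(cases[[i]], new)
      }
      new_controls <- g[!d, , drop = FALSE]
      controls <- if (is.null(controls)) new_controls else rbind(controls, new_controls)
    }
    if (!enough_cases() || nrow(controls) < n_half) {
      abort(paste0("draw cap exceeded before filling both groups; ",
                   "check that the penetrances are attainable"))
    }
    case_mat <- do.call(rbind, lapply(seq_along(quota), function(i) {
      cases[[i]][seq_len(quota[i]), , drop = FALSE]
    }))
    case_src <- rep(seq_along(quota), quota)
    geno <- rbind(case_mat, controls[seq_len(n_half), , drop = FALSE])
    out <- tibble::as_tibble(as.data.frame(geno))
    names(out) <- paste0("SNP", seq_along(mafs))
    out$Class <- rep(c(1L, 0L), each = n_half)
    if (keep_latent && het) {
      out$.source <- c(case_src, rep(NA_integer_, n_half))
    }
    out
  })
}
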