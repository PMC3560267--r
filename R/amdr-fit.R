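#' Fit the full aggregated-MDR pipeline
#'
#' One-call interface chaining the three stages: (1) detection -- calibrated
#' pOR/pRR/pChi over all k-way locus combinations ([amdr_interactions()]);
#' (2) aggregation -- epistasis-enriched risk scores with AUC-maximising
#' threshold selection, ROC/AUC and classification cutoff
#' ([amdr_risk_profile()]); (3) for pairwise analyses, the
#' epistasis-enriched network ([build_network()]).
#'
#' @inheritParams amdr_interactions
#' @param statistic Statistic used for threshold selection, risk scores and
#'   the network.
#' @param alpha Fixed significance threshold; `NULL` (default) selects it
#'   by AUC maximisation over `[0, 0.05]`.
#' @param network_rule Significance rule for network edges (`"fdr"` or
#'   `"pvalue"`).
#' @param gene_map Optional named vector (SNP label -> gene) for a
#'   gene-level network.
#' @return An object of class `amdr_fit`: list with `interactions`
#'   (the `amdr_interactions` tibble), `profile` (`amdr_profile`),
#'   `network` (`epistasis_network` or NULL when `k != 2`), and call
#'   metadata.  Supports [tidy()] (interaction table), [glance()] (one-row
#'   model summary) and [autoplot()] (ROC curve).
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 300, seed = 1)
#' fit <- amdr(d, B = 200, B_j = 50, seed = 1)
#' glance(fit)
#' @export
amdr <- function(data, k = 2, B = 1000, B_j = 200, fraction = 0.9,
                 statistic = c("pOR", "pRR", "pChi"), alpha = NULL,
                 network_rule = c("fdr", "pvalue"), gene_map = NULL,
                 seed = NULL, class_column = "Class", id_column = NULL) {
  statistic <- match.arg(statistic)
  network_rule <- match.arg(network_rule)
  interactions <- amdr_interactions(
    data, k = k, B = B, B_j = B_j, fraction = fraction, seed = seed,
    sort_by = statistic, class_column = class_column, id_column = id_column)
  profile <- amdr_risk_profile(
    data, interactions, alpha = alpha, statistic = statistic,
    class_column = class_column, id_column = id_column)
  network <- if (k == 2) {
    build_network(interactions, rule = network_rule, statistic = statistic,
                  gene_map = gene_map)
  }
  structure(list(
    interactions = interactions, profile = profile, network = network,
    statistic = statistic, k = k,
    n = nrow(data), m = length(attr(interactions, "snp_labels")),
    p0 = attr(interactions, "p0")
  ), class = "amdr_fit")
}

#' @export
print.amdr_fit <- function(x, ...) {
  cat(sprintf(
    "Aggregated-MDR fit: %d subjects, %d SNPs, %d %d-way interaction(s)\n",
    x$n, x$m, nrow(x$interactions), x$k))
  cat(sprintf("  case fraction (risk threshold) %.3f\n", x$p0))
  print(x$profile)
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d node(s), %d significant edge(s) (%s < 0.05)\n",
                nrow(x$network$nodes), nrow(x$network$edges), x$network$rule))
  }
  invisible(x)
}

#' @rdname amdr
#' @param x,object An `amdr_fit`.
#' @param ... Unused.
#' @export
tidy.amdr_fit <- function(x, ...) x$interactions

#' @rdname amdr
#' @export
glance.amdr_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, m = x$m, k = x$k,
                   n_interactions = nrow(x$interactions)),
    glance(x$profile),
    tibble::tibble(n_edges = if (is.null(x$network)) NA_integer_
                   else nrow(x$network$edges))
  )
}

#' @rdname amdr
#' @export
autoplot.amdr_fit <- function(object, ...) autoplot(object$profile, ...)
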