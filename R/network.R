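#' Build the epistasis-enriched network
#'
#' Nodes are SNPs (or genes, when a mapping is supplied) and edges are the
#' significant pairwise interactions, weighted by pOR.  At gene level, SNPs
#' collapse via `gene_map` and parallel edges are kept with their SNP-pair
#' annotation; a pair of distinct SNPs in the same gene becomes a
#' self-edge, retained and flagged.
#'
#' @param results An `amdr_interactions` tibble with `k = 2`.
#' @param rule Significance rule: `"fdr"` (default, FDR-adjusted p below
#'   `threshold`) or `"pvalue"` (unadjusted).
#' @param threshold Significance threshold, default 0.05.
#' @param statistic Which statistic's p-value/FDR the rule applies to; its
#'   calibrated value also labels the edges (edge weight = pOR by default).
#' @param level `"gene"` or `"snp"`; defaults to gene when `gene_map` is
#'   supplied, else SNP.
#' @param gene_map Named character vector, SNP label -> gene label.
#' @return An object of class `epistasis_network`: list with `nodes`
#'   (tibble `node`), `edges` (tibble `from`, `to`, `snp_a`, `snp_b`,
#'   `weight`, `pvalue`, `fdr`, `self_loop`), and the rule metadata.
#' @examples
#' d <- simulate_dataset(simulation_scenario("single-pair", "model1"), 300, seed = 1)
#' ia <- amdr_interactions(d, B = 200, B_j = 50, seed = 1)
#' build_network(ia)
#' @export
build_network <- function(results, rule = c("fdr", "pvalue"), threshold = 0.05,
                          statistic = c("pOR", "pRR", "pChi"),
                          level = NULL, gene_map = NULL) {
  stopifnot(inherits(results, "amdr_interactions"))
  rule <- match.arg(rule)
  statistic <- match.arg(statistic)
  if (attr(results, "k") != 2) {
    abort("the epistasis network is defined for pairwise (k = 2) interactions")
  }
  level <- level %||% if (is.null(gene_map)) "snp" else "gene"
  level <- match.arg(level, c("snp", "gene"))
  if (level == "gene" && is.null(gene_map)) {
    abort("gene-level networks require a gene_map (SNP label -> gene)")
  }
  cols <- stat_columns(statistic)
  crit <- results[[if (rule == "fdr") cols$fdr else cols$pvalue]]
  keep <- !is.na(crit) & crit < threshold
  sig <- results[keep, , drop = FALSE]
  snp_pair <- t(vapply(strsplit(sig$interaction, ":", fixed = TRUE),
                       function(x) x[1:2], character(2)))
  if (!nrow(sig)) snp_pair <- matrix(character(0), 0, 2)
  to_node <- function(s) {
    if (level == "snp") return(s)
    mapped <- unname(gene_map[s])
    ifelse(is.na(mapped), s, mapped)
  }
  edges <- tibble::tibble(
    from = to_node(snp_pair[, 1]),
    to = to_node(snp_pair[, 2]),
    snp_a = snp_pair[, 1],
    snp_b = snp_pair[, 2],
    weight = sig[[cols$value]],
    pvalue = sig[[cols$pvalue]],
    fdr = sig[[cols$fdr]]
  )
  edges$self_loop <- edges$from == edges$to
  if (any(edges$self_loop)) {
    inform(sprintf("%d within-gene interaction(s) kept as self-edge(s)",
                   sum(edges$self_loop)))
  }
  structure(list(
    nodes = tibble::tibble(node = sort(unique(c(edges$from, edges$to)))),
    edges = edges,
    rule = rule, threshold = threshold, statistic = statistic, level = level
  ), class = "epistasis_network")
}

#' @export
print.epistasis_network <- function(x, ...) {
  cat(sprintf("Epistasis-enriched network (%s level, %s < %s): %d node(s), %d edge(s)\n",
              x$level, x$rule, format(x$threshold), nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' @export
tidy.epistasis_network <- function(x, ...) x$edges

#' @export
glance.epistasis_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_self_loops = sum(x$edges$self_loop),
                 rule = x$rule, threshold = x$threshold,
                 statistic = x$statistic, level = x$level)
}

# igraph view of the network (self-loops allowed, weights kept).
as_igraph_network <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("from", "to", "weight", "pvalue", "fdr", "snp_a", "snp_b")],
    directed = FALSE, vertices = net$nodes)
}

#' Export an epistasis network
#'
#' `edge-tsv` is a lossless plain-text edge list (plus a `.nodes.tsv`
#' sidecar when isolated nodes exist -- never the case for networks built
#' by [build_network()]); `dot` is Graphviz with edge pen width scaled
#' monotonically with the weight; `graphml` is written via igraph.
#'
#' @param net An `epistasis_network`.
#' @param path Output path.
#' @param format `"edge-tsv"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge-tsv", "dot", "graphml")) {
  stopifnot(inherits(net, "epistasis_network"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
  } else if (format == "dot") {
    w <- net$edges$weight
    pen <- if (nrow(net$edges)) 1 + 3 * (rank(w) - 1) / max(1, length(w) - 1) else numeric(0)
    lines <- c(
      "graph epistasis {",
      sprintf("  \"%s\";", net$nodes$node),
      if (nrow(net$edges)) sprintf(
        "  \"%s\" -- \"%s\" [label=\"%.2f\", penwidth=%.2f];",
        net$edges$from, net$edges$to, w, pen),
      "}")
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph_network(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read back an edge-tsv network export
#'
#' @param path Path written by [export_network()] with `format = "edge-tsv"`.
#' @param rule,threshold,statistic,level Metadata to attach (not stored in
#'   the TSV itself).
#' @return An `epistasis_network`.
#' @export
read_network <- function(path, rule = "fdr", threshold = 0.05,
                         statistic = "pOR", level = "snp") {
  edges <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  structure(list(
    nodes = tibble::tibble(node = sort(unique(c(edges$from, edges$to)))),
    edges = edges, rule = rule, threshold = threshold,
    statistic = statistic, level = level
  ), class = "epistasis_network")
}

#' @rdname build_network
#' @param object An `epistasis_network`.
#' @param ... Unused.
#' @export
autoplot.epistasis_network <- function(object, ...) {
  n <- nrow(object$nodes)
  if (n == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "Empty epistasis network"))
  }
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  pos <- tibble::tibble(node = object$nodes$node, x = cos(ang), y = sin(ang))
  ed <- dplyr::left_join(object$edges, pos, by = c(from = "node"))
  ed <- dplyr::left_join(ed, pos, by = c(to = "node"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$node), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = object$statistic) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Epistasis-enriched network")
}
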