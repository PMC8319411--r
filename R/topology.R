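# Co-occurrence network construction and topology: global summaries,
# per-sample induced subgraphs, and keystone-taxon classification.

#' Build a co-occurrence network
#'
#' An edge connects two OTUs when `|rho| >= threshold` and the BH-adjusted
#' p-value satisfies `q < fdr_alpha` (both conditions required). The signed
#' rho is stored as the edge weight; OTUs with no incident edge are not
#' nodes.
#'
#' @param corr a `correlation_result` from [spearman_matrix()].
#' @param threshold correlation threshold in `(0, 1)`, e.g. the RMT-selected
#'   one.
#' @param fdr_alpha significance level on the q-values.
#' @param positive_only drop negative correlations.
#' @param site optional site label carried on the object.
#' @return a `coocnet` list with `nodes`, `edges` (`otu_a`, `otu_b`, `rho`,
#'   `q`), `threshold_used`, `fdr_alpha`, `site`.
#' @export
build_network <- function(corr, threshold, fdr_alpha = 0.05,
                          positive_only = FALSE, site = NA_character_) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop_stage("network", "threshold must lie in (0, 1)")
  rho <- corr$rho
  q <- corr$q
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[upper.tri(rho)]
  qq <- q[upper.tri(q)]
  pass <- !is.na(r) & !is.na(qq) & abs(r) >= threshold & qq < fdr_alpha
  if (positive_only) pass <- pass & r > 0
  edges <- data.frame(otu_a = colnames(rho)[iu[pass, 1]],
                      otu_b = colnames(rho)[iu[pass, 2]],
                      rho = r[pass], q = qq[pass],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  structure(list(nodes = nodes, edges = edges, threshold_used = threshold,
                 fdr_alpha = fdr_alpha, site = site),
            class = "coocnet")
}

#' @export
print.coocnet <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (|rho| >= %.2f, q < %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold_used, x$fdr_alpha))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Edge attribute `weight` carries the signed rho.
#'
#' @param net a `coocnet` object.
#' @return an undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coocnet"))
  if (length(net$nodes) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$otu_a, to = net$edges$otu_b,
               weight = net$edges$rho),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

topology_of_graph <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0) {
    return(data.frame(node_number = 0L, edge_number = 0L,
                      betweenness = NA_real_, assortativity = NA_real_,
                      transitivity = NA_real_, degree = NA_real_,
                      modularity = NA_real_))
  }
  deg <- igraph::degree(g)
  btw <- if (n > 2) {
    mean(igraph::betweenness(g, weights = NA, normalized = TRUE))
  } else 0
  assort <- if (stats::sd(deg) > 0 && m > 0) {
    suppressWarnings(igraph::assortativity_degree(g))
  } else NA_real_
  trans <- igraph::transitivity(g, type = "global")
  mod <- if (m > 0) {
    comm <- igraph::cluster_fast_greedy(
      g, weights = abs(igraph::E(g)$weight %||% rep(1, m)))
    igraph::modularity(comm)
  } else NA_real_
  data.frame(node_number = n, edge_number = m, betweenness = btw,
             assortativity = assort, transitivity = trans,
             degree = mean(deg), modularity = mod)
}

#' Global network topology summary
#'
#' Betweenness is the mean over nodes of shortest-path betweenness
#' normalized by `(n-1)(n-2)/2`; assortativity is Newman's degree
#' assortativity (undefined on regular graphs, reported as `NA`);
#' transitivity is the global clustering coefficient (3 x triangles /
#' connected triples); modularity comes from fast-greedy community
#' detection on `|rho|` weights. All paths are unweighted.
#'
#' @param net a `coocnet` object.
#' @return one-row `data.frame` with `node_number`, `edge_number`,
#'   `betweenness`, `assortativity`, `transitivity`, `degree`, `modularity`.
#' @export
global_topology <- function(net) {
  stopifnot(inherits(net, "coocnet"))
  topology_of_graph(as_igraph(net))
}

#' Per-sample induced-subgraph topology
#'
#' For each sample, the subgraph induced on the network OTUs present
#' (count > 0) in that sample is summarized with the same metrics as
#' [global_topology()]. Samples inducing an empty subgraph get a missing
#' row.
#'
#' @param net a `coocnet` object.
#' @param counts samples x OTUs matrix containing the network's OTUs.
#' @return `data.frame` with one row per sample.
#' @export
sample_subgraph_topology <- function(net, counts) {
  stopifnot(inherits(net, "coocnet"))
  validate_otu_table(counts)
  missing <- setdiff(net$nodes, colnames(counts))
  if (length(missing) > 0)
    stop_stage("topology", "count table lacks network OTU(s): %s",
               paste(utils::head(missing, 3), collapse = ", "))
  g <- as_igraph(net)
  rows <- lapply(rownames(counts), function(s) {
    present <- net$nodes[counts[s, net$nodes] > 0]
    sub <- igraph::induced_subgraph(g, present)
    cbind(data.frame(sample_id = s), topology_of_graph(sub))
  })
  do.call(rbind, rows)
}

#' Keystone taxon classification
#'
#' Per-node metrics on the global network: degree; weighted degree (sum of
#' `|rho|` over incident edges); harmonic closeness centrality normalized by
#' `n - 1` (defined on disconnected graphs); shortest-path betweenness
#' normalized by `(n-1)(n-2)/2`; and the local clustering coefficient. A
#' node is flagged keystone when degree > 6, weighted degree > 6,
#' closeness > 0.14, betweenness < 0.05 and local transitivity > 0.09 (all
#' inequalities strict; defaults overridable via `thresholds`). Nodes whose
#' local clustering is undefined (degree < 2) are never keystones.
#'
#' @param net a `coocnet` object.
#' @param thresholds named list with `degree_min`, `weighted_degree_min`,
#'   `closeness_min`, `betweenness_max`, `transitivity_min`.
#' @return `data.frame` with one row per node: the five metrics and a
#'   logical `keystone` flag; thresholds attached as an attribute.
#' @export
identify_keystones <- function(net,
                               thresholds = list(degree_min = 6,
                                                 weighted_degree_min = 6,
                                                 closeness_min = 0.14,
                                                 betweenness_max = 0.05,
                                                 transitivity_min = 0.09)) {
  stopifnot(inherits(net, "coocnet"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) {
    out <- data.frame(otu = character(0), degree = numeric(0),
                      weighted_degree = numeric(0), closeness = numeric(0),
                      betweenness = numeric(0), transitivity = numeric(0),
                      keystone = logical(0))
    attr(out, "thresholds") <- thresholds
    return(out)
  }
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g, weights = abs(igraph::E(g)$weight))
  clo <- if (n > 1) {
    igraph::harmonic_centrality(g, weights = NA, normalized = FALSE) / (n - 1)
  } else rep(0, n)
  btw <- if (n > 2) {
    igraph::betweenness(g, weights = NA, normalized = TRUE)
  } else rep(0, n)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  flag <- deg > thresholds$degree_min &
    wdeg > thresholds$weighted_degree_min &
    clo > thresholds$closeness_min &
    btw < thresholds$betweenness_max &
    !is.na(loc) & loc > thresholds$transitivity_min
  out <- data.frame(otu = igraph::V(g)$name, degree = as.numeric(deg),
                    weighted_degree = as.numeric(wdeg),
                    closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    transitivity = as.numeric(loc),
                    keystone = as.logical(flag),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}
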