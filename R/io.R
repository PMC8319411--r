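# Readers and writers for the pipeline's external formats.
#
# On disk the OTU table follows the classic amplicon convention (OTUs as
# rows, first column header "#OTU ID"); in memory the package works with a
# samples x OTUs matrix. Conversion happens here, at the I/O boundary.
# Readers validate and reject malformed input rather than coercing it.

#' Read an OTU count table
#'
#' Expects a tab-separated file with OTU identifiers in the first column
#' (header `#OTU ID`) and one column per sample. Returns the transposed
#' in-memory representation: a non-negative integer matrix with samples as
#' rows and OTUs as columns.
#'
#' @param path file path.
#' @return samples x OTUs integer matrix.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such file: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_stage("io", "OTU table needs id column plus samples")
  otu_ids <- as.character(raw[[1]])
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop_stage("io", "duplicate sample column: %s",
               sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(otu_ids))
    stop_stage("io", "duplicate OTU id: %s", otu_ids[duplicated(otu_ids)][1])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_stage("io", "non-numeric counts in %s", path)
  counts <- t(m)
  dimnames(counts) <- list(sample_ids, otu_ids)
  storage.mode(counts) <- "integer"
  validate_otu_table(counts)
  counts
}

#' Write an OTU count table
#'
#' Inverse of [read_otu_table()]: writes OTUs as rows with a `#OTU ID`
#' header column.
#'
#' @param counts samples x OTUs matrix.
#' @param path file path.
#' @export
write_otu_table <- function(counts, path) {
  validate_otu_table(counts)
  out <- data.frame(`#OTU ID` = colnames(counts), t(counts),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with columns `sample_id`, `site`, `erosion` (one of
#' E0/EL/EM/EH), `transect`, `plot`. The erosion column is returned as an
#' ordered factor.
#'
#' @param path file path.
#' @return a validated `data.frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such file: %s", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_metadata(md)
  md$erosion <- factor(md$erosion, levels = EROSION_LEVELS, ordered = TRUE)
  md
}

#' @rdname read_metadata
#' @param metadata a metadata `data.frame`.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a soil property table
#'
#' Tab-separated, keyed by `sample_id`, with the 13 soil variables
#' (moisture, pH, OC, TN, TP, NH4, NO3, AP, AK, MBC, MBN, Cm, Nm). All
#' variables except net mineralized nitrogen (Nm) must be non-negative.
#'
#' @param path file path.
#' @return a validated `data.frame`.
#' @export
read_soil_table <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such file: %s", path)
  soil <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_soil_table(soil)
  soil
}

#' @rdname read_soil_table
#' @param soil a soil `data.frame`.
#' @export
write_soil_table <- function(soil, path) {
  validate_soil_table(soil)
  utils::write.table(soil, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network
#'
#' `graphml` writes node attribute `name` (OTU id) and edge attributes
#' `weight` (signed Spearman rho) and `q` (BH-adjusted p). `edgelist` writes
#' a TSV with columns `source`, `target`, `rho`, `q`.
#'
#' @param net a `coocnet` object from [build_network()].
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "coocnet"))
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- net$edges
    colnames(edges) <- c("source", "target", "rho", "q")
    utils::write.table(format(edges, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::E(g)$q <- if (nrow(net$edges)) net$edges$q else numeric(0)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path edge-list TSV.
#' @param threshold,fdr_alpha recorded on the returned object.
#' @return a `coocnet` object.
#' @export
read_network_edgelist <- function(path, threshold = NA_real_,
                                  fdr_alpha = NA_real_) {
  if (!file.exists(path)) stop_stage("io", "no such file: %s", path)
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("source", "target", "rho", "q")
  if (!all(needed %in% names(edges)))
    stop_stage("io", "edge list must have columns %s",
               paste(needed, collapse = ", "))
  edges <- edges[, needed]
  colnames(edges) <- c("otu_a", "otu_b", "rho", "q")
  nodes <- sort(unique(c(edges$otu_a, edges$otu_b)))
  structure(list(nodes = nodes, edges = edges, threshold_used = threshold,
                 fdr_alpha = fdr_alpha, site = NA_character_),
            class = "coocnet")
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()]. Defaults follow the
#' package's reference analysis: OTUs retained at mean relative abundance
#' strictly above 0.01%, RMT threshold scan over 0.30-0.99 in steps of 0.01,
#' edge significance at BH-adjusted p < 0.05, and keystone criteria
#' degree > 6, weighted degree > 6, harmonic closeness > 0.14, normalized
#' betweenness < 0.05, local clustering coefficient > 0.09.
#'
#' @param min_rel_abundance retention threshold on mean relative abundance.
#' @param rmt_scan numeric `c(lo, hi, step)` threshold grid.
#' @param fdr_alpha FDR level for edge significance.
#' @param keystone named list of classifier thresholds (`degree_min`,
#'   `weighted_degree_min`, `closeness_min`, `betweenness_max`,
#'   `transitivity_min`).
#' @param anosim_permutations permutations for ANOSIM and ordination tests.
#' @param seed integer seed for all permutation tests.
#' @param mf_excluded_variables soil variables excluded from the
#'   multifunctionality index (pH by default, being a log-scaled quantity).
#' @param positive_only restrict network edges to positive correlations.
#' @param pooled analyze all sites pooled instead of per site.
#' @param rarefy rarefy each sample to the minimum library size before
#'   diversity computation (off by default: the reference analysis used
#'   unrarefied counts).
#' @param mf_global_scaling scale multifunctionality over all samples
#'   jointly instead of within site.
#' @param filter_method `"mean"` (mean per-sample relative abundance) or
#'   `"pooled"` (relative abundance of pooled totals) for the OTU filter.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_rel_abundance = 1e-4,
                            rmt_scan = c(0.30, 0.99, 0.01),
                            fdr_alpha = 0.05,
                            keystone = list(degree_min = 6,
                                            weighted_degree_min = 6,
                                            closeness_min = 0.14,
                                            betweenness_max = 0.05,
                                            transitivity_min = 0.09),
                            anosim_permutations = 9999,
                            seed = 1,
                            mf_excluded_variables = "pH",
                            positive_only = FALSE,
                            pooled = FALSE,
                            rarefy = FALSE,
                            mf_global_scaling = FALSE,
                            filter_method = c("mean", "pooled")) {
  if (min_rel_abundance <= 0 || min_rel_abundance >= 1)
    stop_stage("config", "min_rel_abundance must be in (0, 1)")
  if (length(rmt_scan) != 3 || rmt_scan[1] <= 0 || rmt_scan[2] >= 1 ||
      rmt_scan[1] >= rmt_scan[2] || rmt_scan[3] <= 0)
    stop_stage("config", "rmt_scan must be c(lo, hi, step) with 0 < lo < hi < 1")
  if (fdr_alpha <= 0 || fdr_alpha > 1)
    stop_stage("config", "fdr_alpha must be in (0, 1]")
  needed <- c("degree_min", "weighted_degree_min", "closeness_min",
              "betweenness_max", "transitivity_min")
  if (!all(needed %in% names(keystone)) ||
      any(!is.finite(unlist(keystone[needed]))))
    stop_stage("config", "keystone thresholds must include finite %s",
               paste(needed, collapse = ", "))
  structure(list(min_rel_abundance = min_rel_abundance, rmt_scan = rmt_scan,
                 fdr_alpha = fdr_alpha, keystone = keystone,
                 anosim_permutations = as.integer(anosim_permutations),
                 seed = as.integer(seed),
                 mf_excluded_variables = mf_excluded_variables,
                 positive_only = isTRUE(positive_only),
                 pooled = isTRUE(pooled),
                 rarefy = isTRUE(rarefy),
                 mf_global_scaling = isTRUE(mf_global_scaling),
                 filter_method = match.arg(filter_method)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such file: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop_stage("config", "unknown configuration key(s): %s",
               paste(unknown, collapse = ", "))
  if (!is.null(y$rmt_scan)) y$rmt_scan <- as.numeric(unlist(y$rmt_scan))
  do.call(pipeline_config, y)
}
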