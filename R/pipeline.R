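# End-to-end pipeline driver: per-site filtering -> diversity -> soil
# multifunctionality -> co-occurrence network (RMT threshold, FDR edges) ->
# topology -> keystones -> association statistics, with all results written
# as TSV/JSON plus a log of thresholds and seeds.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full erosion-microbiome analysis pipeline
#'
#' Sites are analyzed separately by default (set `pooled = TRUE` in the
#' configuration to pool them). Per site: OTU filtering at the relative
#' abundance threshold, alpha diversity, ANOSIM and CPCoA over erosion
#' levels, soil multifunctionality, the Spearman/RMT/FDR co-occurrence
#' network with global and per-sample topology and keystone classification,
#' and the association layer (MF ~ alpha diversity and MF ~ per-sample
#' network metrics regressions, Pearson correlations of diversity against
#' soil variables, Kruskal-Wallis of MF over erosion levels). Across sites,
#' a two-way ANOVA (site x erosion, transect as block) is run on MF and
#' Shannon diversity.
#'
#' @param otu_table samples x OTUs count matrix (or a path to one).
#' @param metadata sample metadata `data.frame` (or a path).
#' @param soil_table soil `data.frame` (or a path).
#' @param out_dir output directory for result files; `NULL` disables writing.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with one entry per analysis unit (site) plus
#'   `anova` (cross-site tests) and `config`.
#' @export
run_pipeline <- function(otu_table, metadata, soil_table, out_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(otu_table)) otu_table <- read_otu_table(otu_table)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(soil_table)) soil_table <- read_soil_table(soil_table)
  validate_otu_table(otu_table)
  validate_metadata(metadata)
  validate_soil_table(soil_table)
  al <- align_samples(otu_table, metadata, soil_table)
  otu_table <- al$counts; metadata <- al$metadata; soil_table <- al$soil

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop_stage("io", "cannot create directory %s", out_dir)
  }
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("rmt grid: %s",
                         paste(config$rmt_scan, collapse = " ")),
                 sprintf("min_rel_abundance: %g", config$min_rel_abundance))

  if (config$rarefy) {
    set.seed(derive_seed(config$seed, "rarefy"))
    depth_min <- min(rowSums(otu_table))
    otu_table <- vegan::rrarefy(otu_table, depth_min)
    storage.mode(otu_table) <- "integer"
  }
  mf_global <- if (config$mf_global_scaling) {
    multifunctionality(soil_table, excluded = config$mf_excluded_variables)
  } else NULL

  units <- if (config$pooled) list(all = rownames(otu_table))
           else split(metadata$sample_id, metadata$site)
  results <- list()

  for (site in names(units)) {
    ids <- units[[site]]
    counts <- otu_table[ids, , drop = FALSE]
    md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
    soil <- soil_table[match(ids, soil_table$sample_id), , drop = FALSE]
    res <- list(site = site)

    counts_f <- tryCatch(
      filter_otus(counts, config$min_rel_abundance,
                  method = config$filter_method),
      error = function(e) stop_stage("filter", "%s: %s", site,
                                     conditionMessage(e)))
    res$n_otus_retained <- ncol(counts_f)

    res$alpha <- alpha_diversity(counts_f)
    dist_bc <- bray_curtis_matrix(counts_f)
    if (nrow(counts_f) < 4 || length(unique(md$erosion)) < 2 ||
        any(table(droplevels(md$erosion)) < 2))
      stop_stage("anosim", "%s: need >= 2 erosion levels with >= 2 samples each",
                 site)
    res$anosim <- anosim(dist_bc, as.character(md$erosion),
                         n_permutations = config$anosim_permutations,
                         seed = derive_seed(config$seed, paste0("anosim_", site)))
    res$cpcoa <- cpcoa(dist_bc, md$erosion,
                       n_permutations = min(config$anosim_permutations, 999),
                       seed = derive_seed(config$seed, paste0("cpcoa_", site)))

    res$mf <- if (is.null(mf_global)) {
      multifunctionality(soil, excluded = config$mf_excluded_variables)
    } else {
      mf_global[match(ids, mf_global$sample_id), , drop = FALSE]
    }

    corr <- spearman_matrix(counts_f)
    grid <- seq(config$rmt_scan[1], config$rmt_scan[2], by = config$rmt_scan[3])
    res$rmt <- rmt_select_threshold(corr, grid = grid, fallback = TRUE)
    log_lines <- c(log_lines,
                   sprintf("%s: RMT threshold selected %.2f (rule: %s)", site,
                           res$rmt$selected, res$rmt$selection_rule))
    res$network <- build_network(corr, res$rmt$selected,
                                 fdr_alpha = config$fdr_alpha,
                                 positive_only = config$positive_only,
                                 site = site)
    res$topology <- global_topology(res$network)
    res$sample_topology <- sample_subgraph_topology(res$network, counts_f)
    res$keystones <- identify_keystones(res$network, config$keystone)

    # association layer
    mf <- res$mf$mf[match(ids, res$mf$sample_id)]
    alpha <- res$alpha[match(ids, res$alpha$sample_id), ]
    st <- res$sample_topology[match(ids, res$sample_topology$sample_id), ]
    regs <- list(
      linear_regression(alpha$shannon, mf, "shannon", "mf"),
      linear_regression(alpha$observed_species, mf, "observed_species", "mf"),
      linear_regression(alpha$ace, mf, "ace", "mf"))
    for (metric in c("node_number", "edge_number", "betweenness",
                     "assortativity")) {
      x <- st[[metric]]
      if (sum(is.finite(x)) >= 3 && stats::sd(x[is.finite(x)]) > 0)
        regs[[length(regs) + 1]] <- linear_regression(x, mf, metric, "mf")
    }
    res$regressions <- do.call(rbind, regs)
    res$pearson <- pearson_matrix(
      alpha[, c("shannon", "observed_species", "ace")],
      soil[, SOIL_VARIABLES])
    res$kruskal_mf <- kruskal_wallis(mf, md$erosion)

    if (!is.null(out_dir)) {
      tag <- function(name, ext = "tsv")
        file.path(out_dir, sprintf("%s_%s.%s", name, site, ext))
      write_tsv(res$alpha, tag("alpha_diversity"))
      write_tsv(res$mf, tag("multifunctionality"))
      write_tsv(res$rmt$scan, tag("rmt_scan"))
      write_network(res$network, tag("network_edges"), "edgelist")
      write_network(res$network, tag("network", "graphml"), "graphml")
      write_tsv(res$topology, tag("topology_global"))
      write_tsv(res$sample_topology, tag("topology_samples"))
      write_tsv(res$keystones, tag("keystones"))
      write_tsv(res$regressions, tag("regressions"))
      write_tsv(res$pearson, tag("pearson"))
      jsonlite::write_json(
        list(anosim = list(R = res$anosim$R, p = res$anosim$p_value),
             cpcoa = list(proportion_explained = res$cpcoa$proportion_explained,
                          p = res$cpcoa$p_value),
             kruskal_mf = list(statistic = res$kruskal_mf$statistic,
                               p = res$kruskal_mf$p_value,
                               letters = as.list(res$kruskal_mf$letters))),
        tag("tests", "json"), auto_unbox = TRUE, digits = NA)
    }
    results[[site]] <- res
  }

  # cross-site two-way ANOVA on MF and Shannon (only meaningful per-site runs)
  anova_res <- NULL
  if (!config$pooled && length(results) >= 2) {
    mf_all <- unlist(lapply(results, function(r)
      r$mf$mf[match(units[[r$site]], r$mf$sample_id)]))
    sh_all <- unlist(lapply(results, function(r)
      r$alpha$shannon[match(units[[r$site]], r$alpha$sample_id)]))
    ids_all <- unlist(units, use.names = FALSE)
    md_all <- metadata[match(ids_all, metadata$sample_id), ]
    anova_res <- list(
      mf = two_way_anova(mf_all, md_all$site, md_all$erosion, md_all$transect),
      shannon = two_way_anova(sh_all, md_all$site, md_all$erosion,
                              md_all$transect))
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        lapply(anova_res, function(a) list(table = a$table,
                                           letters = a$letters_by_site)),
        file.path(out_dir, "anova_cross_site.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  }
  invisible(c(results, list(anova = anova_res, config = config)))
}
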