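# Synthetic erosion-gradient microbiome data.
#
# Emulates a two-site field design: at each site, 2 transects x 4 slope
# positions (erosion levels E0/EL/EM/EH) x 3 plots = 24 composite samples.
# OTU counts follow a lognormal species-abundance distribution with
# erosion-dependent richness/evenness decline, correlated OTU guilds with
# hub taxa, and multinomial sampling at a lognormally varying depth.
# Soil variables decline multiplicatively from E0 to EH around published
# field baselines for a loess-region and a black-soil-region site.

# Per-site reference soil baselines: E0 means, coefficients of variation
# (from reported standard errors with n = 6 plots per level), and E0 -> EH
# multiplicative decline factors. pH is held near-constant across levels.
soil_reference <- function() {
  vars <- SOIL_VARIABLES
  loess <- list(
    mean = c(moisture = 21.9, pH = 8.19, OC = 7.5, TN = 0.72, TP = 0.25,
             NH4 = 4.78, NO3 = 1.78, AP = 1.88, AK = 110.7, MBC = 91.1,
             MBN = 3.7, Cm = 3.9, Nm = 2.9),
    se   = c(moisture = 0.35, pH = 0.02, OC = 0.2, TN = 0.02, TP = 0.02,
             NH4 = 0.32, NO3 = 0.22, AP = 0.07, AK = 3.7, MBC = 5.8,
             MBN = 0.2, Cm = 0.18, Nm = 1.5),
    eh   = c(moisture = 20.8, pH = 8.24, OC = 4.7, TN = 0.45, TP = 0.28,
             NH4 = 4.58, NO3 = 1.17, AP = 1.69, AK = 101.5, MBC = 17.6,
             MBN = 0.9, Cm = 4.1, Nm = 1.7))
  blacksoil <- list(
    mean = c(moisture = 28.4, pH = 5.74, OC = 26.0, TN = 1.97, TP = 0.35,
             NH4 = 7.15, NO3 = 2.38, AP = 27.10, AK = 175.8, MBC = 188.1,
             MBN = 16.3, Cm = 3.8, Nm = 21.3),
    se   = c(moisture = 1.02, pH = 0.09, OC = 1.2, TN = 0.09, TP = 0.02,
             NH4 = 1.01, NO3 = 0.22, AP = 1.48, AK = 7.7, MBC = 17.6,
             MBN = 3.2, Cm = 0.27, Nm = 1.2),
    eh   = c(moisture = 8.5, pH = 5.64, OC = 8.4, TN = 0.65, TP = 0.12,
             NH4 = 5.88, NO3 = 1.17, AP = 26.85, AK = 122.6, MBC = 31.7,
             MBN = 12.7, Cm = 2.9, Nm = 4.7))
  lapply(list(loess = loess, blacksoil = blacksoil), function(s) {
    decline <- s$eh / s$mean
    decline["pH"] <- 1           # no erosion effect on pH within site
    cv <- s$se * sqrt(6) / abs(s$mean)
    list(mean = s$mean[vars], cv = cv[vars], decline = decline[vars])
  })
}

#' Simulation configuration for synthetic erosion-gradient data
#'
#' Defines the sampling layout and effect sizes of the generator. The default
#' layout is 2 sites x 4 erosion levels (`E0`, `EL`, `EM`, `EH`) x 2 transects
#' x 3 plots, i.e. 24 composite samples per site and 48 in total.
#'
#' @param n_sites number of sites (default 2: a loess-region and a
#'   black-soil-region site with distinct soil baselines).
#' @param n_erosion_levels number of erosion intensity classes (default 4).
#' @param n_transects transects (slopes) per site.
#' @param n_plots plots per transect x erosion level.
#' @param sequencing_depth mean library size (reads per sample).
#' @param depth_cv coefficient of variation of the lognormal per-sample
#'   depth, emulating uneven library sizes.
#' @param n_otus size of the OTU pool.
#' @param diversity_decline fraction in `[0, 1)` of effective richness lost
#'   from E0 to EH; drives both rare-OTU loss and evenness decline.
#' @param mf_decline per-variable multiplicative E0 -> EH decline factors for
#'   the soil variables: `NULL` (default) uses the built-in per-site field
#'   baselines, a single number applies to all variables except pH, or a
#'   named vector overrides individual variables.
#' @param soil_noise multiplier on the per-variable lognormal noise CV
#'   (0 switches soil noise off).
#' @param n_blocks number of correlated OTU guilds.
#' @param block_size OTUs per guild.
#' @param block_rho latent within-guild correlation in `[0, 1)`.
#' @param n_hubs hub OTUs per guild (loaded on the guild factor with maximal
#'   weight, so they acquire the highest expected degree downstream).
#' @param latent_sd standard deviation of the per-sample latent
#'   log-abundance fluctuation. The default (0.6) emulates composite plot
#'   samples, whose within-treatment variation is small relative to the
#'   erosion effect.
#' @param seed integer seed; all stages derive their own sub-seeds from it.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$n_sites * cfg$n_erosion_levels * cfg$n_transects * cfg$n_plots
simulation_config <- function(n_sites = 2, n_erosion_levels = 4,
                              n_transects = 2, n_plots = 3,
                              sequencing_depth = 20000, depth_cv = 0.35,
                              n_otus = 400, diversity_decline = 0.25,
                              mf_decline = NULL, soil_noise = 1,
                              n_blocks = 4, block_size = 15,
                              block_rho = 0.7, n_hubs = 2,
                              latent_sd = 0.6, seed = 1) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_erosion_levels = as.integer(n_erosion_levels),
              n_transects = as.integer(n_transects),
              n_plots = as.integer(n_plots),
              sequencing_depth = sequencing_depth, depth_cv = depth_cv,
              n_otus = as.integer(n_otus),
              diversity_decline = diversity_decline,
              mf_decline = mf_decline, soil_noise = soil_noise,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size),
              block_rho = block_rho, n_hubs = as.integer(n_hubs),
              latent_sd = latent_sd, seed = as.integer(seed))
  counts <- c("n_sites", "n_erosion_levels", "n_transects", "n_plots",
              "n_otus", "n_blocks", "block_size")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop_stage("config", "%s must be a count >= 1", f)
  }
  if (cfg$n_hubs < 0 || cfg$n_hubs > cfg$block_size)
    stop_stage("config", "n_hubs must be in [0, block_size]")
  if (cfg$n_erosion_levels > length(EROSION_LEVELS))
    stop_stage("config", "at most %d erosion levels are supported",
               length(EROSION_LEVELS))
  if (cfg$diversity_decline < 0 || cfg$diversity_decline >= 1)
    stop_stage("config", "diversity_decline must be in [0, 1)")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop_stage("config", "block_rho must be in [0, 1)")
  if (cfg$sequencing_depth < 1)
    stop_stage("config", "sequencing_depth must be positive")
  if (cfg$depth_cv < 0) stop_stage("config", "depth_cv must be >= 0")
  if (cfg$soil_noise < 0) stop_stage("config", "soil_noise must be >= 0")
  if (cfg$latent_sd < 0) stop_stage("config", "latent_sd must be >= 0")
  if (cfg$n_blocks * cfg$block_size > cfg$n_otus)
    stop_stage("config", "n_blocks * block_size exceeds n_otus")
  if (!is.null(cfg$mf_decline)) {
    if (any(!is.finite(unlist(cfg$mf_decline))) ||
        any(unlist(cfg$mf_decline) < 0))
      stop_stage("config", "mf_decline factors must be finite and >= 0")
  }
  class(cfg) <- "simulation_config"
  cfg
}

site_names <- function(cfg) {
  base <- c("loess", "blacksoil")
  if (cfg$n_sites <= 2) base[seq_len(cfg$n_sites)]
  else c(base, paste0("site", seq_len(cfg$n_sites - 2) + 2))
}

# design frame: one row per sample/plot
design_frame <- function(cfg) {
  levels_used <- EROSION_LEVELS[seq_len(cfg$n_erosion_levels)]
  d <- expand.grid(plot = paste0("P", seq_len(cfg$n_plots)),
                   erosion = levels_used,
                   transect = paste0("T", seq_len(cfg$n_transects)),
                   site = site_names(cfg),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("site", "erosion", "transect", "plot")]
  d$sample_id <- sprintf("%s_%s_%s_%s", d$site, d$erosion, d$transect, d$plot)
  d$erosion <- factor(d$erosion, levels = EROSION_LEVELS, ordered = TRUE)
  d[, c("sample_id", "site", "erosion", "transect", "plot")]
}

# resolve decline factors for one site as a named vector over SOIL_VARIABLES
resolve_decline <- function(cfg, ref_site) {
  decl <- ref_site$decline
  md <- cfg$mf_decline
  if (is.null(md)) return(decl)
  if (is.numeric(md) && is.null(names(md)) && length(md) == 1) {
    decl[] <- md
    decl["pH"] <- 1
  } else {
    md <- unlist(md)
    unknown <- setdiff(names(md), SOIL_VARIABLES)
    if (length(unknown) > 0)
      stop_stage("config", "mf_decline names not soil variables: %s",
                 paste(unknown, collapse = ", "))
    decl[names(md)] <- md
  }
  decl
}

#' Generate a synthetic soil property table
#'
#' One row per plot with the 13 soil variables. Per-variable means decline
#' multiplicatively (geometric interpolation) from E0 to EH by the configured
#' decline factors; noise is multiplicative lognormal with per-variable CVs
#' derived from field data; pH is near-constant across erosion levels.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` with `sample_id`, design columns and the 13 soil
#'   variables; the imposed per-level means are attached as
#'   `attr(, "true_means")`.
#' @export
generate_soil_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "soil"))
  ref <- soil_reference()
  design <- design_frame(config)
  L <- config$n_erosion_levels
  sites <- site_names(config)
  out <- design
  for (v in SOIL_VARIABLES) out[[v]] <- NA_real_
  true_means <- list()
  for (s in sites) {
    rs <- if (s %in% names(ref)) ref[[s]] else ref[["loess"]]
    decl <- resolve_decline(config, rs)
    # geometric interpolation of the mean across the gradient
    lev_frac <- if (L == 1) 0 else (seq_len(L) - 1) / (L - 1)
    mu <- sapply(SOIL_VARIABLES, function(v) rs$mean[[v]] * decl[[v]]^lev_frac)
    if (L == 1) mu <- matrix(mu, nrow = 1, dimnames = list(NULL, SOIL_VARIABLES))
    rownames(mu) <- EROSION_LEVELS[seq_len(L)]
    true_means[[s]] <- mu
    idx_site <- which(design$site == s)
    for (i in idx_site) {
      lev <- as.character(design$erosion[i])
      for (v in SOIL_VARIABLES) {
        m <- mu[lev, v]
        cv <- rs$cv[[v]] * config$soil_noise
        if (cv <= 0 || m == 0) {
          out[[v]][i] <- m
        } else if (v == "Nm" && m <= 0) {
          out[[v]][i] <- m + stats::rnorm(1, 0, abs(rs$mean[[v]]) * cv)
        } else {
          sdlog <- sqrt(log1p(cv^2))
          out[[v]][i] <- stats::rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
        }
      }
    }
  }
  attr(out, "true_means") <- true_means
  validate_soil_table(out)
  out
}

# latent mean log-abundances per level: lognormal species-abundance
# distribution; erosion zeroes the rarest fraction and widens the
# log-abundance spread (evenness decline). The spread at each level is
# calibrated by root-solving so the Shannon diversity of the level's
# expected relative abundances equals the baseline reduced by the
# configured fraction.
latent_abundance_means <- function(config, base_mu) {
  L <- config$n_erosion_levels
  n <- config$n_otus
  rank_order <- order(base_mu)            # rarest first
  softmax_shannon <- function(mu) {
    p <- exp(mu - max(mu))
    p <- p / sum(p)
    -sum(p * log(p))
  }
  h0 <- softmax_shannon(base_mu)
  lapply(seq_len(L), function(l) {
    frac <- if (L == 1) 0 else config$diversity_decline * (l - 1) / (L - 1)
    mu <- base_mu
    n_drop <- floor(frac * n)
    if (n_drop > 0) mu[rank_order[seq_len(n_drop)]] <- -Inf
    keep <- is.finite(mu)
    target <- h0 * (1 - frac)
    center <- mean(mu[keep])
    h_at <- function(s) softmax_shannon(center + (mu[keep] - center) * s)
    if (h_at(1) > target) {
      s <- tryCatch(
        stats::uniroot(function(s) h_at(s) - target, c(1, 50))$root,
        error = function(e) 1)
      mu[keep] <- center + (mu[keep] - center) * s
    }
    mu
  })
}

#' Generate a synthetic OTU count table
#'
#' Latent per-sample log-abundances are the sum of a lognormal
#' species-abundance baseline, guild factor scores shared within correlated
#' OTU blocks (latent correlation `block_rho`; hub OTUs load with maximal
#' weight), and independent noise. Erosion shifts the species-abundance
#' distribution so realized richness and Shannon diversity decline by roughly
#' `diversity_decline` from E0 to EH. Counts are multinomial draws at a
#' lognormally varying sequencing depth.
#'
#' @param config a [simulation_config()].
#' @return a list with `counts` (samples x OTUs integer matrix) and `truth`
#'   (block memberships, hub identities, per-level latent means, depths).
#' @export
generate_otu_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_hubs * config$n_blocks > config$n_otus)
    stop_stage("config", "n_hubs * n_blocks exceeds n_otus")
  set.seed(derive_seed(config$seed, "otu"))
  design <- design_frame(config)
  n_samp <- nrow(design)
  n <- config$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(n))

  base_mu <- stats::rnorm(n, 0, 2)        # lognormal SAD on the log scale
  mu_levels <- latent_abundance_means(config, base_mu)
  names(mu_levels) <- EROSION_LEVELS[seq_len(config$n_erosion_levels)]

  # guild membership: contiguous blocks drawn from mid-abundance ranks so
  # erosion-driven rare-OTU loss thins guilds progressively
  rank_order <- order(base_mu)            # rarest first
  n_members <- config$n_blocks * config$block_size
  lo <- max(1L, floor(0.35 * n))
  member_pool <- rank_order[seq(lo, min(n, lo + n_members - 1L))]
  if (length(member_pool) < n_members)
    member_pool <- rank_order[seq(n - n_members + 1L, n)]
  blocks <- split(member_pool, rep(seq_len(config$n_blocks),
                                   each = config$block_size))
  hubs <- lapply(blocks, function(b) b[seq_len(config$n_hubs)])

  loading <- rep(0, n)
  block_of <- rep(NA_integer_, n)
  a_member <- sqrt(config$block_rho)
  a_hub <- sqrt(config$block_rho + 0.75 * (1 - config$block_rho))
  for (b in seq_along(blocks)) {
    loading[blocks[[b]]] <- a_member
    loading[hubs[[b]]] <- a_hub
    block_of[blocks[[b]]] <- b
  }

  depth_sdlog <- sqrt(log1p(config$depth_cv^2))
  depths <- round(stats::rlnorm(n_samp,
                                log(config$sequencing_depth) - depth_sdlog^2 / 2,
                                depth_sdlog))
  depths <- pmax(depths, 100)

  counts <- matrix(0L, n_samp, n,
                   dimnames = list(design$sample_id, otu_ids))
  latent_sd <- config$latent_sd
  for (i in seq_len(n_samp)) {
    lev <- as.character(design$erosion[i])
    mu <- mu_levels[[lev]]
    f <- stats::rnorm(config$n_blocks)            # guild factor scores
    eps <- stats::rnorm(n)
    z <- ifelse(is.na(block_of), eps,
                loading * f[ifelse(is.na(block_of), 1L, block_of)] +
                  sqrt(pmax(0, 1 - loading^2)) * eps)
    eta <- mu + latent_sd * z
    p <- exp(eta - max(eta[is.finite(eta)]))
    p[!is.finite(p)] <- 0
    counts[i, ] <- stats::rmultinom(1, depths[i], p / sum(p))[, 1]
  }

  truth <- list(
    blocks = lapply(blocks, function(b) otu_ids[b]),
    hubs = lapply(hubs, function(b) otu_ids[b]),
    level_means = mu_levels,
    depths = stats::setNames(depths, design$sample_id))
  list(counts = counts, truth = truth)
}

#' Generate and write a complete synthetic bundle
#'
#' Produces the OTU table, sample metadata and soil table with consistent
#' sample identifiers, writes them (plus a truth record) to `out_dir` in the
#' pipeline's external formats, and returns the in-memory bundle.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory; created if absent. `NULL` skips writing.
#' @return a list of class `synthetic_bundle` with elements `otu_table`
#'   (samples x OTUs matrix), `metadata`, `soil_table` and `truth`.
#' @export
#' @examples
#' bundle <- generate_dataset(simulation_config(n_otus = 50, seed = 7))
#' dim(bundle$otu_table)
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  soil <- generate_soil_table(config)
  otu <- generate_otu_table(config)
  metadata <- design_frame(config)
  truth <- otu$truth
  truth$soil_level_means <- lapply(attr(soil, "true_means"), function(m)
    as.data.frame(m))
  bundle <- list(otu_table = otu$counts,
                 metadata = metadata,
                 soil_table = soil,
                 truth = truth)
  class(bundle) <- "synthetic_bundle"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop_stage("io", "cannot create directory %s", out_dir)
    }
    write_otu_table(otu$counts, file.path(out_dir, "otu_table.tsv"))
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
    write_soil_table(soil, file.path(out_dir, "soil.tsv"))
    truth_json <- truth
    truth_json$level_means <- lapply(truth_json$level_means, function(x) {
      x[!is.finite(x)] <- NA_real_
      x
    })
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  bundle
}
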