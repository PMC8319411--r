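# Alpha diversity (Shannon, observed species, ACE), Bray-Curtis distances,
# ANOSIM and constrained principal coordinate ordination.

#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i * log(p_i))` in nats, over taxa with positive counts.
#'
#' @param counts non-negative count vector for one sample.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(c(25, 25, 25, 25))  # log(4)
shannon <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    stop_stage("diversity", "counts must be non-negative and complete")
  x <- counts[counts > 0]
  if (length(x) == 0) stop_stage("diversity", "all-zero sample")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Abundance-based coverage estimator (ACE) of richness
#'
#' Chao-Lee estimator: taxa with counts at or below `rare_threshold` form the
#' rare group; `S_ace = S_abund + S_rare / C_ace + F1 / C_ace * gamma^2` with
#' sample coverage `C_ace = 1 - F1 / N_rare` and squared coefficient of
#' variation `gamma^2` truncated at zero. When every rare individual is a
#' singleton the coverage is zero and the estimator is undefined; the
#' bias-corrected Chao1 value is reported instead, flagged via the
#' `"undefined"` attribute.
#'
#' @param counts non-negative count vector for one sample.
#' @param rare_threshold rare/abundant cut (default 10).
#' @return estimated richness; attribute `undefined` is `TRUE` when the
#'   Chao1 fallback was used.
#' @export
#' @examples
#' ace(c(1, 2, 11))  # 4
ace <- function(counts, rare_threshold = 10) {
  if (anyNA(counts) || any(counts < 0))
    stop_stage("diversity", "counts must be non-negative and complete")
  x <- counts[counts > 0]
  if (length(x) == 0) stop_stage("diversity", "all-zero sample")
  rare <- x[x <= rare_threshold]
  s_abund <- sum(x > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) {
    return(structure(as.numeric(s_abund), undefined = FALSE))
  }
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    # all rare individuals are singletons: fall back to bias-corrected Chao1
    f2 <- sum(x == 2)
    chao1 <- length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
    return(structure(chao1, undefined = TRUE))
  }
  fi <- tabulate(rare, nbins = rare_threshold)
  i <- seq_len(rare_threshold)
  gamma2 <- max((s_rare / c_ace) * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  structure(s_abund + s_rare / c_ace + f1 / c_ace * gamma2, undefined = FALSE)
}

#' Per-sample alpha diversity table
#'
#' @param counts samples x OTUs matrix.
#' @param rare_threshold passed to [ace()].
#' @return a `data.frame` with `sample_id`, `shannon`, `observed_species`,
#'   `ace` and `ace_undefined` flag.
#' @export
alpha_diversity <- function(counts, rare_threshold = 10) {
  validate_otu_table(counts)
  rows <- lapply(rownames(counts), function(s) {
    x <- counts[s, ]
    if (sum(x) == 0) stop_stage("diversity", "all-zero sample: %s", s)
    a <- ace(x, rare_threshold)
    data.frame(sample_id = s, shannon = shannon(x),
               observed_species = sum(x > 0),
               ace = as.numeric(a),
               ace_undefined = isTRUE(attr(a, "undefined")))
  })
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)`, computed with [vegan::vegdist()].
#'
#' @param counts samples x OTUs matrix with no all-zero sample.
#' @return symmetric matrix of dissimilarities in `[0, 1]` with zero diagonal.
#' @export
bray_curtis_matrix <- function(counts) {
  validate_otu_table(counts)
  if (nrow(counts) < 2) stop_stage("diversity", "need at least 2 samples")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop_stage("diversity", "all-zero sample: %s",
               rownames(counts)[zero][1])
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

anosim_statistic <- function(rank_d, within) {
  n_pairs <- length(rank_d)
  rb <- mean(rank_d[!within])
  rw <- mean(rank_d[within])
  (rb - rw) / (n_pairs / 2)
}

# all distinct assignments of group labels to positions (multiset
# permutations), as a matrix with one assignment per column
enumerate_assignments <- function(labels) {
  rec <- function(lab) {
    if (length(lab) <= 1) return(matrix(lab, nrow = length(lab)))
    out <- NULL
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      sub <- rec(rest)
      out <- cbind(out, rbind(u, sub))
    }
    out
  }
  rec(sort(labels))
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All pairwise dissimilarities are midranked;
#' `R = (mean between-rank - mean within-rank) / (n(n-1)/4)`, so `R` lies in
#' `[-1, 1]` and equals 1 under complete separation. The p-value is
#' `(1 + #permuted R >= observed R) / (1 + n_permutations)` under random
#' relabelling, or the exact enumeration probability when `exact = TRUE`.
#' Pairwise two-group comparisons are Bonferroni-adjusted.
#'
#' @param dist_matrix square symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups of >= 2).
#' @param n_permutations permutation count (ignored when `exact = TRUE`).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct label assignments (small designs only).
#' @param pairwise also run all two-group comparisons.
#' @return an `anosim_result` list with `R`, `p_value`, `n_permutations`,
#'   and a `pairwise` table with Bonferroni-adjusted p-values.
#' @export
anosim <- function(dist_matrix, groups, n_permutations = 9999, seed = 1,
                   exact = FALSE, pairwise = TRUE) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop_stage("anosim", "groups length must match the distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop_stage("anosim", "need at least 2 groups")
  if (any(tab < 2))
    stop_stage("anosim", "singleton group: %s", names(tab)[tab < 2][1])
  iu <- which(upper.tri(d))
  rank_d <- rank(d[iu])                     # midranks
  pair_i <- row(d)[iu]
  pair_j <- col(d)[iu]
  within_of <- function(g) g[pair_i] == g[pair_j]
  r_obs <- anosim_statistic(rank_d, within_of(groups))

  if (exact) {
    perms <- enumerate_assignments(groups)
    r_perm <- apply(perms, 2, function(g) anosim_statistic(rank_d, within_of(g)))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- ncol(perms)
  } else {
    set.seed(seed)
    r_perm <- replicate(n_permutations, {
      g <- sample(groups)
      anosim_statistic(rank_d, within_of(g))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }

  pairwise_tab <- NULL
  if (pairwise && length(tab) > 2) {
    combos <- utils::combn(names(tab), 2)
    n_comp <- ncol(combos)
    rows <- lapply(seq_len(n_comp), function(k) {
      keep <- groups %in% combos[, k]
      sub <- anosim(d[keep, keep, drop = FALSE], groups[keep],
                    n_permutations = n_permutations,
                    seed = derive_seed(seed, paste(combos[, k], collapse = "-")),
                    exact = exact, pairwise = FALSE)
      data.frame(group_a = combos[1, k], group_b = combos[2, k],
                 R = sub$R, p_value = sub$p_value,
                 p_adjusted = min(1, sub$p_value * n_comp))
    })
    pairwise_tab <- do.call(rbind, rows)
  }
  structure(list(R = r_obs, p_value = p, n_permutations = n_used,
                 exact = exact, pairwise = pairwise_tab),
            class = "anosim_result")
}

#' Constrained principal coordinate analysis (CPCoA)
#'
#' Principal-coordinate embedding of a dissimilarity matrix followed by
#' redundancy analysis on a categorical constraint, via [vegan::capscale()].
#' Negative PCoA eigenvalues are dropped before the constrained step.
#' `proportion_explained` is the constrained share of the total
#' (positive-eigenvalue) inertia; significance by permutation of the
#' constraint labels.
#'
#' @param dist_matrix square symmetric dissimilarity matrix.
#' @param constraint factor with >= 2 levels, one per sample.
#' @param n_permutations permutations for the significance test.
#' @param seed integer seed.
#' @return a `cpcoa_result` list with `coordinates` (constrained sample
#'   scores), `proportion_explained` and `p_value`.
#' @export
cpcoa <- function(dist_matrix, constraint, n_permutations = 999, seed = 1) {
  d <- as.matrix(dist_matrix)
  constraint <- factor(constraint)
  if (length(constraint) != nrow(d))
    stop_stage("cpcoa", "constraint length must match the distance matrix")
  if (nlevels(constraint) < 2)
    stop_stage("cpcoa", "constraint must have at least 2 levels")
  df <- data.frame(constraint = constraint)
  cap <- suppressWarnings(
    vegan::capscale(stats::as.dist(d) ~ constraint, data = df))
  prop <- cap$CCA$tot.chi / cap$tot.chi
  set.seed(seed)
  pt <- vegan::anova.cca(cap, permutations = n_permutations)
  scores <- vegan::scores(cap, display = "sites",
                          choices = seq_len(min(2, cap$CCA$rank)))
  structure(list(coordinates = scores,
                 proportion_explained = unname(prop),
                 p_value = pt$`Pr(>F)`[1],
                 n_permutations = n_permutations),
            class = "cpcoa_result")
}
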