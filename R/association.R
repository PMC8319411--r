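# Statistical layer relating multifunctionality to diversity, network
# metrics and soil variables: OLS regression, Pearson correlation tables,
# Kruskal-Wallis with rank-sum post hoc, two-way ANOVA with a blocking
# factor, and redundancy analysis.

#' Ordinary least squares regression of y on x
#'
#' @param x predictor vector (not constant).
#' @param y response vector of the same length.
#' @param predictor,response names carried into the result.
#' @return one-row `data.frame`: `predictor`, `response`, `slope`,
#'   `intercept`, `r_squared`, `p_value` (two-sided t-test on the slope,
#'   `n - 2` df), `n`.
#' @export
linear_regression <- function(x, y, predictor = "x", response = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_stage("regression", "need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop_stage("regression", "constant predictor")
  if (stats::sd(y) == 0) {
    return(data.frame(predictor = predictor, response = response,
                      slope = 0, intercept = y[1], r_squared = 0,
                      p_value = 1, n = n, stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # near-perfect fits warn in summary.lm
  data.frame(predictor = predictor, response = response,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared,
             p_value = if (sm$sigma == 0) 0 else sm$coefficients[2, 4],
             n = n, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations between two tables
#'
#' For every (column of `a`, column of `b`) pair: Pearson r and the
#' two-sided p-value from the t-distribution. Pairs involving a constant
#' column are returned as `NA` with `flag = "constant"`.
#'
#' @param a,b numeric data frames or matrices with aligned rows (n >= 3).
#' @return long-format `data.frame`: `var_a`, `var_b`, `r`, `p_value`, `n`,
#'   `flag`.
#' @export
pearson_matrix <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (nrow(a) != nrow(b)) stop_stage("pearson", "tables must have aligned rows")
  if (nrow(a) < 3) stop_stage("pearson", "need at least 3 samples")
  rows <- list()
  for (va in names(a)) {
    for (vb in names(b)) {
      x <- a[[va]]; y <- b[[vb]]
      n <- sum(is.finite(x) & is.finite(y))
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          var_a = va, var_b = vb, r = NA_real_, p_value = NA_real_,
          n = n, flag = "constant", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1]] <- data.frame(
        var_a = va, var_b = vb, r = unname(ct$estimate),
        p_value = ct$p.value, n = n, flag = "", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Kruskal-Wallis test with rank-sum post hoc letters
#'
#' Midrank-corrected H statistic with a chi-square p-value (k - 1 df) via
#' [stats::kruskal.test()]. Post hoc: pairwise Wilcoxon rank-sum tests with
#' Holm adjustment, summarized as a compact letter display (groups sharing a
#' letter are not significantly different at `alpha`).
#'
#' @param values numeric response.
#' @param groups group label per value (>= 2 groups of >= 2).
#' @param alpha level for the letter display.
#' @return a `group_test` list: `test`, `statistic`, `p_value`, `letters`,
#'   `pairwise` (Holm-adjusted p matrix).
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop_stage("kruskal", "need at least 2 groups")
  if (any(tab < 2))
    stop_stage("kruskal", "singleton group: %s", names(tab)[tab < 2][1])
  kt <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm",
                                exact = FALSE))
  gn <- levels(groups)
  pmat <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in rownames(pw$p.value)) {
    for (j in colnames(pw$p.value)) {
      if (!is.na(pw$p.value[i, j])) {
        pmat[i, j] <- pmat[j, i] <- pw$p.value[i, j]
      }
    }
  }
  signif_mat <- !is.na(pmat) & pmat <= alpha
  letters_out <- letter_display(signif_mat)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 letters = letters_out, pairwise = pmat),
            class = "group_test")
}

#' Two-way ANOVA with a blocking factor
#'
#' Fixed-effects ANOVA of `response ~ block + site * erosion`: F and p for
#' site, erosion and their interaction, with the transect/slope entering as
#' an additive blocking factor. Post hoc: Tukey HSD over erosion levels
#' within each site, summarized as compact letters.
#'
#' @param response numeric vector.
#' @param site,erosion factors of interest.
#' @param block blocking factor (transect), or `NULL`.
#' @param alpha level for the letter display.
#' @return a `group_test` list: `test`, `table` (term, df, F, p),
#'   `letters_by_site`.
#' @export
two_way_anova <- function(response, site, erosion, block = NULL,
                          alpha = 0.05) {
  if (stats::sd(response) == 0)
    stop_stage("anova", "constant response: zero residual variance")
  site <- factor(site); erosion <- factor(erosion)
  dat <- data.frame(response = response, site = site, erosion = erosion)
  if (!is.null(block)) {
    dat$block <- factor(block)
    fit <- stats::aov(response ~ block + site * erosion, data = dat)
  } else {
    fit <- stats::aov(response ~ site * erosion, data = dat)
  }
  if (fit$df.residual == 0)
    stop_stage("anova", "saturated design: no residual degrees of freedom")
  ali <- alias(fit)
  if (!is.null(ali$Complete) && nrow(ali$Complete) > 0)
    stop_stage("anova", "rank-deficient design; aliased terms: %s",
               paste(rownames(ali$Complete), collapse = ", "))
  sm <- summary(fit)[[1]]
  terms_tab <- data.frame(term = trimws(rownames(sm)),
                          df = sm$Df, F = sm$`F value`, p = sm$`Pr(>F)`,
                          stringsAsFactors = FALSE)
  letters_by_site <- lapply(split(dat, dat$site), function(d) {
    if (nlevels(droplevels(d$erosion)) < 2 || stats::sd(d$response) == 0)
      return(NULL)
    d$erosion <- droplevels(d$erosion)
    fit1 <- stats::aov(response ~ erosion, data = d)
    tk <- stats::TukeyHSD(fit1)$erosion
    gn <- levels(d$erosion)
    pmat <- matrix(FALSE, length(gn), length(gn), dimnames = list(gn, gn))
    for (row in rownames(tk)) {
      gg <- strsplit(row, "-", fixed = TRUE)[[1]]
      sig <- tk[row, "p adj"] <= alpha
      pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- sig
    }
    letter_display(pmat)
  })
  structure(list(test = "two_way_anova", table = terms_tab,
                 letters_by_site = letters_by_site),
            class = "group_test")
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a multivariate response on explanatory
#' variables via [vegan::rda()]. `constrained_proportion` is the share of
#' total variance captured by the fitted (constrained) axes; significance
#' by permutation of the sample rows.
#'
#' @param response_matrix samples x variables numeric matrix/data frame.
#' @param explanatory_matrix samples x predictors numeric matrix/data frame
#'   (full column rank).
#' @param n_permutations permutations for the significance test.
#' @param seed integer seed.
#' @return an `rda_result` list: `constrained_proportion`, `eigenvalues`,
#'   `p_value`.
#' @export
redundancy_analysis <- function(response_matrix, explanatory_matrix,
                                n_permutations = 999, seed = 1) {
  y <- as.matrix(response_matrix)
  x <- as.data.frame(explanatory_matrix)
  if (nrow(y) != nrow(x)) stop_stage("rda", "tables must have aligned rows")
  xm <- stats::model.matrix(~ ., data = x)
  if (qr(xm)$rank < ncol(xm))
    stop_stage("rda", "explanatory variables are collinear to rank deficiency")
  fit <- vegan::rda(y ~ ., data = x)
  cca_chi <- if (is.null(fit$CCA)) 0 else fit$CCA$tot.chi
  ca_chi <- if (is.null(fit$CA) || is.null(fit$CA$tot.chi)) 0 else fit$CA$tot.chi
  prop <- cca_chi / fit$tot.chi
  p_value <- NA_real_
  if (ca_chi / fit$tot.chi > 1e-12) {
    set.seed(seed)
    pt <- vegan::anova.cca(fit, permutations = n_permutations)
    p_value <- pt$`Pr(>F)`[1]
  }
  structure(list(constrained_proportion = unname(prop),
                 eigenvalues = if (is.null(fit$CCA)) numeric(0) else fit$CCA$eig,
                 unconstrained_proportion = unname(ca_chi / fit$tot.chi),
                 p_value = p_value),
            class = "rda_result")
}
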