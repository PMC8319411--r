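# Spearman co-occurrence matrix construction, Benjamini-Hochberg edge
# significance, and random-matrix-theory (RMT) selection of the correlation
# threshold from the eigenvalue nearest-neighbour spacing distribution.

#' Filter OTUs by mean relative abundance
#'
#' Keeps OTUs whose mean per-sample relative abundance strictly exceeds
#' `min_rel_abundance` (default 1e-4, i.e. the 0.01% rule). The alternative
#' `"pooled"` method uses the relative abundance of pooled totals instead.
#' OTU order is preserved.
#'
#' @param counts samples x OTUs matrix.
#' @param min_rel_abundance strict retention threshold.
#' @param method `"mean"` or `"pooled"`.
#' @return the filtered samples x OTUs matrix.
#' @export
filter_otus <- function(counts, min_rel_abundance = 1e-4,
                        method = c("mean", "pooled")) {
  validate_otu_table(counts)
  method <- match.arg(method)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop_stage("filter", "all-zero sample: %s",
               rownames(counts)[totals == 0][1])
  rel <- counts / totals
  abundance <- switch(method,
                      mean = colMeans(rel),
                      pooled = colSums(counts) / sum(counts))
  keep <- abundance > min_rel_abundance
  if (!any(keep))
    stop_stage("filter",
               "no OTU exceeds relative abundance %g; lower the threshold",
               min_rel_abundance)
  counts[, keep, drop = FALSE]
}

#' Spearman correlation matrix with significance
#'
#' Midrank-based Spearman rho over all OTU pairs, two-sided p-values from
#' the t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`, and
#' Benjamini-Hochberg q-values over the upper-triangle p-values. Pairs
#' involving a constant OTU are undefined and recorded as `NA` (they can
#' never become edges).
#'
#' @param counts samples x OTUs matrix with >= 4 samples.
#' @return a `correlation_result` list with symmetric matrices `rho`, `p`
#'   and `q`.
#' @export
spearman_matrix <- function(counts) {
  validate_otu_table(counts)
  n <- nrow(counts)
  if (n < 4) stop_stage("network", "need at least 4 samples")
  constant <- apply(counts, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(counts, method = "spearman"))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- 1
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  diag(p) <- 0
  iu <- upper.tri(p)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  q[iu] <- bh_fdr(p[iu])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  structure(list(rho = rho, p = p, q = q, n_samples = n),
            class = "correlation_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the original order. Missing values stay missing and do not
#' count toward `m`.
#'
#' @param pvalues vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop_stage("fdr", "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# --- RMT threshold selection -------------------------------------------------

wigner_cdf <- function(d) 1 - exp(-pi * d^2 / 4)
poisson_cdf <- function(d) 1 - exp(-d)

# chi-square goodness of fit of unit-mean spacings against a spacing law.
# Histogram bins of width 0.1 on [0, 3] plus an open tail bin; consecutive
# bins are merged until each carries an expected frequency of at least 5
# (Cochran's rule) so the test keeps power at the spectrum sizes typical of
# a filtered OTU table.
spacing_gof <- function(spacings, cdf, bin_width = 0.1, upper = 3,
                        min_expected = 5) {
  breaks <- c(seq(0, upper, by = bin_width), Inf)
  obs <- as.numeric(table(cut(spacings, breaks = breaks, right = TRUE,
                              include.lowest = TRUE)))
  probs <- c(diff(cdf(utils::head(breaks, -1))), 1 - cdf(upper))
  expected <- length(spacings) * probs
  merged_obs <- c(); merged_exp <- c(); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expected[i]
    if (ce >= min_expected) {
      merged_obs <- c(merged_obs, co); merged_exp <- c(merged_exp, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0 && length(merged_obs) > 0) {
    k <- length(merged_obs)
    merged_obs[k] <- merged_obs[k] + co
    merged_exp[k] <- merged_exp[k] + ce
  }
  if (length(merged_obs) < 3) return(NA_real_)
  stat <- sum((merged_obs - merged_exp)^2 / merged_exp)
  stats::pchisq(stat, df = length(merged_obs) - 1, lower.tail = FALSE)
}

# unfolded nearest-neighbour spacings of the eigenvalues of a thresholded
# correlation matrix: cubic polynomial fit to the empirical cumulative
# spectral density, eigenvalues mapped through the fit, successive
# differences normalized to unit mean. Degenerate (tied) eigenvalues are
# collapsed first so zeroed-out blocks do not swamp the spacing law, and
# the largest 5% of distinct eigenvalues (Perron/module outliers, which a
# cubic cannot track) are dropped before the fit.
unfolded_spacings <- function(ev, min_distinct = 20, tol = 1e-8,
                              trim_upper = 0.05) {
  ev <- sort(ev)
  distinct <- ev[c(TRUE, diff(ev) > tol)]
  m0 <- length(distinct)
  k <- max(1L, round(trim_upper * m0))
  distinct <- distinct[seq_len(m0 - k)]
  m <- length(distinct)
  if (m < min_distinct) return(NULL)
  f_emp <- seq_len(m) / m
  fit <- stats::lm(f_emp ~ poly(distinct, 3, raw = TRUE))
  unfolded <- m * stats::predict(fit)
  d <- diff(unfolded)
  d <- d[d > 0]
  if (length(d) < min_distinct - 1) return(NULL)
  d / mean(d)
}

#' RMT scan for the co-occurrence correlation threshold
#'
#' For each candidate threshold, correlations below it (in absolute value)
#' are zeroed, the eigenvalue spectrum of the resulting matrix is unfolded,
#' and the nearest-neighbour spacing distribution is tested against the
#' Poisson law `exp(-d)` (uncorrelated, non-random structure) and the
#' Wigner-Dyson surmise (Gaussian orthogonal ensemble, random noise). The
#' selected threshold is the smallest one opening a run of at least two
#' consecutive grid points whose Poisson fit is accepted (chi-square
#' p > 0.05): the point where the spectrum transitions from GOE to Poisson
#' statistics.
#'
#' @param corr a `correlation_result` from [spearman_matrix()], or a plain
#'   symmetric correlation matrix.
#' @param grid candidate thresholds (default `seq(0.30, 0.99, 0.01)`).
#' @param accept_alpha acceptance level for the Poisson fit.
#' @param fallback when no stable accepted run exists, fall back to the
#'   smallest singly-accepted threshold, then to the threshold with the
#'   best Poisson fit, instead of erroring; the rule used is recorded in
#'   the result's `selection_rule`.
#' @return an `rmt_scan` list with the per-threshold table (`threshold`,
#'   `poisson_p`, `goe_p`, `n_spacings`), the `selected` threshold and the
#'   `selection_rule` applied (`"stable_run"`, `"single_accept"` or
#'   `"best_fit"`).
#' @export
rmt_select_threshold <- function(corr, grid = seq(0.30, 0.99, by = 0.01),
                                 accept_alpha = 0.05, fallback = FALSE) {
  rho <- if (inherits(corr, "correlation_result")) corr$rho else corr
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  p <- nrow(rho)
  if (p < 20)
    stop_stage("rmt", "need at least 20 retained OTUs (%d given)", p)
  rho0 <- rho
  rho0[is.na(rho0)] <- 0
  diag(rho0) <- 1
  if (max(abs(rho0[upper.tri(rho0)])) < 1e-12)
    stop_stage("rmt", "insufficient spectral variation: identity correlation matrix")

  scan <- data.frame(threshold = grid, poisson_p = NA_real_,
                     goe_p = NA_real_, n_spacings = NA_integer_)
  for (k in seq_along(grid)) {
    a <- rho0
    a[abs(a) < grid[k]] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    sp <- unfolded_spacings(ev)
    if (is.null(sp)) next
    scan$n_spacings[k] <- length(sp)
    scan$poisson_p[k] <- spacing_gof(sp, poisson_cdf)
    scan$goe_p[k] <- spacing_gof(sp, wigner_cdf)
  }
  accepted <- !is.na(scan$poisson_p) & scan$poisson_p > accept_alpha
  selected <- NA_real_
  rule <- "stable_run"
  run <- rle(accepted)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  good <- which(run$values & run$lengths >= 2)
  if (length(good) > 0) selected <- grid[starts[good[1]]]
  if (is.na(selected) && fallback) {
    if (any(accepted)) {
      selected <- grid[which(accepted)[1]]
      rule <- "single_accept"
    } else if (any(is.finite(scan$poisson_p))) {
      selected <- grid[which.max(scan$poisson_p)]
      rule <- "best_fit"
    }
  }
  if (is.na(selected))
    stop_stage("rmt",
               "no threshold passes the Poisson spacing test; choose one manually")
  structure(list(scan = scan, selected = selected,
                 accept_alpha = accept_alpha, selection_rule = rule),
            class = "rmt_scan")
}
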