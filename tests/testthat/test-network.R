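# OTU filtering, Spearman correlation, FDR adjustment and RMT threshold
# selection.

test_that("the 0.01% filter uses a strict mean relative abundance rule", {
  # 4 samples at depth 10000: OTU a sits exactly at 1e-4, OTU b just above
  counts <- cbind(a = rep(1L, 4), b = rep(2L, 4), c = rep(9996L, 4),
                  d = rep(1L, 4))
  rownames(counts) <- paste0("s", 1:4)
  kept <- filter_otus(counts, 1e-4)
  expect_false("a" %in% colnames(kept))    # exactly at threshold: removed
  expect_true("b" %in% colnames(kept))     # 2e-4: kept
  # threshold zero keeps everything present in at least one sample
  kept0 <- filter_otus(counts, min_rel_abundance = 1e-12)
  expect_equal(ncol(kept0), 4)
  expect_error(filter_otus(counts, 0.9999), "no OTU")
})

test_that("filter preserves OTU order and supports pooled totals", {
  set.seed(1)
  counts <- matrix(rpois(200, 5), 10,
                   dimnames = list(paste0("s", 1:10), paste0("o", 1:20)))
  storage.mode(counts) <- "integer"
  kept <- filter_otus(counts, 1e-3)
  expect_identical(colnames(kept),
                   intersect(colnames(counts), colnames(kept)))
  expect_silent(filter_otus(counts, 1e-3, method = "pooled"))
})

test_that("spearman matrix matches rank formula and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  counts <- cbind(a = x, b = y, c = 5:1)
  rownames(counts) <- paste0("s", 1:5)
  storage.mode(counts) <- "integer"
  res <- spearman_matrix(counts)
  expect_equal(res$rho["a", "b"], 0.8, tolerance = 1e-12)  # 1 - 6*4/(5*24)
  expect_equal(res$rho["a", "c"], -1)
  expect_equal(unname(diag(res$rho)), rep(1, 3))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  # monotone pair
  counts2 <- cbind(u = 1:6, v = c(2L, 4L, 5L, 7L, 8L, 9L))
  rownames(counts2) <- paste0("s", 1:6)
  storage.mode(counts2) <- "integer"
  expect_equal(spearman_matrix(counts2)$rho["u", "v"], 1)
})

test_that("constant OTUs give missing correlations, never edges", {
  counts <- cbind(a = c(1L, 2L, 3L, 4L, 5L), b = rep(3L, 5),
                  c = c(5L, 3L, 1L, 2L, 4L))
  rownames(counts) <- paste0("s", 1:5)
  res <- spearman_matrix(counts)
  expect_true(is.na(res$rho["a", "b"]))
  net <- build_network(res, 0.5, fdr_alpha = 1)
  expect_false("b" %in% net$nodes)
})

test_that("bh_fdr matches the step-up hand computation and oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    # monotone: q >= p, order preserved after sorting
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("edges require both the threshold and the q-value condition", {
  rho <- diag(4)
  dimnames(rho) <- list(paste0("o", 1:4), paste0("o", 1:4))
  rho["o1", "o2"] <- rho["o2", "o1"] <- 0.95
  rho["o1", "o3"] <- rho["o3", "o1"] <- 0.90   # strong but non-significant
  rho["o3", "o4"] <- rho["o4", "o3"] <- -0.92  # negative edges admitted
  q <- matrix(0.001, 4, 4, dimnames = dimnames(rho)); diag(q) <- 0
  q["o1", "o3"] <- q["o3", "o1"] <- 0.2
  p <- q
  corr <- structure(list(rho = rho, p = p, q = q, n_samples = 10),
                    class = "correlation_result")
  net <- build_network(corr, 0.84, fdr_alpha = 0.05)
  key <- paste(net$edges$otu_a, net$edges$otu_b)
  expect_setequal(key, c("o1 o2", "o3 o4"))
  expect_true(all(abs(net$edges$rho) >= net$threshold_used))
  expect_true(all(net$edges$q < 0.05))
  # positive-only variant drops the negative edge
  net_pos <- build_network(corr, 0.84, positive_only = TRUE)
  expect_equal(nrow(net_pos$edges), 1)
  # nothing passes: empty network
  net0 <- build_network(corr, 0.99)
  expect_equal(length(net0$nodes), 0)
})

test_that("raising the threshold never adds edges", {
  b <- generate_dataset(small_config(seed = 19, n_sites = 1))
  corr <- spearman_matrix(filter_otus(b$otu_table))
  sizes <- sapply(seq(0.4, 0.9, 0.1), function(th)
    nrow(build_network(corr, th)$edges))
  expect_true(all(diff(sizes) <= 0))
})

rmt_block_matrix <- function(seed, p = 60, n_blocks = 3, block_size = 12) {
  set.seed(seed)
  sgn <- matrix(0, p, p)
  sgn[upper.tri(sgn)] <- sample(c(-0.4, 0.4), p * (p - 1) / 2, replace = TRUE)
  rho <- sgn + t(sgn)
  for (b in seq_len(n_blocks) - 1) {
    idx <- b * block_size + seq_len(block_size)
    blk <- matrix(0.9 + runif(block_size^2, -0.04, 0.04), block_size)
    rho[idx, idx] <- (blk + t(blk)) / 2
  }
  diag(rho) <- 1
  dimnames(rho) <- list(paste0("o", 1:p), paste0("o", 1:p))
  rho
}

test_that("rmt selection lands between noise and signal correlations", {
  # signal blocks near 0.9, dense noise bounded by 0.4: the spacing law
  # transition must be detected strictly above the noise level
  sel <- rmt_select_threshold(rmt_block_matrix(1))$selected
  expect_gt(sel, 0.40)
  expect_lte(sel, 0.90)
})

test_that("rmt scan is reproducible and rejects degenerate spectra", {
  rho <- rmt_block_matrix(2)
  s1 <- rmt_select_threshold(rho)
  s2 <- rmt_select_threshold(rho)
  expect_identical(s1$selected, s2$selected)
  expect_true(s1$selected %in% s1$scan$threshold)
  # selection is reproducible from the stored p-values
  acc <- !is.na(s1$scan$poisson_p) & s1$scan$poisson_p > s1$accept_alpha
  runs <- rle(acc)
  first <- which(runs$values & runs$lengths >= 2)[1]
  start <- cumsum(runs$lengths)[first] - runs$lengths[first] + 1
  expect_equal(s1$scan$threshold[start], s1$selected)

  id <- diag(30)
  dimnames(id) <- list(paste0("o", 1:30), paste0("o", 1:30))
  expect_error(rmt_select_threshold(id), "insufficient spectral variation")
  expect_error(rmt_select_threshold(diag(5)), "at least 20")
})
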