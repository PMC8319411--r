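# Alpha diversity closed forms, Bray-Curtis, ANOSIM (with exhaustive
# oracle) and constrained ordination.

test_that("shannon matches closed forms and direct summation", {
  expect_equal(shannon(c(25, 25, 25, 25)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(100)), 0)
  # direct summation: -sum((i/6) log(i/6)) for counts 1, 2, 3
  expect_equal(shannon(c(1, 2, 3)),
               -sum((1:3) / 6 * log((1:3) / 6)), tolerance = 1e-12)
  expect_equal(shannon(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_equal(shannon(c(0, 5, 0, 5)), log(2))   # zeros ignored
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("shannon is invariant under common count rescaling", {
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(30, 5)
    x[x == 0] <- 1
    k <- sample(2:50, 1)
    expect_equal(shannon(x), shannon(x * k), tolerance = 1e-12)
  }
})

test_that("ace reproduces the Chao-Lee form and its conventions", {
  # S_abund = 1, S_rare = 2, N_rare = 3, F1 = 1, C_ace = 2/3, gamma2 = 0
  expect_equal(as.numeric(ace(c(1, 2, 11))), 4.0, tolerance = 1e-12)
  # all abundant: ACE = observed richness
  a <- ace(c(20, 30, 40))
  expect_equal(as.numeric(a), 3)
  expect_false(attr(a, "undefined"))
  # all-singleton rare group: coverage zero, flagged Chao1 fallback
  a <- ace(c(1, 1))
  expect_true(attr(a, "undefined"))
  expect_equal(as.numeric(a), 2 + 1 * 0 / 2 + 1)  # bias-corrected Chao1 = 3
})

test_that("ace is bounded below by observed richness and matches vegan", {
  set.seed(7)
  for (i in 1:25) {
    x <- rpois(60, 3)
    if (sum(x) == 0 || sum(x == 1) == sum(x[x <= 10] > 0)) next
    a <- ace(x)
    if (!attr(a, "undefined")) {
      expect_gte(as.numeric(a) + 1e-9, sum(x > 0))
      expect_equal(as.numeric(a),
                   unname(vegan::estimateR(x)["S.ACE"]), tolerance = 1e-6)
    }
  }
})

test_that("bray-curtis matches hand computation and bounds", {
  m <- rbind(s1 = c(2L, 2L), s2 = c(1L, 3L))
  colnames(m) <- c("o1", "o2")
  d <- bray_curtis_matrix(m)
  expect_equal(d["s1", "s2"], 0.25)        # (1+1)/(4+4)
  m2 <- rbind(a = c(3L, 0L), b = c(0L, 5L), c = c(3L, 0L))
  colnames(m2) <- c("o1", "o2")
  d2 <- bray_curtis_matrix(m2)
  expect_equal(d2["a", "b"], 1)            # disjoint support
  expect_equal(d2["a", "c"], 0)            # identical
  expect_equal(unname(diag(d2)), rep(0, 3))
  expect_equal(d2, t(d2), tolerance = 1e-12)
  expect_true(all(d2 >= 0 & d2 <= 1))
})

test_that("anosim recovers closed-form extremes", {
  # maximal separation: all between-distances exceed all within-distances
  d <- matrix(10, 6, 6)
  d[1:3, 1:3] <- matrix(runif(9, 0.1, 0.2), 3)
  d[4:6, 4:6] <- matrix(runif(9, 0.1, 0.2), 3)
  d <- (d + t(d)) / 2; diag(d) <- 0
  g <- rep(c("x", "y"), each = 3)
  expect_equal(anosim(d, g, exact = TRUE)$R, 1, tolerance = 1e-12)
  # fully tied distances: R = 0
  d0 <- matrix(1, 6, 6); diag(d0) <- 0
  expect_equal(anosim(d0, g, exact = TRUE)$R, 0, tolerance = 1e-12)
})

test_that("exact anosim p equals exhaustive enumeration for 3+3", {
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(rnorm(6 * 4), 6)
    d <- as.matrix(dist(x))
    g <- rep(c("u", "v"), each = 3)
    res <- anosim(d, g, exact = TRUE)
    expect_equal(res$n_permutations, 20)   # choose(6, 3) distinct labellings
    expect_equal(res$p_value, oracle_anosim_exact_p(d, g), tolerance = 1e-12)
    expect_equal(res$R, oracle_anosim_r(d, g), tolerance = 1e-12)
  }
})

test_that("anosim R agrees with vegan and is rank-invariant", {
  set.seed(3)
  x <- matrix(rpois(12 * 8, 10), 12)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b", "c"), each = 4)
  r_pkg <- anosim(d, g, n_permutations = 99, seed = 1)$R
  r_veg <- vegan::anosim(as.dist(d), g, permutations = 9)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-12)
  # monotone transform of distances leaves the rank-based R unchanged
  expect_equal(anosim(d^2, g, n_permutations = 99, seed = 1)$R, r_pkg,
               tolerance = 1e-12)
})

test_that("anosim rejects degenerate groupings and adjusts pairwise", {
  d <- as.matrix(dist(matrix(rnorm(20), 10)))
  expect_error(anosim(d, c("a", rep("b", 9))), "singleton")
  g <- rep(c("a", "b", "c"), c(4, 3, 3))
  res <- anosim(d, g, n_permutations = 49, seed = 2)
  expect_equal(nrow(res$pairwise), 3)
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, res$pairwise$p_value * 3))
})

test_that("cpcoa explains everything for duplicated group points", {
  x <- rbind(matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE),
             matrix(rep(c(5, 1), 3), ncol = 2, byrow = TRUE))
  d <- as.matrix(dist(x))
  res <- cpcoa(d, rep(c("g1", "g2"), each = 3), n_permutations = 99, seed = 1)
  expect_equal(res$proportion_explained, 1, tolerance = 1e-9)
})

test_that("cpcoa proportion equals between-group share of embedded inertia", {
  set.seed(9)
  x <- matrix(rnorm(6 * 3), 6)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 3)
  res <- cpcoa(d, g, n_permutations = 99, seed = 1)
  # brute force on the principal-coordinate embedding
  emb <- cmdscale(d, k = 5)
  center <- colMeans(emb)
  fitted <- apply(emb, 2, function(col) stats::ave(col, g))
  ss_between <- sum(scale(fitted, center = center, scale = FALSE)^2)
  ss_total <- sum(scale(emb, center = center, scale = FALSE)^2)
  expect_equal(res$proportion_explained, ss_between / ss_total,
               tolerance = 1e-9)
})

test_that("cpcoa proportion is invariant to sample order", {
  set.seed(10)
  x <- matrix(rnorm(12 * 4), 12)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b", "c"), each = 4)
  p1 <- cpcoa(d, g, n_permutations = 49, seed = 1)$proportion_explained
  perm <- sample(12)
  p2 <- cpcoa(d[perm, perm], g[perm],
              n_permutations = 49, seed = 1)$proportion_explained
  expect_equal(p1, p2, tolerance = 1e-9)
  expect_error(cpcoa(d, rep("a", 12)), "2 levels")
})

test_that("alpha_diversity assembles a consistent per-sample table", {
  b <- generate_dataset(small_config(seed = 17, n_sites = 1))
  ad <- alpha_diversity(b$otu_table)
  expect_equal(ad$sample_id, rownames(b$otu_table))
  expect_true(all(ad$shannon <= log(ad$observed_species + 1e-12)))
  expect_true(all(ad$observed_species <= ncol(b$otu_table)))
  ok <- !ad$ace_undefined
  expect_true(all(ad$ace[ok] >= ad$observed_species[ok] - 1e-9))
})
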