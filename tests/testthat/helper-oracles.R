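# Independent brute-force oracles for graph metrics and statistics, used to
# cross-check the package implementations. Everything here works from first
# principles on adjacency matrices and raw formulas.

# adjacency matrix from a coocnet
net_adjacency <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    for (k in seq_len(nrow(net$edges))) {
      i <- net$edges$otu_a[k]; j <- net$edges$otu_b[k]
      a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

# all-pairs shortest path lengths by breadth-first search
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[d[s, nxt] == Inf & nxt != s]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# number of shortest s-t paths = walks of minimal length (A^d)[s, t]
oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  maxd <- max(d[is.finite(d)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- a
  if (maxd >= 2) for (k in 2:maxd) pows[[k]] <- pows[[k - 1]] %*% a
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(d[s, t])) sigma[s, t] <- pows[[d[s, t]]][s, t]
  }
  sigma
}

# normalized shortest-path betweenness of every node
oracle_betweenness <- function(a) {
  n <- nrow(a)
  if (n < 3) return(rep(0, n))
  d <- oracle_distances(a)
  sigma <- oracle_path_counts(a, d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    out[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  out
}

# harmonic closeness normalized by n - 1
oracle_closeness <- function(a) {
  n <- nrow(a)
  if (n < 2) return(rep(0, n))
  d <- oracle_distances(a)
  sapply(seq_len(n), function(v) sum(1 / d[v, -v]) / (n - 1))
}

oracle_global_transitivity <- function(a) {
  n <- nrow(a)
  triangles <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k) {
      if (a[i, j] && a[j, k]) {
        triples <- triples + 1
        if (a[i, k]) triangles <- triangles + 1
      }
    }
  }
  if (triples == 0) return(NaN)
  triangles / triples
}

oracle_local_transitivity <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(NaN)
    sum(a[nb, nb]) / 2 / choose(k, 2)
  })
}

# Newman degree assortativity: Pearson correlation of endpoint degrees over
# the edge list with both orientations
oracle_assortativity <- function(a) {
  deg <- rowSums(a)
  ij <- which(a == 1, arr.ind = TRUE)     # both orientations included
  if (nrow(ij) == 0) return(NA_real_)
  x <- deg[ij[, 1]]; y <- deg[ij[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# quadratic-time Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) p[ord[j]] * m / j)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# ANOSIM R for one labelling, from the raw rank formula
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  iu <- which(upper.tri(d))
  rk <- rank(d[iu])
  same <- (matrix(groups, n, n) == matrix(groups, n, n, byrow = TRUE))[iu]
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

# exhaustive ANOSIM p for a two-group design by subset enumeration
oracle_anosim_exact_p <- function(d, groups) {
  n <- nrow(d)
  g1 <- sum(groups == unique(groups)[1])
  r_obs <- oracle_anosim_r(d, groups)
  splits <- utils::combn(n, g1)
  r_all <- apply(splits, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    oracle_anosim_r(d, g)
  })
  mean(r_all >= r_obs - 1e-12)
}

# Kruskal-Wallis H with midrank tie correction, direct formula
oracle_kruskal_h <- function(values, groups) {
  rk <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, groups, function(r) sum(r)^2 / length(r))) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# random undirected graph as a coocnet object
random_net <- function(n_nodes, p_edge = 0.4, node_prefix = "n") {
  nodes <- paste0(node_prefix, seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(otu_a = nodes[pairs[1, keep]],
                      otu_b = nodes[pairs[2, keep]],
                      rho = stats::runif(sum(keep), 0.6, 1) *
                        sample(c(-1, 1), sum(keep), replace = TRUE),
                      q = stats::runif(sum(keep), 0, 0.04),
                      stringsAsFactors = FALSE)
  used <- sort(unique(c(edges$otu_a, edges$otu_b)))
  structure(list(nodes = used, edges = edges, threshold_used = 0.6,
                 fdr_alpha = 0.05, site = NA_character_),
            class = "coocnet")
}

# small synthetic bundle for fast tests
small_config <- function(seed = 1, ...) {
  args <- list(n_otus = 80, sequencing_depth = 2000, n_blocks = 2,
               block_size = 10, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}
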