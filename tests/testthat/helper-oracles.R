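# Independent straight-from-formula oracles used to cross-check the
# vectorized implementations. Deliberately slow and literal.

# topological overlap by explicit triple loop, sums over u != i, j
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, ]); kj <- sum(a[j, ])
    out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  out
}

oracle_cut_loss <- function(M, A) {
  n <- nrow(M); k <- ncol(M)
  d <- rowSums(A)
  num <- 0; den <- 0
  for (c in seq_len(k)) {
    num <- num + sum(t(M[, c]) %*% A %*% M[, c])
    den <- den + sum(d * M[, c]^2)
  }
  -num / den
}

oracle_ortho_loss <- function(M) {
  G <- t(M) %*% M
  B <- G / norm(G, "F") - diag(ncol(M)) / sqrt(ncol(M))
  norm(B, "F")
}

# Newman weighted modularity through igraph on the zero-diagonal graph
oracle_modularity <- function(tom, labels) {
  tz <- tom; diag(tz) <- 0
  g <- igraph::graph_from_adjacency_matrix(tz, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::modularity(g, membership = labels,
                     weights = igraph::E(g)$weight)
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# random row-stochastic assignment matrix
random_assignment <- function(n, k) {
  m <- matrix(stats::runif(n * k, 0.01, 1), n)
  m / rowSums(m)
}

# compact planted fixture for training tests
small_fixture <- function(seed = 11) {
  simulate_expression(fixture_spec(
    n_genes = 150, n_samples = 15, module_sizes = rep(40, 3),
    trait_effects = data.frame(module = 1:3, effect = 2), seed = seed))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# block TOM with two planted groups (within t_w, between t_b)
block_tom <- function(sizes, t_within = 0.9, t_between = 0.1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  t <- ifelse(outer(lab, lab, "=="), t_within, t_between)
  diag(t) <- 1
  list(tom = t, labels = lab)
}
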