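# Shared fixtures and independent oracles for the test suite.

# A fast, small study configuration for tests that do not need the
# full-size cohort.
small_config <- function(seed = 1, ...) {
  sba_config(n_recruited = 40, n_dropout = 3, n_antigens = 24,
             n_empty_wells = 4, planted_assoc = list(), coreactive_blocks = list(),
             n_zero_variance_low = 0,
             graph_spec = list(n_nodes = 24, n_communities = 2, n_bridges = 1,
                               p_within = 0.5, n_decoy = 4),
             rng_seed = seed, ...)
}

# Direct closed-form Benjamini-Hochberg step-up, written independently of
# the package (and of p.adjust): q_(i) = min_{j >= i} m p_(j) / j.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Independent one-way PERMANOVA pseudo-F (fresh implementation of the
# sum-of-squares identities, used for exhaustive small-n enumeration).
pseudo_f_direct <- function(x, labels) {
  d2 <- as.matrix(dist(x))^2
  N <- nrow(d2)
  groups <- unique(labels)
  a <- length(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (g in groups) {
    i <- which(labels == g)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  if (ss_w <= 1e-12) return(Inf)
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (N - a))
}

# Exact permutation p for a 2-group PERMANOVA by enumerating every
# assignment of n1 labels to positions.
permanova_exact_p <- function(x, labels) {
  n <- length(labels)
  g1 <- unique(labels)[1]
  n1 <- sum(labels == g1)
  f_obs <- pseudo_f_direct(x, labels)
  combos <- combn(n, n1)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep("b", n)
    lab[idx] <- "a"
    pseudo_f_direct(x, lab)
  })
  mean(f_all >= f_obs)
}

# Exact two-sided permutation p for the Welch t by enumeration.
welch_t_direct <- function(g1, g2) {
  se2 <- var(g1) / length(g1) + var(g2) / length(g2)
  dm <- mean(g1) - mean(g2)
  if (se2 <= 0) return(if (dm == 0) 0 else sign(dm) * Inf)
  dm / sqrt(se2)
}
t_test_exact_p <- function(values, labels) {
  n <- length(values)
  g1 <- unique(labels)[1]
  n1 <- sum(labels == g1)
  t_obs <- abs(welch_t_direct(values[labels == g1], values[labels != g1]))
  combos <- combn(n, n1)
  t_all <- apply(combos, 2, function(idx)
    abs(welch_t_direct(values[idx], values[-idx])))
  mean(t_all >= t_obs)
}

# Recurrence counts accumulated from explicitly enumerated shortest paths
# (the exhaustive oracle for shortest_path_recurrence).
recurrence_from_enumeration <- function(graph, seeds) {
  nm <- igraph::V(graph)$name
  seeds <- intersect(seeds, nm)
  node_R <- setNames(numeric(length(nm)), nm)
  el <- igraph::as_edgelist(graph)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  edge_R <- setNames(numeric(nrow(el)), ekey)
  pr <- t(combn(seeds, 2))
  for (r in seq_len(nrow(pr))) {
    paths <- enumerate_all_shortest_paths(graph, pr[r, 1], pr[r, 2])
    for (p in paths) {
      if (length(p) > 2) {
        interior <- p[-c(1, length(p))]
        node_R[interior] <- node_R[interior] + 1
      }
      if (length(p) > 1) {
        ek <- paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))
        edge_R[ek] <- edge_R[ek] + 1
      }
    }
  }
  list(node = node_R, edge = edge_R)
}

# Random connected-ish test graph with fractional strengths.
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  igraph::E(g)$strength <- runif(igraph::ecount(g), 0.2, 1)
  g
}

# Rank of given antigens within one parameter of an association table,
# ordered by q with ties broken by p.
assoc_rank <- function(assoc, parameter, antigens) {
  sub <- assoc[assoc$parameter == parameter & !is.na(assoc$p), , drop = FALSE]
  rk <- rank(sub$q + sub$p * 1e-9, ties.method = "min")
  rk[match(antigens, sub$antigen)]
}
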