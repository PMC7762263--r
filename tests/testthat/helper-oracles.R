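# Independent oracles and small generators used across the suite. These
# deliberately use naive algorithms (iterative pruning, exhaustive pair
# enumeration, direct entropy sums) so they share no code path with the
# package implementations they check.

# k-core by literal iterative pruning on an adjacency list.
brute_kcore <- function(g) {
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  core <- stats::setNames(integer(length(nodes)), nodes)
  alive <- rep(TRUE, length(nodes))
  deg <- lengths(adj)
  k <- 0L
  while (any(alive)) {
    repeat {
      rm <- which(alive & deg <= k)
      if (length(rm) == 0L) break
      for (v in rm) {
        core[v] <- k
        alive[v] <- FALSE
        for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

# ARI by exhaustive enumeration of all node pairs.
oracle_ari <- function(p, t) {
  nodes <- names(p)
  t <- t[nodes]
  n <- length(nodes)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      same_p <- p[[i]] == p[[j]]
      same_t <- t[[i]] == t[[j]]
      if (same_p && same_t) a <- a + 1
      else if (same_p && !same_t) b <- b + 1
      else if (!same_p && same_t) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  total <- a + b + c_ + d
  exp_index <- (a + b) * (a + c_) / total
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == exp_index) return(1)
  (a - exp_index) / (max_index - exp_index)
}

# NMI by direct per-cluster probability sums (arithmetic-mean normalized).
oracle_nmi <- function(p, t) {
  nodes <- names(p)
  t <- t[nodes]
  n <- length(nodes)
  px <- table(as.character(p)) / n
  py <- table(as.character(t)) / n
  hx <- -sum(px * log(px))
  hy <- -sum(py * log(py))
  i <- 0
  for (cx in names(px)) {
    for (cy in names(py)) {
      pij <- sum(p == cx & t == cy) / n
      if (pij > 0) i <- i + pij * log(pij / (px[[cx]] * py[[cy]]))
    }
  }
  if (hx + hy == 0) return(1)
  2 * i / (hx + hy)
}

# Purity by direct per-community plurality counts.
oracle_purity <- function(p, t) {
  nodes <- names(p)
  t <- t[nodes]
  s <- 0
  for (com in unique(as.character(p))) {
    members <- nodes[p == com]
    s <- s + max(table(as.character(t[members])))
  }
  s / length(nodes)
}

# Seeded G(n, p) random graph with character names "1".."n".
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Random assignment of nodes to at most kmax labels.
random_partition <- function(nodes, kmax, seed) {
  set.seed(seed)
  stats::setNames(as.character(sample.int(kmax, length(nodes),
                                          replace = TRUE)), nodes)
}

write_tmp_lines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Edge-list file of the worked example network.
example_edge_file <- function() {
  el <- igraph::as_edgelist(example_network()$network)
  write_tmp_lines(paste(el[, 1L], el[, 2L], sep = "\t"))
}
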