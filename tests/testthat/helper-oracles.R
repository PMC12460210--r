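# Independent test oracles and small fixture builders. These re-derive
# quantities by brute force or textbook formulas, deliberately avoiding the
# package's implementation paths.

# Two-channel sinusoid recording at fs Hz.
sinusoid_recording <- function(freq, duration, fs = 512,
                               phase2 = 0, labels = c("a", "b")) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  eeg_recording(rbind(sin(2 * pi * freq * t),
                      sin(2 * pi * freq * t + phase2)),
                fs = fs, channel_labels = labels)
}

# Random connected symmetric weight matrix with strictly positive
# off-diagonal weights (complete graph => always connected).
random_weight_matrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, 0.05, 1)
  w + t(w)
}

# Sparse random connected graph: random spanning tree plus extra edges.
random_sparse_connected <- function(n, extra = n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  perm <- sample(n)
  for (k in 2:n) {
    i <- perm[k]
    j <- perm[sample(k - 1, 1)]
    w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- runif(1, 0.05, 1)
  }
  w
}

# Floyd-Warshall all-pairs shortest paths on reciprocal-weight lengths.
fw_closeness <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  (n - 1) / rowSums(d)
}

# Maximum-spanning-tree bottleneck via Kruskal on descending weights.
mst_bottleneck <- function(w) {
  n <- nrow(w)
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ord <- order(-w[up])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  bottleneck <- Inf
  taken <- 0L
  for (k in ord) {
    i <- up[k, 1]; j <- up[k, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      bottleneck <- min(bottleneck, w[i, j])
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  bottleneck
}

# Brute-force maximal connected edge-component extent: grow components by
# repeated scanning over an edge list (i, j).
bf_max_extent <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  comp <- seq_len(nrow(edges))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(edges))) {
      for (b in seq_len(nrow(edges))) {
        if (comp[a] != comp[b] &&
            length(intersect(edges[a, ], edges[b, ])) > 0) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  max(table(comp))
}

# Per-subject stacks of plain random symmetric matrices.
random_stacks <- function(n_subjects, n_nodes, seed) {
  set.seed(seed)
  make <- function() {
    lapply(seq_len(n_subjects), function(s) {
      w <- matrix(0, n_nodes, n_nodes)
      w[upper.tri(w)] <- runif(n_nodes * (n_nodes - 1) / 2, 0.2, 0.8)
      w + t(w)
    })
  }
  list(pre = make(), post = make())
}

planted_edges_rf <- function() {
  list(c("AF4", "FC4"), c("FC4", "C4"), c("C4", "CP4"), c("AF4", "O2"))
}
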