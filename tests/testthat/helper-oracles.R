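# Independent brute-force graph oracles. These deliberately avoid igraph
# and the package's own metric code: distances by explicit BFS, triangles
# by direct neighbor-pair enumeration, betweenness by exhaustive simple-
# path enumeration. Only usable for small graphs.

adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

brute_distances <- function(adj) {
  t(sapply(seq_len(nrow(adj)), function(s) bfs_dist(adj, s)))
}

brute_lp <- function(adj) {
  d <- brute_distances(adj)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

brute_eg <- function(adj) {
  if (nrow(adj) < 2) return(0)
  d <- brute_distances(adj)
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v), 1 / v, 0))
}

brute_clustering <- function(adj) {
  n <- nrow(adj)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      links <- links + adj[nb[a], nb[b]]
    per[i] <- 2 * links / (k * (k - 1))
  }
  list(per_node = per, Cp = mean(per))
}

brute_eloc <- function(adj) {
  n <- nrow(adj)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    per[i] <- brute_eg(adj[nb, nb, drop = FALSE])
  }
  list(per_node = per, Eloc = mean(per))
}

# all simple paths from s to t by DFS
all_simple_paths_brute <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# betweenness by exhaustive shortest-path enumeration, fractional credit,
# endpoints excluded
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  B <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_brute(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      ns <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        B[inner] <- B[inner] + 1 / ns
      }
    }
  }
  B
}

# deterministic Watts-Strogatz graph: ring lattice of even degree k,
# each edge rewired with probability p (R RNG; call under set.seed)
ws_graph <- function(n, k, p) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in seq_len(k / 2)) {
      j <- ((i - 1 + off) %% n) + 1
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    if (stats::runif(1) < p) {
      i <- edges[e, 1]
      cand <- which(adj[i, ] == 0)
      cand <- setdiff(cand, i)
      if (length(cand) == 0) next
      j_new <- cand[sample.int(length(cand), 1)]
      j_old <- edges[e, 2]
      adj[i, j_old] <- adj[j_old, i] <- 0
      adj[i, j_new] <- adj[j_new, i] <- 1
    }
  }
  adj
}

random_graph <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- as.numeric(stats::runif(length(ut)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# similarity matrix with given upper-tri values (row-major order)
sim_from_upper <- function(vals, n, names = NULL) {
  m <- matrix(NA_real_, n, n)
  m[upper.tri(m)] <- NA
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- vals[k]
    k <- k + 1
  }
  if (!is.null(names)) dimnames(m) <- list(names, names)
  structure(m, class = c("similarity_matrix", "matrix"))
}

# small synthetic spec for fast tests
tiny_spec <- function(n_regions = 12L, voxels_per_region = 200L, seed = 42L,
                      ...) {
  synthetic_spec(n_regions = n_regions,
                 voxels_per_region = voxels_per_region, seed = seed, ...)
}
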