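# Graph-theoretical analysis of binarized morphological networks:
# sparsity thresholding, small-world and efficiency metrics, Maslov
# degree-preserving null ensembles, betweenness-based hubs, and
# between-subject profile similarity/uniqueness.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

.as_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

.check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have zero diagonal")
  if (!all(adj %in% c(0, 1))) stop("adjacency must be binary")
  invisible(adj)
}

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Sparsity S is the fraction of realized edges over all possible node
#' pairs. The `K = round(S * R(R-1)/2)` strongest off-diagonal pairs
#' become edges; the value cut-off is therefore subject-specific, which
#' guarantees every subject's network has identical node and edge counts.
#' Ties at the cut-off are broken deterministically by lexicographic
#' (row, column) order.
#'
#' @param similarity `similarity_matrix` (diagonal `NA`, excluded).
#' @param S Sparsity in (0, 1); must yield 0 < K < R(R-1)/2.
#' @return Binary symmetric adjacency matrix with attributes `sparsity`
#'   and `n_edges`.
#' @export
binarize_by_sparsity <- function(similarity, S) {
  if (S <= 0 || S >= 1) stop("sparsity must lie in (0, 1)")
  R <- nrow(similarity)
  max_edges <- R * (R - 1) / 2
  K <- round(S * max_edges)
  if (K < 1) stop("sparsity ", S, " yields 0 edges: degenerate network")
  if (K >= max_edges)
    stop("sparsity ", S, " yields the complete graph: degenerate network")
  ut <- which(upper.tri(similarity), arr.ind = TRUE)
  vals <- similarity[ut]
  if (any(is.na(vals))) stop("NA similarity off the diagonal")
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  keep <- ut[ord[seq_len(K)], , drop = FALSE]
  adj <- matrix(0, R, R, dimnames = dimnames(similarity))
  adj[keep] <- 1
  adj[keep[, c(2, 1), drop = FALSE]] <- 1
  structure(adj, sparsity = S, n_edges = K)
}

#' Clustering coefficient
#'
#' Per-node clustering is the fraction of a node's neighbor pairs that are
#' themselves connected (0 for degree < 2); the network value `Cp` is the
#' mean over all nodes.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with `per_node` and `Cp`.
#' @export
clustering_coefficient <- function(adj) {
  .check_adjacency(adj)
  k <- rowSums(adj)
  triangles <- diag(adj %*% adj %*% adj) / 2
  per_node <- ifelse(k >= 2, 2 * triangles / (k * (k - 1)), 0)
  list(per_node = per_node, Cp = mean(per_node))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all reachable unordered node pairs. If
#' the graph is disconnected the unreachable pairs are dropped from the
#' average and a warning is raised (a condition of class
#' `morphnet_disconnected`), so low-sparsity networks remain analyzable
#' but flagged.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return `Lp` (scalar).
#' @export
characteristic_path_length <- function(adj) {
  .check_adjacency(adj)
  if (sum(adj) == 0) stop("graph has no edges: path length undefined")
  d <- igraph::distances(.as_graph(adj))
  d <- d[upper.tri(d)]
  unreachable <- sum(is.infinite(d))
  if (unreachable > 0L)
    warning(warningCondition(
      paste0("graph disconnected: ", unreachable,
             " unreachable pair(s) dropped from Lp"),
      class = "morphnet_disconnected"))
  mean(d[is.finite(d)])
}

#' Betweenness centrality, raw and normalized
#'
#' Raw betweenness `B_i` counts shortest paths between other node pairs
#' passing through node i, with fractional credit when several shortest
#' paths exist (Freeman/Brandes semantics, endpoints excluded). The
#' normalized value is `b_i = B_i / meanBet` with `meanBet = mean(B)`, so
#' normalized values average to 1.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with `B` (raw), `b` (normalized; all `NA` when
#'   `meanBet == 0`, e.g. a complete graph), `meanBet`.
#' @export
betweenness_normalized <- function(adj) {
  .check_adjacency(adj)
  B <- igraph::betweenness(.as_graph(adj), directed = FALSE)
  meanBet <- mean(B)
  b <- if (meanBet > 0) B / meanBet else rep(NA_real_, length(B))
  list(B = B, b = b, meanBet = meanBet)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all unordered node pairs, with
#' unreachable pairs contributing 0. Defined for any graph, including the
#' empty one (efficiency 0).
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return `Eg` (scalar in [0, 1]).
#' @export
global_efficiency <- function(adj) {
  .check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2L) return(0)
  if (sum(adj) == 0) return(0)
  d <- igraph::distances(.as_graph(adj))
  inv <- 1 / d[upper.tri(d)]
  inv[is.infinite(d[upper.tri(d)])] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbors (0 for degree < 2); `Eloc` is the mean over all nodes.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return List with `per_node` and `Eloc`.
#' @export
local_efficiency <- function(adj) {
  .check_adjacency(adj)
  n <- nrow(adj)
  per_node <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2L) next
    per_node[i] <- global_efficiency(adj[nb, nb, drop = FALSE])
  }
  list(per_node = per_node, Eloc = mean(per_node))
}

#' Degree-preserving random reference network (Maslov rewiring)
#'
#' Repeated random double-edge swaps: two edges (a,b), (c,d) are replaced
#' by (a,d), (c,b) whenever that creates no self-loop or duplicate edge.
#' The node count, edge count and full degree sequence of the input are
#' preserved exactly. `n_swaps_per_edge * n_edges` swaps are attempted.
#'
#' @param adj Binary symmetric adjacency matrix with >= 2 edges.
#' @param seed Optional integer; the caller's RNG state is restored.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @return Rewired adjacency matrix with attribute `n_swaps` (successful
#'   swaps). Warns if fewer than one swap per edge succeeded.
#' @export
maslov_random_reference <- function(adj, seed = NULL, n_swaps_per_edge = 10) {
  .check_adjacency(adj)
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  K <- nrow(ut)
  if (K < 2L) stop("need at least 2 edges to rewire")
  .with_seed(seed, {
    attempts <- as.integer(ceiling(n_swaps_per_edge * K))
    e1s <- sample.int(K, attempts, replace = TRUE)
    e2s <- sample.int(K, attempts, replace = TRUE)
    flips <- stats::runif(attempts) < 0.5
    out <- matrix(as.numeric(adj), nrow(adj), ncol(adj),
                  dimnames = dimnames(adj))
    E <- matrix(as.integer(ut), nrow(ut), 2L)
    done <- .maslov_swaps_cpp(out, E, e1s, e2s, flips)
    if (done < K)
      warning("rewiring stalled: only ", done, " successful swap(s) for ",
              K, " edges")
    structure(out, sparsity = attr(adj, "sparsity"), n_edges = K,
              n_swaps = done)
  })
}

#' Global network metrics with small-world normalization
#'
#' Computes Cp, Lp, Eg, Eloc and meanBet for the network, then
#' `Cp_rand`/`Lp_rand` as means over `n_random` Maslov degree-preserving
#' references, and the small-world ratios `gamma = Cp/Cp_rand`,
#' `lambda = Lp/Lp_rand`, `sigma = gamma/lambda`. A network is small-world
#' when gamma > 1 with lambda close to 1, i.e. sigma > 1.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param n_random Null-ensemble size (default 100).
#' @param seed Optional integer; replicate k uses `seed + k`.
#' @param n_swaps_per_edge Swaps per edge for each reference.
#' @return A `global_metrics` object (list): Cp, Lp, Eg, Eloc, meanBet,
#'   Cp_rand, Lp_rand, gamma, lambda, sigma, n_random.
#' @export
small_world_metrics <- function(adj, n_random = 100L, seed = NULL,
                                n_swaps_per_edge = 10) {
  if (n_random < 1L) stop("n_random must be >= 1")
  cc <- clustering_coefficient(adj)
  Lp <- characteristic_path_length(adj)
  Eg <- global_efficiency(adj)
  le <- local_efficiency(adj)
  bet <- betweenness_normalized(adj)
  cps <- numeric(n_random)
  lps <- numeric(n_random)
  for (k in seq_len(n_random)) {
    sk <- if (is.null(seed)) NULL else seed + k
    ref <- maslov_random_reference(adj, seed = sk,
                                   n_swaps_per_edge = n_swaps_per_edge)
    cps[k] <- clustering_coefficient(ref)$Cp
    lps[k] <- suppressWarnings(characteristic_path_length(ref))
  }
  Cp_rand <- mean(cps)
  Lp_rand <- mean(lps)
  gamma <- cc$Cp / Cp_rand
  lambda <- Lp / Lp_rand
  structure(list(Cp = cc$Cp, Lp = Lp, Eg = Eg, Eloc = le$Eloc,
                 meanBet = bet$meanBet, Cp_rand = Cp_rand, Lp_rand = Lp_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_random = n_random),
            class = "global_metrics")
}

#' Identify hubs from cross-subject betweenness
#'
#' Averages each node's normalized betweenness over subjects; hubs are the
#' nodes whose average exceeds the across-node mean by more than one
#' (sample) standard deviation.
#'
#' @param b_matrix Numeric matrix, subjects x nodes, of normalized
#'   betweenness `b_i` (a single subject may pass a 1-row matrix or
#'   vector).
#' @return List with `mean_b` (per node), `threshold`, `hubs` (node
#'   names/indices above threshold).
#' @export
identify_hubs <- function(b_matrix) {
  if (is.vector(b_matrix)) b_matrix <- matrix(b_matrix, nrow = 1L,
                                              dimnames = list(NULL, names(b_matrix)))
  if (ncol(b_matrix) < 2L) stop("hub detection needs at least 2 nodes")
  mean_b <- colMeans(b_matrix)
  thr <- mean(mean_b) + stats::sd(mean_b)
  hubs <- which(mean_b > thr)
  list(mean_b = mean_b, threshold = thr,
       hubs = if (!is.null(colnames(b_matrix))) colnames(b_matrix)[hubs]
              else hubs)
}

#' Similarity and uniqueness of betweenness profiles
#'
#' For subject m with betweenness profile `Bd_m` over nodes:
#' `Similarity_m` is the mean Pearson correlation with all other subjects'
#' profiles and `Uniqueness_m` is 1 minus the maximal correlation with any
#' other subject. Raw scores range over [-1, 1] and [0, 2] respectively
#' and are also returned rescaled to [0, 1] (`(s+1)/2` and `u/2`).
#'
#' @param profiles Numeric matrix, subjects x nodes (>= 2 subjects), or a
#'   list of equal-length profile vectors.
#' @return A data.frame: subject, similarity_raw, uniqueness_raw,
#'   similarity, uniqueness.
#' @export
profile_similarity_uniqueness <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  N <- nrow(profiles)
  if (N < 2L) stop("need at least 2 subjects")
  vars <- apply(profiles, 1L, stats::var)
  if (any(vars == 0))
    stop("zero-variance betweenness profile for subject(s): ",
         paste(which(vars == 0), collapse = ", "))
  cm <- stats::cor(t(profiles))
  diag(cm) <- NA
  sim_raw <- rowMeans(cm, na.rm = TRUE)
  unq_raw <- 1 - apply(cm, 1L, max, na.rm = TRUE)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  data.frame(subject = ids,
             similarity_raw = sim_raw, uniqueness_raw = unq_raw,
             similarity = (sim_raw + 1) / 2, uniqueness = unq_raw / 2,
             row.names = NULL, stringsAsFactors = FALSE)
}
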