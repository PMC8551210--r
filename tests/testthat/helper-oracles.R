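# Independent oracles and small fixtures shared across tests.

# Exhaustive simple-path shortest distances over reciprocal-flow edge lengths.
# Depth-first enumeration of simple paths from every source; a branch is cut
# only when its length already exceeds the best known distance to its head
# (safe for positive lengths). Independent of the Dijkstra-based production
# path.
oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  len <- matrix(Inf, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- idx[[edges$llm_i[k]]]
    j <- idx[[edges$llm_j[k]]]
    len[i, j] <- len[j, i] <- 1 / edges$weight[k]
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    dfs <- function(v, acc) {
      for (u in seq_len(n)) {
        if (visited[u] || !is.finite(len[v, u])) next
        d <- acc + len[v, u]
        if (d >= D[s, u] - 1e-15) next
        D[s, u] <<- d
        visited[u] <<- TRUE
        dfs(u, d)
        visited[u] <<- FALSE
      }
    }
    dfs(s, 0)
  }
  D
}

oracle_efficiency <- function(network) {
  D <- oracle_distances(network$nodes, network$edges)
  n <- length(network$nodes)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  e_raw <- rowSums(inv) / (n - 1)
  list(E_glob = sum(inv) / (n * (n - 1)), e_raw = e_raw)
}

# random weighted network on n nodes with integer flows
random_network <- function(n, p_edge = 0.5) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.table::data.table(
    llm_i = nodes[pairs[, 1]], llm_j = nodes[pairs[, 2]],
    weight = sample(1:50, nrow(pairs), replace = TRUE))
  structure(list(window_index = 0L, nodes = nodes, edges = edges),
            class = "mobility_network")
}

# tiny network straight from an edge list
make_network <- function(edges, nodes = NULL) {
  edges <- data.table::as.data.table(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$llm_i, edges$llm_j)))
  structure(list(window_index = 0L, nodes = nodes, edges = edges),
            class = "mobility_network")
}

# brute-force quantile-regression oracle: a basic optimum interpolates p
# observations, so enumerating every p-subset exact fit finds the global
# minimum of the check loss
oracle_quantile_loss <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best <- Inf
  for (ix in utils::combn(n, p, simplify = FALSE)) {
    Xi <- X[ix, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- tryCatch(solve(Xi, y[ix]), error = function(e) NULL)
    if (is.null(b)) next
    best <- min(best, check_loss(y - as.numeric(X %*% b), tau))
  }
  best
}

# small, fast scenario configuration for unit tests
tiny_config <- function(seed = 1L, ...) {
  scenario_config(n_llms = 30L, n_provinces = 5L, n_windows = 6L,
                  bins_per_window = 6L, municipalities_per_llm = c(2L, 3L),
                  privacy_floor = 0, seed = seed, ...)
}
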