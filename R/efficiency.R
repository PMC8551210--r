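#' Global and nodal efficiency of a mobility network
#'
#' Edge distances are the reciprocals of flow counts (heavily travelled links
#' are "short"), and `d_ij` is the shortest-path distance over those
#' reciprocal weights, with `1/d_ij = 0` for disconnected pairs. The measures
#' are
#' \deqn{E_{glob} = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}, \qquad
#'       e_i = \frac{1}{n-1} \sum_{j \ne i} 1/d_{ij},}
#' so the mean of the nodal efficiencies over all nodes equals the global
#' efficiency identically. Normalization divides by the ideal efficiency of a
#' complete graph in which every pair sits at the smallest observed distance
#' `w_min = 1/max(w_ij)`, giving `E_norm = E_glob * w_min` (1 for an
#' equal-weight complete graph) and `e_i_norm = e_i * w_min`. `w_min` is
#' recomputed in every window, so normalized efficiencies measure topology
#' relative to that window's strongest link.
#'
#' An edgeless network is degenerate: all efficiencies are 0, `w_min` is `NA`
#' and a warning is raised.
#'
#' @param network a `mobility_network` (see [build_network()]).
#' @return An object of class `efficiency_result`: list with `window_index`,
#'   `E_glob`, `E_norm`, `w_min`, `n_edges`, `total_flow`, and a `nodal`
#'   data.table (`llm_id`, `e_raw`, `e_norm`).
#' @export
network_efficiency <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  n <- length(network$nodes)
  if (n < 2) stop("efficiency is undefined for networks with fewer than 2 nodes")
  if (nrow(network$edges) == 0) {
    warning("edgeless network: efficiency degenerate, reported as 0")
    nodal <- data.table::data.table(llm_id = network$nodes, e_raw = 0, e_norm = 0)
    return(structure(list(window_index = network$window_index,
                          E_glob = 0, E_norm = 0, w_min = NA_real_,
                          n_edges = 0L, total_flow = 0, nodal = nodal),
                     class = "efficiency_result"))
  }
  g <- as_igraph(network)
  D <- igraph::distances(g, weights = igraph::E(g)$dist, algorithm = "dijkstra")
  D <- D[network$nodes, network$nodes, drop = FALSE]
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  e_raw <- rowSums(inv) / (n - 1)
  E_glob <- sum(inv) / (n * (n - 1))
  w_min <- 1 / max(network$edges$weight)
  nodal <- data.table::data.table(llm_id = network$nodes,
                                  e_raw = as.numeric(e_raw),
                                  e_norm = as.numeric(e_raw) * w_min)
  structure(list(window_index = network$window_index,
                 E_glob = E_glob, E_norm = E_glob * w_min, w_min = w_min,
                 n_edges = nrow(network$edges),
                 total_flow = sum(network$edges$weight),
                 nodal = nodal),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(paste0("<efficiency_result> window %s: E_glob = %.4g, ",
                     "E_norm = %.4g, w_min = %.4g (%d edges)\n"),
              format(x$window_index), x$E_glob, x$E_norm,
              x$w_min, x$n_edges))
  invisible(x)
}

#' Efficiency of every window in a network sequence
#'
#' @param networks list of `mobility_network` (see [build_networks()]).
#' @return List with `nodal` (data.table: `window`, `llm_id`, `e_raw`,
#'   `e_norm`) and `global` (data.table: `window`, `E_glob`, `E_norm`,
#'   `w_min`, `n_edges`, `total_flow`).
#' @export
efficiency_series <- function(networks) {
  res <- lapply(networks, network_efficiency)
  nodal <- data.table::rbindlist(lapply(res, function(r) {
    cbind(window = r$window_index, r$nodal)
  }))
  globals <- data.table::rbindlist(lapply(res, function(r) {
    data.table::data.table(window = r$window_index, E_glob = r$E_glob,
                           E_norm = r$E_norm, w_min = r$w_min,
                           n_edges = r$n_edges, total_flow = r$total_flow)
  }))
  list(nodal = nodal, global = globals)
}
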