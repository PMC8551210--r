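#' Define the 14-day observation window grid
#'
#' Windows are consecutive, non-overlapping and half-open:
#' window k covers `[start_date + k*len, start_date + (k+1)*len)`.
#'
#' @param start_date first day of window 0.
#' @param n_windows number of windows.
#' @param window_length_days window length in days.
#' @return An object of class `window_grid`.
#' @export
window_grid <- function(start_date = as.Date("2020-02-24"),
                        n_windows = 16L, window_length_days = 14L) {
  stopifnot(n_windows >= 1, window_length_days >= 1)
  structure(list(start_date = as.Date(start_date),
                 n_windows = as.integer(n_windows),
                 window_length_days = as.integer(window_length_days)),
            class = "window_grid")
}

#' Window date range
#'
#' First and last day covered by one window of a grid.
#' @param grid a [window_grid()].
#' @param window_index 0-based window index.
#' @return Date vector of length 2 (first day, last day).
#' @export
window_span <- function(grid, window_index) {
  s <- grid$start_date + window_index * grid$window_length_days
  c(s, s + grid$window_length_days - 1L)
}

#' Assign origin-destination records to observation windows
#'
#' Each record is placed into the half-open window containing its time bin;
#' records before the grid start or past its end are dropped (their count is
#' attached as the `dropped_out_of_range` attribute and logged).
#'
#' @param records data.table of OD records with columns `origin_tile`,
#'   `destination_tile`, `datetime_bin` (POSIXct) and `n_travelers`.
#' @param grid a [window_grid()].
#' @return The retained records with an added integer `window` column.
#' @export
assign_windows <- function(records, grid) {
  stopifnot(inherits(grid, "window_grid"))
  records <- data.table::as.data.table(records)
  t0 <- as.POSIXct(paste0(format(grid$start_date), " 00:00:00"), tz = "UTC")
  len_sec <- grid$window_length_days * 86400
  w <- floor(as.numeric(difftime(records$datetime_bin, t0, units = "secs")) /
               len_sec)
  keep <- w >= 0 & w < grid$n_windows & !is.na(w)
  n_drop <- sum(!keep)
  if (n_drop > 0) mf_log("assign_windows: dropped %d out-of-range records", n_drop)
  out <- records[keep]
  out[, window := as.integer(w[keep])]
  data.table::setattr(out, "dropped_out_of_range", n_drop)
  out[]
}

#' Build one weighted undirected mobility network
#'
#' Maps tile-level directed flows to territorial units (LLMs), sums both
#' directions of each LLM pair into a single undirected edge weight, and
#' discards flows internal to one LLM. The node set is the full set of LLMs
#' in the tile map (or `nodes` when given) so that networks of different
#' windows are comparable over an identical node set; nodes with no incident
#' flow remain as isolates.
#'
#' @param records OD records of a single window (any table with
#'   `origin_tile`, `destination_tile`, `n_travelers`).
#' @param tile_map data.table mapping `tile_id` to `llm_id`.
#' @param nodes optional character vector fixing the node set.
#' @param window_index window label stored on the network.
#' @return An object of class `mobility_network`: list with `window_index`,
#'   `nodes`, and an `edges` data.table (`llm_i`, `llm_j`, `weight`) with
#'   `llm_i < llm_j` and strictly positive weights. Attributes
#'   `dropped_unknown_tiles` and `dropped_internal_flow` carry the counts of
#'   travellers discarded at each step.
#' @export
build_network <- function(records, tile_map, nodes = NULL, window_index = NA_integer_) {
  records <- data.table::as.data.table(records)
  tile_map <- data.table::as.data.table(tile_map)
  if (anyDuplicated(tile_map$tile_id)) {
    stop("tile_map maps some tile to more than one LLM")
  }
  if (is.null(nodes)) nodes <- sort(unique(tile_map$llm_id))
  lut <- tile_map$llm_id
  names(lut) <- tile_map$tile_id

  if (nrow(records) == 0) {
    edges <- data.table::data.table(llm_i = character(), llm_j = character(),
                                    weight = numeric())
    net <- structure(list(window_index = window_index, nodes = nodes,
                          edges = edges), class = "mobility_network")
    attr(net, "dropped_unknown_tiles") <- 0
    attr(net, "dropped_internal_flow") <- 0
    return(net)
  }

  o <- unname(lut[records$origin_tile])
  d <- unname(lut[records$destination_tile])
  known <- !is.na(o) & !is.na(d)
  dropped_unknown <- sum(records$n_travelers[!known])
  if (dropped_unknown > 0) {
    mf_log("build_network: dropped %d travellers on unknown tiles", dropped_unknown)
  }
  o <- o[known]; d <- d[known]
  cnt <- records$n_travelers[known]
  internal <- o == d
  dropped_internal <- sum(cnt[internal])
  o <- o[!internal]; d <- d[!internal]; cnt <- cnt[!internal]

  ed <- data.table::data.table(llm_i = pmin(o, d), llm_j = pmax(o, d),
                               weight = as.numeric(cnt))
  edges <- ed[, list(weight = sum(weight)), by = c("llm_i", "llm_j")]
  edges <- edges[edges$weight > 0]
  data.table::setorder(edges, llm_i, llm_j)
  net <- structure(list(window_index = window_index, nodes = nodes,
                        edges = edges), class = "mobility_network")
  attr(net, "dropped_unknown_tiles") <- dropped_unknown
  attr(net, "dropped_internal_flow") <- dropped_internal
  net
}

#' Build the per-window network sequence from raw records
#'
#' Convenience wrapper: [assign_windows()] then [build_network()] per window
#' over the fixed node set of the tile map.
#'
#' @param records OD records (all windows).
#' @param grid a [window_grid()].
#' @param tile_map tile-to-LLM mapping.
#' @return List of `mobility_network`, one per window (index 0..n_windows-1).
#' @export
build_networks <- function(records, grid, tile_map) {
  recs <- assign_windows(records, grid)
  nodes <- sort(unique(tile_map$llm_id))
  lapply(seq_len(grid$n_windows) - 1L, function(w) {
    build_network(recs[recs$window == w], tile_map, nodes = nodes,
                  window_index = w)
  })
}

#' @export
print.mobility_network <- function(x, ...) {
  cat(sprintf("<mobility_network> window %s: %d nodes, %d edges, total flow %g\n",
              format(x$window_index), length(x$nodes), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Degree and strength centralities
#'
#' Degree is the number of incident edges; strength the sum of incident edge
#' weights (travellers). Isolated nodes get 0 for both.
#'
#' @param network a `mobility_network`.
#' @return data.table with `llm_id`, `degree`, `strength` for every node.
#' @export
degree_strength <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  ids <- c(network$edges$llm_i, network$edges$llm_j)
  wts <- rep(network$edges$weight, 2)
  deg <- table(factor(ids, levels = network$nodes))
  str <- tapply(wts, factor(ids, levels = network$nodes), sum)
  str[is.na(str)] <- 0
  data.table::data.table(llm_id = network$nodes,
                         degree = as.integer(deg),
                         strength = as.numeric(str))
}

# igraph view of a mobility network; edge attribute `weight` is the flow and
# `dist` its reciprocal (the travel distance used by the efficiency measures).
as_igraph <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$llm_i, to = network$edges$llm_j,
               weight = network$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
  igraph::E(g)$dist <- 1 / igraph::E(g)$weight
  g
}
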