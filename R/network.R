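# Weighted-graph metrics on state centroid matrices, and temporal metrics
# (occurrence rates, transition counts) on state label sequences.

#' Build a weighted graph from a state centroid matrix
#'
#' Nodes are ROIs; the edge weight between ROIs i and j is the centroid's
#' synchrony value, and the edge length used by path metrics is its
#' reciprocal (stronger synchrony = shorter distance). Self-loops are
#' dropped; zero-weight entries yield no edge.
#'
#' @param centroid Symmetric non-negative ROI x ROI matrix.
#' @return An igraph graph with edge attributes `weight` and `length`.
#' @export
centroid_to_graph <- function(centroid) {
  if (!isTRUE(all.equal(centroid, t(centroid), tolerance = 1e-9)))
    stop("centroid matrix must be symmetric")
  if (any(centroid < 0)) stop("centroid matrix must be non-negative")
  m <- centroid
  diag(m) <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

graph_distances <- function(graph) {
  if (igraph::vcount(graph) < 2) stop("graph needs at least 2 nodes")
  if (igraph::ecount(graph) == 0)
    stop("empty graph: path metrics undefined")
  igraph::distances(graph, weights = igraph::E(graph)$length)
}

#' Global efficiency of a weighted graph
#'
#' `globE = mean over ordered node pairs of 1 / d_ij`, with `d_ij` the
#' shortest path length on edge lengths `1 / weight`; unreachable pairs
#' contribute zero. The inverse of the harmonic mean of the pairwise
#' shortest path lengths.
#'
#' @param graph Graph from [centroid_to_graph()].
#' @return Non-negative scalar (1 for a complete unit-weight graph).
#' @export
global_efficiency <- function(graph) {
  d <- graph_distances(graph)
  n <- nrow(d)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Characteristic path length (harmonic-mean variant)
#'
#' Harmonic mean of the pairwise shortest path lengths over reachable
#' ordered pairs: `Lp = n_pairs / sum(1 / d_ij)`. The arithmetic-mean
#' variant is returned as an attribute for audit.
#'
#' @param graph Graph from [centroid_to_graph()].
#' @return Positive scalar with attribute `arithmetic`.
#' @export
characteristic_path_length <- function(graph) {
  d <- graph_distances(graph)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) stop("no reachable node pairs")
  lp <- sum(reach) / sum(1 / off[reach])
  attr(lp, "arithmetic") <- mean(off[reach])
  lp
}

#' Occurrence rate of each state per task
#'
#' Fraction of each task's windows spent in each state; rates sum to one
#' within a task.
#'
#' @param labels Integer state label per window (chronological).
#' @param task Task label per window.
#' @param k Number of states.
#' @return Data frame: `task`, `state`, `occurrence`.
#' @export
occurrence_rates <- function(labels, task, k = max(labels)) {
  stopifnot(length(labels) == length(task))
  out <- list()
  for (tk in unique(task)) {
    sel <- labels[task == tk]
    for (s in seq_len(k))
      out[[length(out) + 1L]] <- data.frame(task = tk, state = s,
                                            occurrence = mean(sel == s))
  }
  do.call(rbind, out)
}

#' Number of state transitions per task
#'
#' Counts adjacent window pairs with different states within each task;
#' the boundary between tasks is not counted.
#'
#' @inheritParams occurrence_rates
#' @return Data frame: `task`, `transitions`.
#' @export
transition_count <- function(labels, task) {
  stopifnot(length(labels) == length(task))
  out <- list()
  for (tk in unique(task)) {
    sel <- labels[task == tk]
    n_tr <- if (length(sel) > 1) sum(diff(sel) != 0) else 0L
    out[[length(out) + 1L]] <- data.frame(task = tk, transitions = n_tr)
  }
  do.call(rbind, out)
}

#' Tidy per-dyad state metrics for a partition
#'
#' Combines per-dyad occurrence rates and transition counts with the
#' graph metrics of each dyad's state centroids.
#'
#' @param partition A `state_partition` from [cluster_group_then_dyads()].
#' @param dyad_ids Optional dyad identifiers.
#' @return Data frame: `dyad`, `task`, `state`, `occurrence`,
#'   `transitions` (per task, repeated across states), `globE`, `Lp`.
#' @export
state_metrics <- function(partition, dyad_ids = NULL) {
  nd <- length(partition$labels)
  if (is.null(dyad_ids)) dyad_ids <- paste0("dyad", seq_len(nd))
  rows <- list()
  for (d in seq_len(nd)) {
    occ <- occurrence_rates(partition$labels[[d]], partition$window_task,
                            k = partition$k)
    tr <- transition_count(partition$labels[[d]], partition$window_task)
    gmet <- vapply(partition$dyad_centroids[[d]], function(m) {
      g <- centroid_to_graph(m)
      c(global_efficiency(g), as.numeric(characteristic_path_length(g)))
    }, numeric(2))
    occ$dyad <- dyad_ids[d]
    occ$transitions <- tr$transitions[match(occ$task, tr$task)]
    occ$globE <- gmet[1, occ$state]
    occ$Lp <- gmet[2, occ$state]
    rows[[d]] <- occ
  }
  out <- do.call(rbind, rows)
  out[, c("dyad", "task", "state", "occurrence", "transitions", "globE", "Lp")]
}
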