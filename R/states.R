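# Two-level Manhattan-distance k-means over windowed IBS matrices:
# group-level centroids with an elbow-selected k, then dyad-level labeling
# seeded from the group centroids. Median centroid updates give the exact
# L1 minimizer, so the objective is non-increasing across iterations.

#' Flatten windowed IBS matrices to feature vectors
#'
#' Each symmetric ROI x ROI matrix becomes its upper triangle including the
#' diagonal (`n*(n+1)/2` features; 91 for 13 ROIs). [unvectorize_window()]
#' inverts the mapping exactly.
#'
#' @param series An `ibs_window_series` or a 3-d array (ROI x ROI x
#'   windows) of symmetric matrices.
#' @return Numeric matrix, windows x features.
#' @export
vectorize_windows <- function(series) {
  arr <- if (inherits(series, "ibs_window_series")) series$win else series
  n <- dim(arr)[1]
  ut <- upper.tri(diag(n), diag = TRUE)
  n_win <- dim(arr)[3]
  out <- matrix(0, n_win, sum(ut))
  for (w in seq_len(n_win)) {
    m <- arr[, , w]
    if (max(abs(m - t(m))) > 1e-9)
      stop("window ", w, " matrix is not symmetric")
    out[w, ] <- m[ut]
  }
  out
}

#' @rdname vectorize_windows
#' @param v Feature vector produced by [vectorize_windows()].
#' @param n_rois Matrix dimension.
#' @export
unvectorize_window <- function(v, n_rois) {
  m <- matrix(0, n_rois, n_rois)
  m[upper.tri(m, diag = TRUE)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

l1_dist_to_centroids <- function(X, C) {
  k <- nrow(C)
  D <- matrix(0, nrow(X), k)
  for (c_i in seq_len(k))
    D[, c_i] <- rowSums(abs(X - matrix(C[c_i, ], nrow(X), ncol(X), byrow = TRUE)))
  D
}

lloyd_l1 <- function(X, C, max_iter) {
  prev_labels <- rep(0L, nrow(X))
  cost <- Inf
  for (it in seq_len(max_iter)) {
    D <- l1_dist_to_centroids(X, C)
    labels <- max.col(-D, ties.method = "first")
    reseeded <- FALSE
    for (c_i in seq_len(nrow(C))) {
      if (!any(labels == c_i)) {       # empty cluster: reseed at farthest point
        counts <- tabulate(labels, nbins = nrow(C))
        movable <- which(counts[labels] > 1)   # never orphan another cluster
        if (length(movable) == 0) next         # fewer distinct points than k
        own <- D[cbind(movable, labels[movable])]
        far <- movable[which.max(own)]
        C[c_i, ] <- X[far, ]
        labels[far] <- c_i
        reseeded <- TRUE
      }
    }
    new_cost <- sum(D[cbind(seq_len(nrow(X)), labels)])
    if (!reseeded && new_cost > cost + 1e-8)
      stop("internal error: L1 k-means objective increased")
    cost <- new_cost
    if (identical(labels, prev_labels)) break
    prev_labels <- labels
    for (c_i in seq_len(nrow(C)))
      if (any(labels == c_i))
        C[c_i, ] <- apply(X[labels == c_i, , drop = FALSE], 2, stats::median)
  }
  D <- l1_dist_to_centroids(X, C)
  labels <- max.col(-D, ties.method = "first")
  list(centroids = C, labels = labels,
       cost = sum(D[cbind(seq_len(nrow(X)), labels)]), iterations = it)
}

#' Manhattan-distance k-means with median centroids
#'
#' Lloyd iterations under the L1 metric: points are assigned to the nearest
#' centroid in Manhattan distance and centroids are updated to the
#' component-wise median of their members (the exact L1 minimizer). The
#' algorithm is restarted from `n_replicates` random initializations (the
#' standard remedy against local minima) and the lowest-cost solution is
#' returned. Deterministic under a fixed seed.
#'
#' @param X Numeric matrix, points x features.
#' @param k Number of clusters (`k <= nrow(X)`).
#' @param n_replicates Number of random-initialization restarts.
#' @param max_iter Maximum Lloyd iterations per replicate.
#' @param seed Integer seed.
#' @param init Optional k x features matrix of initial centroids; when
#'   given, a single run from this initialization is performed.
#' @return List: `centroids` (k x features), `labels`, `cost` (total L1
#'   distance of points to their centroid), `iterations`, `n_replicates`.
#' @export
kmeans_manhattan <- function(X, k, n_replicates = 1000, max_iter = 300,
                             seed = 1L, init = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < k) stop("need at least k points")
  if (!is.null(init)) {
    stopifnot(nrow(init) == k, ncol(init) == ncol(X))
    res <- lloyd_l1(X, as.matrix(init), max_iter)
    res$n_replicates <- 1L
    return(res)
  }
  set.seed(seed)
  best <- NULL
  for (rep_i in seq_len(n_replicates)) {
    C0 <- X[sample.int(nrow(X), k), , drop = FALSE]
    res <- lloyd_l1(X, C0, max_iter)
    if (is.null(best) || res$cost < best$cost) best <- res
  }
  best$n_replicates <- n_replicates
  best
}

#' Cluster validity index (within- to between-cluster distance ratio)
#'
#' Mean L1 distance of points to their own centroid divided by the mean
#' pairwise L1 distance between centroids. Lower is better; the elbow of
#' this curve as a function of k selects the number of states.
#'
#' @param X Points x features matrix.
#' @param labels Cluster assignment per point.
#' @param centroids k x features matrix.
#' @return Non-negative ratio (infinite, with a warning, if all centroids
#'   coincide).
#' @export
validity_index <- function(X, labels, centroids) {
  k <- nrow(centroids)
  if (k < 2) stop("validity index needs k >= 2")
  D <- l1_dist_to_centroids(X, centroids)
  within <- mean(D[cbind(seq_len(nrow(X)), labels)])
  cd <- c()
  for (a in seq_len(k - 1))
    for (b in (a + 1):k)
      cd <- c(cd, sum(abs(centroids[a, ] - centroids[b, ])))
  between <- mean(cd)
  if (between == 0) {
    warning("coincident centroids: validity index is infinite")
    return(Inf)
  }
  within / between
}

#' Select the number of states at the elbow of the validity-index curve
#'
#' Runs [kmeans_manhattan()] for each k in `k_range`, computes the validity
#' index, and selects the point of maximum curvature. So that the smallest
#' k can be selected, the curve is extended on the left with a pseudo-index
#' at k = 1 (total within-distance to the global median, normalized by the
#' k = 2 between-centroid distance). Curvature is located by the standard
#' knee rule: the curve is normalized to the unit square and the elbow is
#' the k lying farthest below the chord joining its endpoints; when no
#' point deviates from the chord by more than `knee_threshold` (the curve
#' declines featurelessly, as for unstructured data) the smallest k is
#' returned. A flat curve (range below `1e-6`) falls back to the smallest k
#' with a warning.
#'
#' @param X Points x features matrix.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param n_replicates,max_iter,seed Passed to [kmeans_manhattan()].
#' @param knee_threshold Minimum below-chord deviation (on the normalized
#'   curve) required to call an elbow.
#' @return List: `k` (selected), `curve` (data frame of k, validity index,
#'   cost), `deviation` (below-chord profile over the extended curve), and
#'   the per-k clustering `fits`.
#' @export
elbow_select_k <- function(X, k_range = 2:8, n_replicates = 100,
                           max_iter = 300, seed = 1L,
                           knee_threshold = 0.12) {
  X <- as.matrix(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) >= nrow(X))
    stop("k_range must lie within [2, n points)")
  fits <- list(); vi <- numeric(length(k_range)); cost <- numeric(length(k_range))
  for (m in seq_along(k_range)) {
    fit <- kmeans_manhattan(X, k_range[m], n_replicates = n_replicates,
                            max_iter = max_iter, seed = seed + k_range[m])
    fits[[m]] <- fit
    vi[m] <- validity_index(X, fit$labels, fit$centroids)
    cost[m] <- fit$cost
  }
  curve <- data.frame(k = k_range, validity = vi, cost = cost)
  if (diff(range(vi[is.finite(vi)])) < 1e-6) {
    warning("validity-index curve is flat; selecting the smallest k")
    return(list(k = k_range[1], curve = curve, deviation = NULL, fits = fits))
  }
  gmed <- apply(X, 2, stats::median)
  w1 <- mean(rowSums(abs(X - matrix(gmed, nrow(X), ncol(X), byrow = TRUE))))
  C2 <- fits[[1]]$centroids
  b2 <- mean(l1_dist_to_centroids(C2, C2)[upper.tri(diag(nrow(C2)))])
  ext <- c(w1 / b2, vi)                 # index curve extended to k = 1
  ks <- c(k_range[1] - 1L, k_range)
  y <- (ext - min(ext)) / diff(range(ext))
  x <- (ks - min(ks)) / diff(range(ks))
  chord <- y[1] + (y[length(y)] - y[1]) * x
  dev_below <- chord - y
  k_star <- if (max(dev_below) < knee_threshold) k_range[1] else
    max(ks[which.max(dev_below)], k_range[1])
  list(k = k_star, curve = curve, deviation = dev_below, fits = fits)
}

#' Two-level state clustering across a cohort
#'
#' First level: the windowed IBS matrices are averaged across dyads (all
#' task windows pooled) and clustered with [kmeans_manhattan()] at the
#' elbow-selected k. Second level: each dyad's windows are clustered by a
#' single k-means run initialized at the group centroids. States are then
#' relabeled in descending order of group-centroid global efficiency, so
#' state 1 is always the densest, most efficient inter-brain network.
#'
#' @param series_list List of `ibs_window_series`, one per dyad, on a
#'   common window grid.
#' @param k Fixed number of states; `NULL` (default) selects k by
#'   [elbow_select_k()].
#' @param k_range Candidate k values for the elbow search.
#' @param n_replicates Random restarts for the group-level clustering.
#' @param seed Integer seed.
#' @param dyad_update `"none"` (default): label dyad windows by their
#'   nearest group centroid without updating (per-dyad state centroids are
#'   then medians of the assigned windows); `"kmeans"`: a full k-means run
#'   per dyad initialized at the group centroids. On synthetic cohorts the
#'   full per-dyad update drifts toward dyad-specific noise and degrades
#'   recovery of planted states, so labeling-only is the default. The
#'   centroid drift between levels is reported either way.
#' @return A `state_partition`: `k`, relabeled `group_centroids` (list of
#'   ROI x ROI matrices), per-dyad `labels` (windows), per-dyad
#'   `dyad_centroids`, `window_task`, the elbow `selection` audit, and the
#'   mean centroid drift between dyad- and group-level centroids.
#' @export
cluster_group_then_dyads <- function(series_list, k = NULL, k_range = 2:8,
                                     n_replicates = 1000, seed = 1L,
                                     dyad_update = c("none", "kmeans")) {
  dyad_update <- match.arg(dyad_update)
  n_win <- dim(series_list[[1]]$win)[3]
  n_rois <- dim(series_list[[1]]$win)[1]
  for (s in series_list) {
    if (!identical(dim(s$win), dim(series_list[[1]]$win)) ||
        !identical(s$window_task, series_list[[1]]$window_task))
      stop("dyads have mismatched window grids")
  }
  Xs <- lapply(series_list, vectorize_windows)
  Xg <- Reduce(`+`, Xs) / length(Xs)
  selection <- NULL
  if (is.null(k)) {
    selection <- elbow_select_k(Xg, k_range = k_range,
                                n_replicates = max(20, n_replicates %/% 10),
                                seed = seed)
    k <- selection$k
  }
  gfit <- kmeans_manhattan(Xg, k, n_replicates = n_replicates, seed = seed)
  # order states by descending global efficiency of the group centroids
  cent_mats <- lapply(seq_len(k), function(c_i)
    unvectorize_window(gfit$centroids[c_i, ], n_rois))
  ge <- vapply(cent_mats, function(m)
    global_efficiency(centroid_to_graph(m)), numeric(1))
  ord <- order(ge, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)       # old label -> new label
  group_centroids <- cent_mats[ord]
  dyad_fits <- lapply(Xs, function(X) {
    if (dyad_update == "kmeans")
      return(kmeans_manhattan(X, k, init = gfit$centroids))
    D <- l1_dist_to_centroids(X, gfit$centroids)
    labels <- max.col(-D, ties.method = "first")
    C <- gfit$centroids
    for (c_i in seq_len(k)) {
      if (any(labels == c_i))  # states absent from a dyad keep group centroid
        C[c_i, ] <- apply(X[labels == c_i, , drop = FALSE], 2, stats::median)
    }
    list(centroids = C, labels = labels,
         cost = sum(D[cbind(seq_len(nrow(X)), labels)]))
  })
  labels <- lapply(dyad_fits, function(f) relabel[f$labels])
  dyad_centroids <- lapply(dyad_fits, function(f)
    lapply(ord, function(c_i) unvectorize_window(f$centroids[c_i, ], n_rois)))
  drift <- mean(vapply(dyad_fits, function(f)
    mean(abs(f$centroids - gfit$centroids)), numeric(1)))
  structure(list(k = k, group_centroids = group_centroids,
                 group_labels = relabel[gfit$labels], labels = labels,
                 dyad_centroids = dyad_centroids,
                 window_task = series_list[[1]]$window_task,
                 window_start = series_list[[1]]$window_start,
                 globE = sort(ge, decreasing = TRUE),
                 selection = selection, centroid_drift = drift, seed = seed),
            class = "state_partition")
}

#' Majority-vote truth label per window (synthetic recordings)
#'
#' Maps a trimmed recording's per-second latent state labels onto the task
#' window grid: each window takes the majority state over the seconds it
#' covers.
#'
#' @param recording A preprocessed synthetic `dyad_recording` carrying
#'   `truth_states` (task-edge trims in `$trim` are honoured).
#' @param window_start Window start times (s) within the concatenated task
#'   period, as stored in an `ibs_window_series`.
#' @param window_length Window length (s).
#' @return Integer vector of truth states per window.
#' @export
window_truth_labels <- function(recording, window_start, window_length) {
  if (is.null(recording$truth_states)) stop("recording has no truth states")
  ann <- recording$annotations
  trim <- recording$trim
  if (is.null(trim)) trim <- list(head = 0, tail = 0)
  task_secs <- integer(0)
  for (r in which(ann$label != "rest"))
    task_secs <- c(task_secs, seq(ann$start[r] + trim$head,
                                  ann$end[r] - trim$tail - 1))
  truth_task <- recording$truth_states[task_secs + 1L]
  vapply(window_start, function(s0) {
    span <- truth_task[(floor(s0) + 1):min(length(truth_task),
                                           floor(s0) + window_length)]
    as.integer(names(which.max(table(span))))
  }, integer(1))
}

#' Align estimated state labels to truth by best permutation
#'
#' Enumerates all relabelings of the estimated states and returns the one
#' maximizing agreement with the truth labels.
#'
#' @param est,truth Equal-length integer label vectors.
#' @param k Number of states.
#' @return List: `accuracy` (agreement fraction under the best permutation)
#'   and `mapping` (estimated label -> truth label).
#' @export
align_states <- function(est, truth, k = max(est, truth)) {
  stopifnot(length(est) == length(truth))
  conf <- matrix(0, k, k)
  for (a in seq_len(k))
    for (b in seq_len(k))
      conf[a, b] <- sum(est == a & truth == b)
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(conf[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  list(accuracy = max(scores) / length(est), mapping = best)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
  out
}
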