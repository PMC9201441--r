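# ROI-level inter-brain synchrony: cross-participant ROI pairing with
# reciprocal averaging, data-driven frequency-band selection, and
# sliding-window segmentation of the z-transformed coherence.

#' Average channels into ROI series
#'
#' @param recording A `dyad_recording`.
#' @param chromophore `"hbo"` (default; synchrony analysis uses HbO) or
#'   `"hbr"`.
#' @return List of two `n_rois` x time matrices (one per participant) with
#'   ROI row names; each ROI series is the mean of its member channels.
#' @export
channels_to_roi <- function(recording, chromophore = "hbo") {
  validate_dyad_recording(recording)
  rois <- unique(unname(recording$roi_map))
  lapply(1:2, function(p) {
    X <- recording[[chromophore]][[p]]
    out <- matrix(0, length(rois), ncol(X), dimnames = list(rois, NULL))
    for (r in rois) {
      ch <- names(recording$roi_map)[recording$roi_map == r]
      if (length(ch) == 0) stop("ROI ", r, " has no channels")
      out[r, ] <- colMeans(X[ch, , drop = FALSE])
    }
    out
  })
}

#' Unordered ROI pair index
#'
#' All unordered cross-participant ROI pairings including homologous
#' (same-ROI) pairs: `n * (n + 1) / 2` rows (91 for 13 ROIs).
#'
#' @param n_rois Number of ROIs.
#' @return Data frame with columns `i`, `j` (`i <= j`).
#' @export
roi_pair_index <- function(n_rois) {
  idx <- which(upper.tri(diag(n_rois), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(i = idx[, "row"], j = idx[, "col"])
}

#' Reduce ordered cross-participant pairings to unordered ROI pairs
#'
#' Entry (i, j) of the unordered table is the mean of the two reciprocal
#' cross-participant pairings (participant 1's ROI i with participant 2's
#' ROI j, and vice versa); homologous entries (i, i) are the single
#' cross-participant pairing. Relabeling the participants leaves the table
#' unchanged.
#'
#' @param coh Array whose first two dimensions index participant 1's and
#'   participant 2's ROIs (any trailing dimensions carried through).
#' @return List with `pairs` (the [roi_pair_index()]) and `values` (array
#'   with first dimension indexing pairs).
#' @export
build_roi_pair_table <- function(coh) {
  d <- dim(coh)
  if (is.null(d) || length(d) < 2 || d[1] != d[2])
    stop("coh must be an array with square leading dimensions")
  if (anyNA(coh)) stop("missing ordered pairing(s) in coherence array")
  n <- d[1]
  pairs <- roi_pair_index(n)
  rest <- if (length(d) > 2) d[-(1:2)] else integer(0)
  out <- array(0, dim = c(nrow(pairs), rest))
  flat <- matrix(coh, nrow = n * n)
  outm <- matrix(out, nrow = nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    a <- flat[(j - 1) * n + i, ]
    b <- flat[(i - 1) * n + j, ]
    outm[k, ] <- if (i == j) a else (a + b) / 2
  }
  list(pairs = pairs, values = array(outm, dim = c(nrow(pairs), rest)))
}

# sliding-window start indices (samples); window/step given in seconds
sliding_window_index <- function(n_samples, fs, window_length, step) {
  wl <- as.integer(round(window_length * fs))
  st <- as.integer(round(step * fs))
  if (wl > n_samples) stop("window longer than the available series")
  starts <- seq(1L, n_samples - wl + 1L, by = st)
  list(starts = starts, wl = wl, st = st)
}

# Per-participant CWT cache: one cwt + smoothed auto power per ROI.
participant_cwt_cache <- function(roi_mat, fs, spec) {
  out <- lapply(seq_len(nrow(roi_mat)), function(r) {
    cw <- cwt_morlet(roi_mat[r, ], fs, spec)
    list(cw = cw, P = smoothed_power(cw))
  })
  names(out) <- rownames(roi_mat)
  out
}

#' Dyad-level IBS: z-coherence per ROI pair, reduced for downstream stages
#'
#' Computes wavelet coherence between every ordered cross-participant ROI
#' pairing, Fisher-transforms the coherence value, averages reciprocal
#' pairings into the unordered ROI-pair table, and reduces each pair's
#' (scale x time) z-map to (a) mean task-period and rest-period values per
#' scale (for frequency-band selection) and (b) sliding-window means over
#' the concatenated task period (for state clustering).
#'
#' @param recording A preprocessed `dyad_recording`. The wavelet transform
#'   runs on the continuous series; the task-edge trims stored by
#'   [preprocess_recording()] (or zero trims if absent) are applied as
#'   sample masks here, so no splice discontinuities enter the transform.
#' @param spec A [wavelet_spec()].
#' @param window_length Window length in seconds (default 10).
#' @param step Window increment in seconds (default 1).
#' @param caches Optional precomputed pair of participant CWT caches (used
#'   by the permutation machinery to re-pair participants cheaply).
#' @return A `dyad_ibs` object: `zwin` (scales x windows x pairs),
#'   `scale_task`/`scale_rest` (scales x pairs), pair index, frequency
#'   axes, per-window task label and start time.
#' @export
dyad_ibs <- function(recording, spec = wavelet_spec(), window_length = 10,
                     step = 1, caches = NULL) {
  fs <- recording$fs
  ann <- recording$annotations
  n <- if (is.null(caches)) ncol(recording$hbo[[1]]) else
    caches[[1]][[1]]$cw$n
  tsec <- (seq_len(n) - 1) / fs
  trim <- recording$trim
  if (is.null(trim)) trim <- list(head = 0, tail = 0)
  sess_of_samp <- rep(NA_character_, n)
  kept <- rep(FALSE, n)
  for (k in seq_len(nrow(ann))) {
    in_sess <- tsec >= ann$start[k] & tsec < ann$end[k]
    sess_of_samp[in_sess] <- ann$label[k]
    if (ann$label[k] == "rest") {
      kept <- kept | in_sess
    } else {
      kept <- kept | (tsec >= ann$start[k] + trim$head &
                        tsec < ann$end[k] - trim$tail)
    }
  }
  task_mask <- kept & sess_of_samp != "rest"
  rest_mask <- kept & sess_of_samp == "rest"
  if (!any(task_mask)) stop("no task samples in recording")
  if (is.null(caches)) {
    roi <- channels_to_roi(recording, "hbo")
    caches <- lapply(roi, participant_cwt_cache, fs = fs, spec = spec)
  }
  roi_names <- names(caches[[1]])
  n_rois <- length(caches[[1]])
  pairs <- roi_pair_index(n_rois)
  freqs <- caches[[1]][[1]]$cw$freqs
  ns <- length(freqs)
  task_idx <- which(task_mask)
  widx <- sliding_window_index(length(task_idx), fs, window_length, step)
  n_win <- length(widx$starts)

  zwin <- array(0, dim = c(ns, n_win, nrow(pairs)))
  scale_task <- matrix(0, ns, nrow(pairs))
  scale_rest <- matrix(0, ns, nrow(pairs))

  z_ordered <- function(i, j) {
    co <- coherence_from_cwt(caches[[1]][[i]]$cw, caches[[2]][[j]]$cw,
                             Px = caches[[1]][[i]]$P, Py = caches[[2]][[j]]$P)
    fisher_z(sqrt(co$R2))
  }
  window_means <- function(z_task) {
    cs <- cbind(0, t(apply(z_task, 1, cumsum)))
    lo <- widx$starts
    hi <- widx$starts + widx$wl - 1L
    (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) / widx$wl
  }
  # Task/rest scale profiles exclude points whose smoothing support
  # touches the recording edges (within 3 scale lengths): edge-padded
  # smoothing inflates coherence there, which would bias the short rest
  # blocks at the recording boundaries. Windows keep all points (they sit
  # mid-recording).
  scales_s <- caches[[1]][[1]]$cw$scales
  t_edge <- pmin(tsec, tsec[n] - tsec)
  outside <- outer(3 * scales_s, t_edge, FUN = "<=")
  masked_mean <- function(z, m) {
    keep <- outside & matrix(m, nrow(z), length(m), byrow = TRUE)
    num <- rowSums(z * keep)
    den <- rowSums(keep)
    ifelse(den > 0, num / den, rowMeans(z[, m, drop = FALSE]))
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    z <- z_ordered(i, j)
    if (i != j) z <- (z + z_ordered(j, i)) / 2
    scale_task[, k] <- masked_mean(z, task_mask)
    if (any(rest_mask)) scale_rest[, k] <- masked_mean(z, rest_mask)
    zwin[, , k] <- window_means(z[, task_idx, drop = FALSE])
  }

  # per-window task label: majority vote, ties to the earlier task
  task_labels_samp <- sess_of_samp[task_idx]
  task_order <- unique(ann$label[ann$label != "rest"])
  window_task <- vapply(widx$starts, function(s) {
    span <- task_labels_samp[s:(s + widx$wl - 1L)]
    tab <- table(factor(span, levels = task_order))
    names(tab)[which.max(tab)]  # which.max takes the first (earlier) on ties
  }, character(1))
  window_start <- (widx$starts - 1L) / fs

  structure(list(dyad_id = recording$dyad_id, zwin = zwin,
                 scale_task = scale_task, scale_rest = scale_rest,
                 pairs = pairs, freqs = freqs, periods = 1 / freqs,
                 roi_names = if (is.null(roi_names))
                   paste0("ROI", seq_len(n_rois)) else roi_names,
                 n_rois = n_rois, window_task = window_task,
                 window_start = window_start,
                 window_length = window_length, step = step, fs = fs),
            class = "dyad_ibs")
}

#' Select the frequency band of interest (FOI)
#'
#' Paired t-tests across dyads compare task-period versus rest-period mean
#' z-coherence, per scale and per ROI pair, over the full analyzed range. A
#' scale is significant when any ROI pair passes `p_threshold` with task
#' greater than rest (no multiple-comparison correction: the test only
#' identifies the band). The FOI is the largest contiguous run of
#' significant scales.
#'
#' @param ibs_list List of `dyad_ibs` objects (>= 3 dyads) on a common
#'   scale grid.
#' @param p_threshold Two-sided p-value threshold (default 5e-6).
#' @return A `foi_band`: `f_lo`/`f_hi` (Hz), selected `scale_idx`, per-scale
#'   test table, and the threshold. `scale_idx` is empty when no scale is
#'   significant; downstream windowing then refuses to run.
#' @export
select_foi <- function(ibs_list, p_threshold = 5e-6) {
  if (length(ibs_list) < 3) stop("FOI selection needs >= 3 dyads")
  freqs <- ibs_list[[1]]$freqs
  ns <- length(freqs)
  np <- nrow(ibs_list[[1]]$pairs)
  nd <- length(ibs_list)
  D <- array(0, dim = c(nd, ns, np))
  for (d in seq_len(nd)) {
    stopifnot(length(ibs_list[[d]]$freqs) == ns)
    D[d, , ] <- ibs_list[[d]]$scale_task - ibs_list[[d]]$scale_rest
  }
  mu <- apply(D, c(2, 3), mean)
  sdv <- apply(D, c(2, 3), stats::sd)
  tstat <- mu / (sdv / sqrt(nd))
  tstat[sdv == 0] <- ifelse(mu[sdv == 0] == 0, 0, Inf * sign(mu[sdv == 0]))
  pval <- 2 * stats::pt(-abs(tstat), df = nd - 1)
  sig_pair <- (pval < p_threshold) & (tstat > 0)
  sig_scale <- apply(sig_pair, 1, any)
  runs <- rle(sig_scale)
  scale_idx <- integer(0)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    tr <- which(runs$values)
    best <- tr[which.max(runs$lengths[tr])]
    scale_idx <- starts[best]:ends[best]
  }
  tab <- data.frame(freq = freqs, period = 1 / freqs,
                    n_sig_pairs = rowSums(sig_pair),
                    min_p = apply(pval, 1, min),
                    max_t = apply(tstat, 1, max))
  structure(list(
    f_lo = if (length(scale_idx)) min(freqs[scale_idx]) else NA_real_,
    f_hi = if (length(scale_idx)) max(freqs[scale_idx]) else NA_real_,
    scale_idx = scale_idx, table = tab, p_threshold = p_threshold,
    n_dyads = nd), class = "foi_band")
}

#' Windowed IBS matrices over the selected frequency band
#'
#' Averages each dyad's windowed z-coherence over the FOI scales, producing
#' the chronological stack of symmetric ROI x ROI matrices that the state
#' clustering consumes. With 480 s of task data, 10-s windows and a 1-s
#' step, the stack holds 471 windows.
#'
#' @param dibs A `dyad_ibs` object.
#' @param foi A [select_foi()] result (must be non-empty).
#' @return An `ibs_window_series`: array `win` (ROI x ROI x windows),
#'   per-window task label and start time.
#' @export
window_ibs <- function(dibs, foi) {
  if (length(foi$scale_idx) == 0)
    stop("empty frequency band of interest: no scale showed task > rest ",
         "synchrony at the configured threshold; cannot window")
  sel <- foi$scale_idx
  n_rois <- dibs$n_rois
  n_win <- dim(dibs$zwin)[2]
  vals <- apply(dibs$zwin[sel, , , drop = FALSE], c(2, 3), mean)  # win x pair
  win <- array(0, dim = c(n_rois, n_rois, n_win),
               dimnames = list(dibs$roi_names, dibs$roi_names, NULL))
  for (k in seq_len(nrow(dibs$pairs))) {
    i <- dibs$pairs$i[k]; j <- dibs$pairs$j[k]
    win[i, j, ] <- vals[, k]
    win[j, i, ] <- vals[, k]
  }
  structure(list(dyad_id = dibs$dyad_id, win = win,
                 window_task = dibs$window_task,
                 window_start = dibs$window_start,
                 window_length = dibs$window_length, step = dibs$step),
            class = "ibs_window_series")
}
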