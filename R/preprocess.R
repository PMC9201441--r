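# Preprocessing chain: global PCA spatial filter -> CBSI motion correction
# -> task-session trimming. Order is fixed; each step is pure.

#' Preprocessing configuration
#'
#' @param n_components_removed Number of leading principal components across
#'   channels projected out per participant and chromophore (global
#'   systemic-signal removal). 0 disables the filter.
#' @param trim_head,trim_tail Seconds removed from the start/end of each
#'   task session to keep only the steady-state period.
#' @param cbsi_enabled Apply correlation-based signal improvement (CBSI)
#'   motion correction per channel.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(n_components_removed = 1, trim_head = 30,
                              trim_tail = 30, cbsi_enabled = TRUE) {
  stopifnot(trim_head >= 0, trim_tail >= 0, n_components_removed >= 0)
  structure(list(n_components_removed = as.integer(n_components_removed),
                 trim_head = trim_head, trim_tail = trim_tail,
                 cbsi_enabled = isTRUE(cbsi_enabled)),
            class = "preprocess_config")
}

#' Global PCA spatial filter
#'
#' Removes systemic components shared across channels: per participant and
#' chromophore, channels are centered, the leading `n_components` principal
#' components across channels are estimated by SVD, and their projection is
#' subtracted from every channel. Zero-variance channels are excluded from
#' the decomposition and passed through unchanged (with a warning).
#'
#' @param recording A `dyad_recording`.
#' @param n_components Number of spatial components to remove; must be less
#'   than the number of (non-constant) channels.
#' @return The filtered `dyad_recording`.
#' @export
pca_spatial_filter <- function(recording, n_components = 1) {
  validate_dyad_recording(recording)
  n_components <- as.integer(n_components)
  if (n_components == 0) return(recording)
  for (p in 1:2) {
    for (chrom in c("hbo", "hbr")) {
      X <- recording[[chrom]][[p]]
      if (nrow(X) < 2) stop("need >= 2 channels per participant")
      sds <- apply(X, 1, stats::sd)
      keep <- sds > 0
      if (!all(keep))
        warning("constant channels excluded from PCA filter: ",
                paste(rownames(X)[!keep], collapse = ", "))
      Xk <- X[keep, , drop = FALSE]
      if (n_components >= nrow(Xk))
        stop("n_components must be smaller than the channel count")
      mu <- rowMeans(Xk)
      Xc <- Xk - mu
      # spatial PCA: components are directions across channels
      sv <- svd(Xc, nu = n_components, nv = 0)
      U <- sv$u  # channels x n_components
      Xf <- Xc - U %*% (t(U) %*% Xc)
      X[keep, ] <- Xf + mu
      recording[[chrom]][[p]] <- X
    }
  }
  recording
}

#' Correlation-based signal improvement (CBSI)
#'
#' Motion correction exploiting the physiological anti-correlation of HbO
#' and HbR: motion artifacts move both chromophores in the same direction,
#' so the corrected signals `x0 = (x - alpha * y) / 2` with
#' `alpha = sd(x) / sd(y)` and `y0 = -x0 / alpha` cancel the common-mode
#' component and are exactly anti-correlated.
#'
#' @param hbo,hbr Equal-length numeric series for one channel.
#' @return List with `hbo`, `hbr` (corrected series) and `alpha` (the scale
#'   ratio, kept for audit).
#' @export
cbsi_correct <- function(hbo, hbr) {
  if (length(hbo) != length(hbr)) stop("hbo and hbr must have equal length")
  if (anyNA(hbo) || anyNA(hbr)) stop("NA values in input series")
  s_y <- stats::sd(hbr)
  if (s_y == 0) stop("zero-variance HbR series: CBSI undefined")
  alpha <- stats::sd(hbo) / s_y
  x0 <- (hbo - alpha * hbr) / 2
  y0 <- -x0 / alpha
  list(hbo = x0, hbr = y0, alpha = alpha)
}

apply_cbsi <- function(recording) {
  for (p in 1:2) {
    ho <- recording$hbo[[p]]; hr <- recording$hbr[[p]]
    for (ch in seq_len(nrow(ho))) {
      res <- tryCatch(cbsi_correct(ho[ch, ], hr[ch, ]),
                      error = function(e)
                        stop("CBSI failed on channel ", rownames(ho)[ch],
                             ": ", conditionMessage(e)))
      ho[ch, ] <- res$hbo; hr[ch, ] <- res$hbr
    }
    recording$hbo[[p]] <- ho; recording$hbr[[p]] <- hr
  }
  recording
}

#' Trim the unsteady edges of each task session
#'
#' Drops the first `trim_head` and last `trim_tail` seconds of every task
#' session (rest sessions are kept whole), splices the remaining samples
#' together, and rebuilds contiguous annotations. Per-second truth labels,
#' when present, are trimmed identically. With the default two 300-s tasks
#' and 30-s trims, 480 s of task data remain.
#'
#' @param recording A `dyad_recording`.
#' @param cfg A [preprocess_config()].
#' @return The trimmed `dyad_recording`.
#' @export
trim_sessions <- function(recording, cfg = preprocess_config()) {
  validate_dyad_recording(recording)
  fs <- recording$fs
  ann <- recording$annotations
  keep_samp <- integer(0)
  new_ann <- list()
  t_acc <- 0
  n <- ncol(recording$hbo[[1]])
  for (k in seq_len(nrow(ann))) {
    is_task <- ann$label[k] != "rest"
    head_cut <- if (is_task) cfg$trim_head else 0
    tail_cut <- if (is_task) cfg$trim_tail else 0
    dur <- ann$end[k] - ann$start[k]
    if (is_task && dur <= head_cut + tail_cut)
      stop("session ", k, " (", ann$label[k], ") shorter than its trims")
    lo <- ann$start[k] + head_cut
    hi <- ann$end[k] - tail_cut
    tsec <- (seq_len(n) - 1) / fs
    keep_samp <- c(keep_samp, which(tsec >= lo & tsec < hi))
    new_dur <- hi - lo
    new_ann[[k]] <- data.frame(label = ann$label[k], start = t_acc,
                               end = t_acc + new_dur)
    t_acc <- t_acc + new_dur
  }
  keep_samp <- unique(sort(keep_samp))
  for (p in 1:2) {
    recording$hbo[[p]] <- recording$hbo[[p]][, keep_samp, drop = FALSE]
    recording$hbr[[p]] <- recording$hbr[[p]][, keep_samp, drop = FALSE]
  }
  if (!is.null(recording$truth_states)) {
    secs_all <- seq_len(length(recording$truth_states)) - 1
    keep_tr <- rep(FALSE, length(secs_all))
    for (k in seq_len(nrow(ann))) {
      is_task <- ann$label[k] != "rest"
      lo <- ann$start[k] + if (is_task) cfg$trim_head else 0
      hi <- ann$end[k] - if (is_task) cfg$trim_tail else 0
      keep_tr <- keep_tr | (secs_all >= lo & secs_all < hi)
    }
    recording$truth_states <- recording$truth_states[keep_tr]
  }
  recording$annotations <- do.call(rbind, new_ann)
  recording$n_time <- length(keep_samp)
  recording
}

#' Run the full preprocessing chain
#'
#' Fixed order: global PCA spatial filter, then CBSI motion correction.
#' The task-edge trims are attached to the recording and applied as sample
#' masks by the coherence reduction ([dyad_ibs()]) rather than by splicing
#' the series: physically concatenating non-contiguous segments creates
#' jump discontinuities that are time-locked across both participants and
#' produce spurious wavelet coherence around every splice point, so the
#' transform must see the continuous recording. [trim_sessions()] remains
#' available for workflows that need a physically trimmed recording.
#' Downstream synchrony analysis uses the HbO series; CBSI-corrected HbR
#' is retained for audit.
#'
#' @param recording A `dyad_recording`.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `dyad_recording`, carrying the trim
#'   configuration in `$trim` and a `preprocess` provenance entry.
#' @export
preprocess_recording <- function(recording, cfg = preprocess_config()) {
  rec <- pca_spatial_filter(recording, cfg$n_components_removed)
  if (cfg$cbsi_enabled) rec <- apply_cbsi(rec)
  rec$trim <- list(head = cfg$trim_head, tail = cfg$trim_tail)
  rec$preprocess <- list(order = c("pca_spatial_filter", "cbsi",
                                   "trim_mask"),
                         config = unclass(cfg))
  rec
}
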