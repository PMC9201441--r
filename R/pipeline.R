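# File formats, probe-geometry utilities, configuration, and the
# end-to-end pipeline driver.

#' Optode probe grid and its channel count
#'
#' In an alternating source/detector lattice, measurement channels exist
#' between lattice-adjacent optode pairs, giving
#' `rows * (cols - 1) + cols * (rows - 1)` channels (22 for a 3x5 set, 24
#' for a 4x4 set).
#'
#' @param rows,cols Lattice dimensions (>= 1).
#' @return A `probe_grid` list.
#' @export
probe_grid <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "probe_grid")
}

#' @rdname probe_grid
#' @param grid A [probe_grid()].
#' @export
channel_count <- function(grid) {
  grid$rows * (grid$cols - 1L) + grid$cols * (grid$rows - 1L)
}

#' Write / read a dyadic recording as long-format CSV
#'
#' The canonical interchange format: columns `dyad`, `participant`,
#' `channel`, `roi`, `chromophore`, `t`, `value`, with sampling rate and
#' session annotations in a JSON sidecar (`<path>.meta.json`) and optional
#' per-second truth states in `<path>.truth.csv`. Round-trips are lossless
#' to numerical precision.
#'
#' @param recording A `dyad_recording`.
#' @param path CSV file path.
#' @param digits Significant digits written (default 12).
#' @return `write_recording_csv`: the path, invisibly.
#'   `read_recording_csv`: the reconstructed `dyad_recording`.
#' @export
write_recording_csv <- function(recording, path, digits = 12) {
  validate_dyad_recording(recording)
  n <- ncol(recording$hbo[[1]])
  tvec <- (seq_len(n) - 1) / recording$fs
  rows <- list()
  for (p in 1:2) {
    for (chrom in c("hbo", "hbr")) {
      X <- recording[[chrom]][[p]]
      for (ch in rownames(X)) {
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = recording$dyad_id, participant = p, channel = ch,
          roi = unname(recording$roi_map[ch]), chromophore = chrom,
          t = tvec, value = signif(X[ch, ], digits),
          stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(dyad_id = recording$dyad_id, fs = recording$fs,
               annotations = recording$annotations)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(recording$truth_states)) {
    utils::write.csv(data.frame(second = seq_along(recording$truth_states) - 1,
                                state = recording$truth_states),
                     paste0(path, ".truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad", "participant", "channel", "roi", "chromophore", "t", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed recording CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tvec <- sort(unique(df$t))
  channels <- unique(df$channel[df$participant == 1])
  roi_map <- stats::setNames(
    df$roi[match(channels, df$channel)], channels)
  build <- function(p, chrom) {
    X <- matrix(0, length(channels), length(tvec),
                dimnames = list(channels, NULL))
    sub <- df[df$participant == p & df$chromophore == chrom, ]
    for (ch in channels) {
      sc <- sub[sub$channel == ch, ]
      X[ch, ] <- sc$value[order(sc$t)]
    }
    X
  }
  truth <- NULL
  tp <- paste0(path, ".truth.csv")
  if (file.exists(tp)) truth <- utils::read.csv(tp)$state
  structure(list(dyad_id = meta$dyad_id, fs = meta$fs,
                 hbo = list(build(1, "hbo"), build(2, "hbo")),
                 hbr = list(build(1, "hbr"), build(2, "hbr")),
                 roi_map = roi_map,
                 annotations = as.data.frame(meta$annotations),
                 truth_states = truth,
                 n_time = length(tvec)),
            class = "dyad_recording")
}

#' Pipeline configuration
#'
#' Bundles all stage configurations. Unknown argument names are rejected.
#'
#' @param wavelet A [wavelet_spec()].
#' @param preprocess A [preprocess_config()].
#' @param foi_p_threshold Band-selection p-value threshold.
#' @param window_length,step Sliding-window parameters (s).
#' @param k Fixed state count, or `NULL` for elbow selection.
#' @param k_range Candidate k values for the elbow search.
#' @param n_replicates Random restarts for group-level clustering.
#' @param seed Integer seed.
#' @param out_dir Optional artifact directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(wavelet = wavelet_spec(),
                            preprocess = preprocess_config(),
                            foi_p_threshold = 5e-6,
                            window_length = 10, step = 1,
                            k = NULL, k_range = 2:8,
                            n_replicates = 1000, seed = 1L,
                            out_dir = NULL) {
  structure(list(wavelet = wavelet, preprocess = preprocess,
                 foi_p_threshold = foi_p_threshold,
                 window_length = window_length, step = step, k = k,
                 k_range = k_range, n_replicates = n_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; nested
#' `wavelet` and `preprocess` maps mirror [wavelet_spec()] and
#' [preprocess_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("wavelet", "preprocess", "foi_p_threshold", "window_length",
             "step", "k", "k_range", "n_replicates", "seed", "out_dir")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- y
  if (!is.null(y$wavelet)) args$wavelet <- do.call(wavelet_spec, y$wavelet)
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  do.call(pipeline_config, args)
}

#' Run the full dynamic inter-brain synchrony pipeline on a cohort
#'
#' Stages, in order: preprocessing (spatial filter, CBSI, trimming),
#' wavelet coherence and ROI-pair reduction per dyad, frequency-band
#' selection across the cohort, sliding-window segmentation, two-level
#' state clustering, state/network metrics, behavioral scoring (when logs
#' are present), and the inferential tests: RM-ANOVA of centroid global
#' efficiency and path length across states, RM-ANOVA of occurrence across
#' states per task, per-state task contrasts, a task contrast of
#' transition counts, and Pearson correlations of state-1 occurrence with
#' originality and the index of cooperation.
#'
#' @param cohort A `cohort` (see [generate_cohort()]) or any list of
#'   elements each holding a `recording` (and optionally `behavior`).
#' @param config A [pipeline_config()].
#' @return A `dibs_result` bundle: `foi`, `partition`, `metrics`,
#'   `behavior`, `stats`, and provenance. Artifacts are written as
#'   CSV/JSON when `config$out_dir` is set.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  preproc <- lapply(cohort, function(d)
    preprocess_recording(d$recording, config$preprocess))
  ibs_list <- lapply(preproc, dyad_ibs, spec = config$wavelet,
                     window_length = config$window_length,
                     step = config$step)
  foi <- select_foi(ibs_list, p_threshold = config$foi_p_threshold)
  if (length(foi$scale_idx) == 0)
    stop("pipeline halted: empty frequency band of interest (no scale with ",
         "task > rest synchrony at p < ", config$foi_p_threshold, ")")
  series <- lapply(ibs_list, window_ibs, foi = foi)
  partition <- cluster_group_then_dyads(series, k = config$k,
                                        k_range = config$k_range,
                                        n_replicates = config$n_replicates,
                                        seed = config$seed)
  dyad_ids <- vapply(cohort, function(d) d$recording$dyad_id, character(1))
  metrics <- state_metrics(partition, dyad_ids)
  k <- partition$k
  nd <- length(cohort)

  behavior <- NULL
  if (!is.null(cohort[[1]]$behavior))
    behavior <- score_cohort_behavior(cohort)

  # dyad x state matrices for the omnibus tests
  mat_of <- function(col, task = NULL) {
    m <- matrix(0, nd, k)
    for (d in seq_len(nd)) {
      sel <- metrics[metrics$dyad == dyad_ids[d], ]
      if (!is.null(task)) sel <- sel[sel$task == task, ]
      m[d, ] <- vapply(seq_len(k), function(s)
        sel[[col]][sel$state == s][1], numeric(1))
    }
    m
  }
  tasks <- unique(metrics$task)
  stats_out <- list(
    globE_states = rm_anova_oneway(mat_of("globE")),
    Lp_states = rm_anova_oneway(mat_of("Lp"))
  )
  occ_by_task <- lapply(tasks, function(tk) mat_of("occurrence", tk))
  names(occ_by_task) <- tasks
  for (tk in tasks)
    stats_out[[paste0("occurrence_states_", tk)]] <-
      rm_anova_oneway(occ_by_task[[tk]])
  if (length(tasks) == 2) {
    for (s in seq_len(k)) {
      Y <- cbind(occ_by_task[[1]][, s], occ_by_task[[2]][, s])
      colnames(Y) <- tasks
      stats_out[[paste0("occurrence_task_contrast_state", s)]] <-
        rm_anova_oneway(Y)
    }
    tr <- matrix(0, nd, 2)
    for (d in seq_len(nd)) {
      sel <- metrics[metrics$dyad == dyad_ids[d], ]
      tr[d, ] <- vapply(tasks, function(tk)
        sel$transitions[sel$task == tk][1], numeric(1))
    }
    colnames(tr) <- tasks
    stats_out$transitions_task_contrast <- rm_anova_oneway(tr)
  }
  if (!is.null(behavior)) {
    occ1 <- occ_by_task[["taskA"]]
    if (is.null(occ1)) occ1 <- occ_by_task[[1]]
    ok <- function(v) stats::sd(v) > 0
    if ("originality" %in% names(behavior) && ok(behavior$originality))
      stats_out$cor_state1_originality <-
        brain_behavior_correlation(occ1[, 1], behavior$originality)
    if ("ioc_AUT" %in% names(behavior) && ok(behavior$ioc_AUT))
      stats_out$cor_state1_ioc <-
        brain_behavior_correlation(occ1[, 1], behavior$ioc_AUT)
  }

  result <- structure(list(
    foi = foi, partition = partition, metrics = metrics,
    behavior = behavior, stats = stats_out,
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("dibs")),
                      n_dyads = nd, k = k,
                      window_length = config$window_length,
                      step = config$step)),
    class = "dibs_result")
  if (!is.null(config$out_dir)) write_result_bundle(result, config$out_dir)
  result
}

write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(out_dir, "state_metrics.csv"),
                   row.names = FALSE)
  part <- result$partition
  lab_rows <- do.call(rbind, lapply(seq_along(part$labels), function(d)
    data.frame(dyad = d, window_start = part$window_start,
               task = part$window_task, state = part$labels[[d]])))
  utils::write.csv(lab_rows, file.path(out_dir, "state_labels.csv"),
                   row.names = FALSE)
  if (!is.null(part$selection))
    utils::write.csv(part$selection$curve,
                     file.path(out_dir, "validity_curve.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(f_lo = result$foi$f_lo, f_hi = result$foi$f_hi,
         p_threshold = result$foi$p_threshold,
         table = result$foi$table),
    file.path(out_dir, "foi.json"), auto_unbox = TRUE, digits = NA)
  flat_stats <- lapply(result$stats, function(s) {
    if (inherits(s, "rm_anova"))
      list(F = s$F, df = s$df, p = s$p, partial_eta2 = s$partial_eta2,
           means = as.list(s$means))
    else s
  })
  jsonlite::write_json(flat_stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$behavior))
    utils::write.csv(result$behavior,
                     file.path(out_dir, "behavior_scores.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
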