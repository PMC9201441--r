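# Synthetic dyadic fNIRS generator: plants latent inter-brain coupling states
# in realistic hemodynamic noise so the full pipeline can be validated.

#' Simulation configuration for synthetic dyadic recordings
#'
#' Builds the configuration object consumed by [generate_state_sequence()],
#' [generate_dyad_recording()] and [generate_cohort()]. Defaults emulate a
#' dyadic hyperscanning session: a 2-min rest, two 5-min communication tasks
#' (a creative task `taskA` and a control task `taskB`), and a final 1-min
#' rest, recorded at 10 Hz over 13 regions of interest (ROIs) per
#' participant, with inter-brain coupling confined to a 0.10--0.19 Hz band.
#'
#' @param sampling_rate Sampling rate in Hz. Must exceed twice the cardiac
#'   frequency so the cardiac band stays below Nyquist.
#' @param n_rois Number of ROIs per participant.
#' @param channels_per_roi Measurement channels per ROI (channels within an
#'   ROI share the ROI signal plus channel-specific white noise).
#' @param session_plan Data frame with columns `label` (one of `"rest"`,
#'   `"taskA"`, `"taskB"`) and `duration` (seconds).
#' @param n_states Number of latent coupling states.
#' @param state_dwell_mean Mean dwell time of a state visit, in seconds.
#'   Either a single value or a named vector with one entry per session
#'   label (e.g. `c(taskA = 20, taskB = 30)`); shorter dwells produce more
#'   state transitions.
#' @param state_probs Target long-run occupancy of each state. Either a
#'   probability vector of length `n_states` or a named list of such vectors
#'   keyed by session label. Dwell times are rescaled per state so that
#'   realized occupancy converges to these targets (see
#'   [generate_state_sequence()]).
#' @param coupling_band Frequency band (Hz) carrying the planted inter-brain
#'   coupling; must lie inside (0.01, 0.7) Hz.
#' @param coupling_strength List of `n_states` symmetric `n_rois` x `n_rois`
#'   matrices with zero diagonal: entry (i, j) is the target shared variance
#'   of the band-limited signal linking the cross-participant ROI pair
#'   (i, j) while that state is active. Each connected component of a
#'   state's coupling graph is realized as one synchronous module driven by
#'   a single dyad-common source (see [generate_dyad_recording()]). `NULL`
#'   uses the default tiers: state 1 couples every ROI strongly, later
#'   states couple smaller, staggered ROI subsets more weakly.
#' @param rest_coupling_scale Multiplier applied to coupling amplitude during
#'   rest sessions (near zero: coupling is a task phenomenon).
#' @param noise_amplitudes Named vector of additive noise amplitudes (signal
#'   units): `neural` (broadband 0.01--0.5 Hz background), `drift`
#'   (< 0.01 Hz), `mayer` (~0.1 Hz), `respiration` (~0.3 Hz), `cardiac`
#'   (~1.2 Hz) and `white` (channel-level white noise).
#' @param motion_rate Motion spikes per minute (Poisson).
#' @param hbr_ratio Negative scalar: HbR = `hbr_ratio` * HbO + independent
#'   noise, emulating the physiological anti-correlation of the chromophores.
#' @param seed Integer seed used by the generators.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(sampling_rate = 10,
                       n_rois = 13,
                       channels_per_roi = 1,
                       session_plan = default_session_plan(),
                       n_states = 3,
                       state_dwell_mean = c(taskA = 25, taskB = 40, rest = 40),
                       state_probs = list(
                         taskA = c(0.08, 0.33, 0.59),
                         taskB = c(0.06, 0.19, 0.75),
                         rest  = c(0.06, 0.19, 0.75)
                       ),
                       coupling_band = c(0.10, 0.19),
                       coupling_strength = NULL,
                       rest_coupling_scale = 0.05,
                       noise_amplitudes = c(neural = 0.6, drift = 1.0,
                                            mayer = 0.3, respiration = 0.4,
                                            cardiac = 0.5, white = 0.5),
                       motion_rate = 0.5,
                       hbr_ratio = -0.5,
                       seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, n_rois = as.integer(n_rois),
    channels_per_roi = as.integer(channels_per_roi),
    session_plan = session_plan, n_states = as.integer(n_states),
    state_dwell_mean = state_dwell_mean, state_probs = state_probs,
    coupling_band = coupling_band,
    coupling_strength = coupling_strength,
    rest_coupling_scale = rest_coupling_scale,
    noise_amplitudes = noise_amplitudes, motion_rate = motion_rate,
    hbr_ratio = hbr_ratio, seed = as.integer(seed)
  )
  if (is.null(cfg$coupling_strength)) {
    cfg$coupling_strength <- default_coupling_states(cfg$n_rois, cfg$n_states)
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_session_plan <- function() {
  data.frame(label = c("rest", "taskA", "taskB", "rest"),
             duration = c(120, 300, 300, 60),
             stringsAsFactors = FALSE)
}

# Default state topologies mirror the dense efficient / sparse inefficient
# structure the clustering is meant to recover: state 1 couples all ROIs
# in one strongly synchronous module; later states couple a smaller ROI
# subset (staggered over a fixed pseudo-shuffled ROI order, so subsets
# differ between states) at weaker amplitude. States therefore differ in
# overall synchrony level, extent, and which regions carry it, and every
# state keeps some coupling (task synchrony thins out, it never vanishes).
default_coupling_states <- function(n_rois, n_states,
                                    strengths = exp(seq(log(0.8), log(0.1),
                                                        length.out = n_states)),
                                    extents = seq(1.0, 0.5,
                                                  length.out = n_states)) {
  roi_ord <- order((seq_len(n_rois) * 7) %% 11, seq_len(n_rois))
  lapply(seq_len(n_states), function(s) {
    m <- matrix(0, n_rois, n_rois)
    n_take <- max(2L, round(extents[s] * n_rois))
    offset <- round((s - 1) * n_rois / n_states)
    members <- roi_ord[((offset + seq_len(n_take) - 1L) %% n_rois) + 1L]
    m[members, members] <- strengths[s]
    diag(m) <- 0
    m
  })
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$sampling_rate <= 2 * 1.2)
    stop("sampling_rate must exceed twice the cardiac frequency (~1.2 Hz)")
  if (!all(c("label", "duration") %in% names(cfg$session_plan)))
    stop("session_plan needs columns 'label' and 'duration'")
  if (any(cfg$session_plan$duration <= 0)) stop("session durations must be positive")
  if (!all(cfg$session_plan$label %in% c("rest", "taskA", "taskB")))
    stop("session labels must be rest/taskA/taskB")
  b <- cfg$coupling_band
  if (!(b[1] > 0.01 && b[2] < 0.7 && b[1] < b[2]))
    stop("coupling_band must lie inside (0.01, 0.7) Hz")
  if (cfg$n_states < 1) stop("n_states must be >= 1")
  if (length(cfg$coupling_strength) != cfg$n_states)
    stop("coupling_strength must have one matrix per state")
  for (m in cfg$coupling_strength) {
    if (!isTRUE(all.equal(m, t(m))))
      stop("coupling_strength matrices must be symmetric")
    if (any(diag(m) != 0))
      stop("coupling_strength matrices must have zero diagonal")
    if (any(m < 0) || any(m > 1))
      stop("coupling_strength values must lie in [0, 1]")
  }
  req <- c("neural", "drift", "mayer", "respiration", "cardiac", "white")
  if (!all(req %in% names(cfg$noise_amplitudes)))
    stop("noise_amplitudes must name: ", paste(req, collapse = ", "))
  invisible(cfg)
}

# per-session lookup helpers (scalar-or-named-by-label parameters)
session_param <- function(x, label) {
  if (is.list(x)) {
    if (!is.null(x[[label]])) return(x[[label]])
    return(x[[1]])
  }
  if (!is.null(names(x)) && label %in% names(x)) return(x[[label]])
  x[[1]]
}

#' Generate a latent coupling-state sequence
#'
#' Draws a semi-Markov sequence of latent inter-brain coupling states at
#' 1-second resolution over the whole session plan. Dwell times are
#' exponential; the next state is never the current one. To make realized
#' occupancy converge to the configured `state_probs` target `p`, per-state
#' mean dwells are set to `dwell_mean * (1 - sum(p^2)) / (1 - p[i])`, which
#' compensates the embedded chain's visit frequencies exactly.
#'
#' @param cfg A [sim_config()] object.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An object of class `state_sequence`: list with `labels` (integer
#'   state per second), `segments` (data frame of dwell segments) and
#'   `session` (session label per second).
#' @export
generate_state_sequence <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  total <- sum(cfg$session_plan$duration)
  n_states <- cfg$n_states
  session_of_sec <- rep(cfg$session_plan$label, times = cfg$session_plan$duration)
  if (n_states == 1) {
    labels <- rep(1L, total)
    segs <- data.frame(state = 1L, start = 0, dur = total)
    return(structure(list(labels = labels, segments = segs,
                          session = session_of_sec),
                     class = "state_sequence"))
  }
  min_dwell_ok <- all(unlist(cfg$state_dwell_mean) >= 5)
  if (!min_dwell_ok) stop("state_dwell_mean must be >= 5 s")
  set.seed(seed)
  labels <- integer(total)
  segs <- list()
  t_now <- 0L
  cur <- NA_integer_
  while (t_now < total) {
    lab <- session_of_sec[t_now + 1L]
    p <- session_param(cfg$state_probs, lab)
    p <- p / sum(p)
    dwell_mean <- session_param(cfg$state_dwell_mean, lab)
    if (is.na(cur)) {
      cur <- sample.int(n_states, 1L, prob = p)
    } else {
      q <- p
      q[cur] <- 0
      cur <- sample.int(n_states, 1L, prob = q / sum(q))
    }
    # occupancy-matching dwell scaling (see details above)
    d_i <- dwell_mean * (1 - sum(p^2)) / (1 - p[cur])
    dwell <- max(1L, as.integer(round(stats::rexp(1, rate = 1 / d_i))))
    dwell <- min(dwell, total - t_now)
    labels[(t_now + 1L):(t_now + dwell)] <- cur
    segs[[length(segs) + 1L]] <- data.frame(state = cur, start = t_now, dur = dwell)
    t_now <- t_now + dwell
  }
  structure(list(labels = labels, segments = do.call(rbind, segs),
                 session = session_of_sec),
            class = "state_sequence")
}

# Band-limited unit-variance Gaussian noise via FFT masking with raised-cosine
# band edges (taper width 10% of the band). DC always excluded.
band_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  w <- 0.1 * (f_hi - f_lo)
  mask <- rep(0, n)
  inside <- freq >= f_lo & freq <= f_hi
  mask[inside] <- 1
  lo_edge <- freq >= (f_lo - w) & freq < f_lo
  mask[lo_edge] <- 0.5 * (1 + cos(pi * (f_lo - freq[lo_edge]) / w))
  hi_edge <- freq > f_hi & freq <= (f_hi + w)
  mask[hi_edge] <- 0.5 * (1 + cos(pi * (freq[hi_edge] - f_hi) / w))
  mask[1] <- 0
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

# Narrowband oscillation with slow frequency jitter and random phase.
jittered_sine <- function(n, fs, f0, jitter = 0.05) {
  slow <- band_noise(n, fs, 1e-4, 0.02)
  f_inst <- f0 * (1 + jitter * slow)
  phase <- 2 * pi * cumsum(f_inst) / fs + stats::runif(1, 0, 2 * pi)
  sqrt(2) * sin(phase)  # unit RMS
}

#' Generate one synthetic dyadic recording
#'
#' Synthesizes paired multi-channel HbO/HbR time series with planted
#' inter-brain coupling. While state `s` is active during a task session,
#' every ROI pair (i, j) with `coupling_strength[[s]][i, j] > 0` receives a
#' shared band-limited Gaussian signal (restricted to `coupling_band`) in
#' both cross-participant directions, so wavelet coherence between the pair
#' is elevated in-band. During rest the coupling amplitude is scaled by
#' `rest_coupling_scale`. Additive noise layers: broadband neural
#' background, slow drift, Mayer waves, respiration, cardiac oscillation
#' (all ROI-level), channel white noise, and participant-wide motion spikes
#' shared by both chromophores. HbR is `hbr_ratio` times HbO plus
#' independent white noise.
#'
#' @param cfg A [sim_config()] object.
#' @param state_seq Optional [generate_state_sequence()] result; generated
#'   from `cfg` if omitted.
#' @param dyad_id Identifier stored in the recording.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return An object of class `dyad_recording`: HbO/HbR matrices
#'   (channel x time) per participant, channel-to-ROI map, session
#'   annotations, sampling rate, and per-second `truth_states`.
#' @export
generate_dyad_recording <- function(cfg, state_seq = NULL, dyad_id = "dyad1",
                                    seed = cfg$seed) {
  validate_sim_config(cfg)
  if (is.null(state_seq)) state_seq <- generate_state_sequence(cfg, seed = seed)
  set.seed(seed + 1000L)
  fs <- cfg$sampling_rate
  total_s <- sum(cfg$session_plan$duration)
  n <- as.integer(round(total_s * fs))
  n_rois <- cfg$n_rois
  amp <- cfg$noise_amplitudes

  # per-sample state envelope: 1 during task, rest_coupling_scale during rest
  sec_idx <- pmin(floor((seq_len(n) - 1) / fs) + 1, total_s)
  state_per_sample <- state_seq$labels[sec_idx]
  is_task <- state_seq$session[sec_idx] != "rest"
  gain <- ifelse(is_task, 1, cfg$rest_coupling_scale)
  # 1-s raised-cosine smoothing of the gate to limit spectral leakage
  smooth_gate <- function(g) {
    k <- max(1L, as.integer(fs))
    kern <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
    kern <- kern / sum(kern)
    stats::filter(c(rep(g[1], k), g, rep(g[length(g)], k)), kern,
                  sides = 2)[(k + 1):(k + length(g))]
  }

  roi_sig <- list(matrix(0, n_rois, n), matrix(0, n_rois, n))

  # Noise layers per participant. Systemic physiology (drift, Mayer waves,
  # respiration, cardiac) is a whole-head signal: one time course per layer
  # per participant, projected onto the ROIs with a smooth spatial gain
  # profile - this is the structure the PCA spatial filter is meant to
  # remove. The broadband neural background is ROI-specific.
  for (p in 1:2) {
    systemic <- rbind(drift = band_noise(n, fs, 1e-4, 0.01),
                      mayer = jittered_sine(n, fs, 0.1),
                      respiration = jittered_sine(n, fs, 0.3),
                      cardiac = jittered_sine(n, fs, 1.2))
    for (r in seq_len(n_rois))
      roi_sig[[p]][r, ] <- amp["neural"] * band_noise(n, fs, 0.01, 0.5)
    for (layer in rownames(systemic)) {
      gains <- stats::runif(n_rois, 0.6, 1.4)
      roi_sig[[p]] <- roi_sig[[p]] +
        (amp[layer] * gains) %o% systemic[layer, ]
    }
  }

  # Planted coupling. Each connected component of a state's coupling graph
  # is a synchronous module driven by one dyad-common band-limited source:
  # every member ROI of both participants receives the source scaled by a
  # loading a_r = sqrt(mean strength of r's edges), so an isolated pair at
  # strength c shares exactly variance c, and within a uniform module every
  # cross-participant pair (including homologous ones) is coherent at the
  # same level. Heterogeneous matrices are realized approximately (pair
  # synchrony follows the product of member loadings).
  band <- cfg$coupling_band
  for (s in seq_len(cfg$n_states)) {
    cs <- cfg$coupling_strength[[s]]
    env <- as.numeric(smooth_gate((state_per_sample == s) * gain))
    if (all(cs == 0) || all(env == 0)) next
    g <- igraph::graph_from_adjacency_matrix(cs > 0, mode = "undirected")
    comp <- igraph::components(g)
    for (m_i in seq_len(comp$no)) {
      members <- which(comp$membership == m_i)
      if (length(members) < 2) next
      src <- band_noise(n, fs, band[1], band[2])
      for (r in members) {
        load <- sqrt(mean(cs[r, members][cs[r, members] > 0]))
        # Regional engagement varies in gain and sign per participant
        # (coherence is invariant to the sign of the loading), so a module
        # is never a uniform global-signal-like spatial component and the
        # spatial filter removes systemic physiology, not the coupling.
        for (p in 1:2) {
          eng <- stats::runif(1, 0.7, 1.3) * sample(c(-1, 1), 1)
          roi_sig[[p]][r, ] <- roi_sig[[p]][r, ] + eng * load * env * src
        }
      }
    }
  }

  # channels: ROI signal + white channel noise + participant motion spikes
  n_ch <- n_rois * cfg$channels_per_roi
  roi_of_ch <- rep(seq_len(n_rois), each = cfg$channels_per_roi)
  ch_names <- paste0("CH", seq_len(n_ch))
  roi_map <- stats::setNames(paste0("ROI", roi_of_ch), ch_names)
  hbo <- list(); hbr <- list()
  for (p in 1:2) {
    spikes <- numeric(n)
    n_spk <- stats::rpois(1, cfg$motion_rate * total_s / 60)
    if (n_spk > 0) {
      at <- sample.int(n, n_spk)
      tau <- 0.5 * fs
      kern_len <- as.integer(5 * tau)
      kern <- exp(-(seq_len(kern_len) - 1) / tau)
      for (a in at) {
        idx <- a:min(n, a + kern_len - 1L)
        spikes[idx] <- spikes[idx] + 3.0 * sample(c(-1, 1), 1) * kern[seq_along(idx)]
      }
    }
    ho <- matrix(0, n_ch, n); hr <- matrix(0, n_ch, n)
    for (c_i in seq_len(n_ch)) {
      g <- stats::runif(1, 0.5, 1.5)
      base <- roi_sig[[p]][roi_of_ch[c_i], ] +
        amp["white"] * stats::rnorm(n)
      ho[c_i, ] <- base + g * spikes
      hr[c_i, ] <- cfg$hbr_ratio * base +
        amp["white"] * stats::rnorm(n) + g * spikes
    }
    rownames(ho) <- ch_names; rownames(hr) <- ch_names
    hbo[[p]] <- ho; hbr[[p]] <- hr
  }

  ann <- session_annotations(cfg$session_plan)
  structure(list(dyad_id = dyad_id, fs = fs, hbo = hbo, hbr = hbr,
                 roi_map = roi_map, annotations = ann,
                 truth_states = state_seq$labels,
                 n_time = n),
            class = "dyad_recording")
}

session_annotations <- function(plan) {
  ends <- cumsum(plan$duration)
  data.frame(label = plan$label, start = c(0, ends[-length(ends)]),
             end = ends, stringsAsFactors = FALSE)
}

validate_dyad_recording <- function(rec) {
  stopifnot(inherits(rec, "dyad_recording"))
  stopifnot(ncol(rec$hbo[[1]]) == ncol(rec$hbo[[2]]))
  stopifnot(all(rownames(rec$hbo[[1]]) %in% names(rec$roi_map)))
  a <- rec$annotations
  if (nrow(a) > 1 && any(abs(a$start[-1] - a$end[-nrow(a)]) > 1e-9))
    stop("annotations must tile the recording without gaps or overlap")
  invisible(rec)
}

#' Generate behavioral response logs for one dyad and task
#'
#' Emulates a turn-taking idea-generation session: the two participants
#' alternate responses; with probability `convergence_prob` a response
#' repeats the previous response's category (the basis of the index of
#' cooperation), otherwise a category is drawn uniformly. Response keys are
#' drawn without replacement within the dyad from a Zipf-weighted global
#' inventory, so cohort-level originality (rarely produced responses) is
#' meaningful; `rare_bias > 0` tilts sampling toward rare items.
#'
#' @param seed Integer seed.
#' @param task Task label stored in the log (e.g. `"AUT"` or `"OCT"`).
#' @param duration Session length in seconds.
#' @param convergence_prob Probability that a response stays in the previous
#'   response's category.
#' @param n_categories Size of the category inventory (>= 2).
#' @param items_per_category Size of each category's response inventory.
#' @param zipf_exponent Zipf exponent of item popularity within a category.
#' @param rare_bias Non-negative tilt toward rare items (0 = popularity
#'   sampling).
#' @param mean_gap Mean inter-response interval in seconds.
#' @param pass_prob Probability that a turn is a "pass" (no idea offered);
#'   passes carry no category and are skipped by the convergence count.
#' @param dyad_id Identifier stored in the log.
#' @return A `response_log` data frame: `dyad`, `task`, `speaker`, `t`,
#'   `response`, `category`.
#' @export
generate_behavior <- function(seed, task = "AUT", duration = 300,
                              convergence_prob = 0.3, n_categories = 8,
                              items_per_category = 40, zipf_exponent = 1.2,
                              rare_bias = 0, mean_gap = 8, pass_prob = 0.05,
                              dyad_id = "dyad1") {
  stopifnot(n_categories >= 2, convergence_prob >= 0, convergence_prob <= 1)
  set.seed(seed)
  # global inventory: item ranks within category give Zipf popularity
  ranks <- seq_len(items_per_category)
  pop <- ranks^(-zipf_exponent)
  w <- pop * (ranks^rare_bias)  # rare_bias > 0 lifts high-rank (rare) items
  used <- character(0)
  recs <- list()
  t_now <- 0
  speaker <- 1L
  prev_cat <- NA_character_
  repeat {
    t_now <- t_now + 2 + stats::rexp(1, 1 / mean_gap)
    if (t_now >= duration) break
    if (stats::runif(1) < pass_prob) {
      recs[[length(recs) + 1L]] <- data.frame(
        dyad = dyad_id, task = task, speaker = speaker, t = t_now,
        response = "pass", category = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      if (!is.na(prev_cat) && stats::runif(1) < convergence_prob) {
        cat_i <- prev_cat
      } else {
        cat_i <- paste0("cat", sample.int(n_categories, 1))
      }
      # sample an unused item from this category
      items <- paste0(cat_i, "_item", ranks)
      avail <- !(items %in% used)
      if (!any(avail)) next
      item <- sample(items[avail], 1, prob = w[avail])
      used <- c(used, item)
      recs[[length(recs) + 1L]] <- data.frame(
        dyad = dyad_id, task = task, speaker = speaker, t = t_now,
        response = item, category = cat_i, stringsAsFactors = FALSE)
      prev_cat <- cat_i
    }
    speaker <- 3L - speaker
  }
  log <- do.call(rbind, recs)
  class(log) <- c("response_log", class(log))
  log
}

#' Generate a synthetic cohort of dyads
#'
#' Generates `n_dyads` dyadic recordings from a shared [sim_config()], plus
#' behavioral logs whose convergence probability and originality bias
#' increase with the dyad's realized occupancy of state 1 (the densest
#' coupling state), so that brain-behavior correlations have a planted
#' positive direction when `behavior_link > 0`.
#'
#' All dyads experience the same session timeline, and part of the
#' engagement rhythm is task-locked rather than idiosyncratic (shared
#' instructions, turn-taking pace, fatigue). `state_share` models this: a
#' cohort-level master state sequence is drawn once, and each dyad keeps a
#' master dwell segment with probability `state_share` or redraws that
#' segment's state otherwise. Group-averaged window clustering presupposes
#' some cross-dyad alignment of this kind; `state_share = 0` gives fully
#' independent dyads.
#'
#' @param n_dyads Number of dyads.
#' @param cfg A [sim_config()] object.
#' @param seed Integer master seed; dyad `d` uses `seed + d` offsets.
#' @param behavior_link Strength of the planted link between state-1
#'   occupancy and behavior (0 disables it).
#' @param state_share Probability in `[0, 1]` that a dyad follows the
#'   cohort master sequence during a given dwell segment.
#' @param master Optional `state_sequence` to use as the cohort master
#'   script (e.g. [periodic_state_sequence()] for the periodic, alternating
#'   state expression seen in group communication); drawn from `cfg` when
#'   omitted.
#' @return A `cohort` list with one element per dyad: `recording`,
#'   `state_seq`, `behavior` (list of logs per task) and `members`
#'   (participant ids).
#' @export
generate_cohort <- function(n_dyads, cfg = sim_config(), seed = cfg$seed,
                            behavior_link = 2, state_share = 0.5,
                            master = NULL) {
  dyads <- vector("list", n_dyads)
  task_sessions <- cfg$session_plan[cfg$session_plan$label != "rest", ]
  if (is.null(master)) master <- generate_state_sequence(cfg, seed = seed)
  for (d in seq_len(n_dyads)) {
    sseq <- perturb_state_sequence(master, cfg, state_share,
                                   seed = seed + 17L * d)
    rec <- generate_dyad_recording(cfg, state_seq = sseq,
                                   dyad_id = paste0("dyad", d),
                                   seed = seed + 17L * d)
    task_secs <- sseq$session != "rest"
    s1_frac <- mean(sseq$labels[task_secs] == 1)
    conv_p <- max(0, min(1, 0.15 + behavior_link * s1_frac))
    rbias <- max(0, behavior_link * s1_frac)
    beh <- list()
    for (k in seq_len(nrow(task_sessions))) {
      task_lab <- if (task_sessions$label[k] == "taskA") "AUT" else "OCT"
      beh[[task_lab]] <- generate_behavior(
        seed = seed + 1000L * d + k, task = task_lab,
        duration = task_sessions$duration[k],
        convergence_prob = conv_p, rare_bias = rbias,
        dyad_id = paste0("dyad", d))
    }
    dyads[[d]] <- list(recording = rec, state_seq = sseq, behavior = beh,
                       members = c(2L * d - 1L, 2L * d))
  }
  structure(dyads, class = "cohort")
}

#' Periodic master state sequence
#'
#' A deterministic state script that cycles 1, 2, ..., n_states with a
#' fixed dwell — the periodic, alternating expression of dense and sparse
#' inter-brain states observed during group communication. Useful as the
#' `master` argument of [generate_cohort()] when a balanced, temporally
#' aligned cohort is wanted (e.g. for planted-state recovery studies).
#'
#' @param cfg A [sim_config()].
#' @param dwell Dwell time per state visit, in seconds.
#' @return A `state_sequence`.
#' @export
periodic_state_sequence <- function(cfg, dwell = 80) {
  total <- sum(cfg$session_plan$duration)
  n_segs <- ceiling(total / dwell)
  states <- rep_len(seq_len(cfg$n_states), n_segs)
  labels <- rep(states, each = dwell)[seq_len(total)]
  durs <- c(rep(dwell, n_segs - 1), total - dwell * (n_segs - 1))
  segs <- data.frame(state = states[durs > 0],
                     start = cumsum(c(0, durs))[seq_len(sum(durs > 0))],
                     dur = durs[durs > 0])
  structure(list(labels = labels, segments = segs,
                 session = rep(cfg$session_plan$label,
                               times = cfg$session_plan$duration)),
            class = "state_sequence")
}

#' Master state sequence with every state substantially expressed
#'
#' Draws [generate_state_sequence()] repeatedly until every state occupies
#' at least `min_occupancy` of the task-period seconds. A single random
#' master script can badly under-represent a state over a short session
#' (the dwell segments are few); cohorts meant for planted-state recovery
#' need a session in which all states actually occur.
#'
#' @param cfg A [sim_config()].
#' @param min_occupancy Minimum task-period occupancy per state.
#' @param max_tries Attempts before giving up with an error.
#' @param seed Integer seed (incremented per attempt).
#' @return A `state_sequence`.
#' @export
balanced_master_sequence <- function(cfg, min_occupancy = 0.2,
                                     max_tries = 100, seed = cfg$seed) {
  for (try in seq_len(max_tries)) {
    ss <- generate_state_sequence(cfg, seed = seed + 7919L * (try - 1L))
    task <- ss$session != "rest"
    occ <- vapply(seq_len(cfg$n_states), function(s)
      mean(ss$labels[task] == s), numeric(1))
    if (min(occ) >= min_occupancy) return(ss)
  }
  stop("no master sequence reached the requested per-state occupancy; ",
       "lower min_occupancy or raise state_probs")
}

# Dyad-level deviation from the cohort master sequence: each master dwell
# segment is kept with probability `share`, otherwise its state is redrawn
# from the other states (weighted by the session's occupancy targets).
perturb_state_sequence <- function(master, cfg, share, seed) {
  if (share >= 1 || cfg$n_states == 1) return(master)
  set.seed(seed)
  if (share <= 0) return(generate_state_sequence(cfg, seed = seed))
  labels <- master$labels
  segs <- master$segments
  for (r in seq_len(nrow(segs))) {
    if (stats::runif(1) < share) next
    sec_range <- (segs$start[r] + 1):(segs$start[r] + segs$dur[r])
    lab <- master$session[sec_range[1]]
    p <- session_param(cfg$state_probs, lab)
    p <- p / sum(p)
    q <- p; q[segs$state[r]] <- 0
    new_state <- sample.int(cfg$n_states, 1L, prob = q / sum(q))
    labels[sec_range] <- new_state
    segs$state[r] <- new_state
  }
  structure(list(labels = labels, segments = segs, session = master$session),
            class = "state_sequence")
}
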