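# Synthetic dyadic fNIRS generator: state sequences, recordings, cohorts.

test_that("state sequences are semi-Markov with matched occupancy", {
  cfg <- small_sim_config(seed = 2)

  # degenerate single state: constant sequence, zero transitions
  cfg1 <- small_sim_config(seed = 2, n_states = 1,
                           state_probs = list(taskA = 1),
                           coupling_strength = list(matrix(0, 4, 4)))
  ss1 <- generate_state_sequence(cfg1)
  expect_equal(unique(ss1$labels), 1L)

  # no self-transitions at dwell boundaries
  ss <- generate_state_sequence(cfg, seed = 5)
  segs <- ss$segments
  expect_true(all(diff(segs$state) != 0 | diff(segs$start) == 0))
  expect_true(all(segs$dur >= 1))
  expect_equal(sum(segs$dur), sum(cfg$session_plan$duration))

  # determinism
  expect_identical(generate_state_sequence(cfg, seed = 7)$labels,
                   generate_state_sequence(cfg, seed = 7)$labels)

  # mean segment count over seeds approximates duration / dwell mean
  cfg3 <- sim_config(sampling_rate = 5, n_rois = 2, n_states = 3,
                     session_plan = data.frame(label = "taskA", duration = 480),
                     state_dwell_mean = 30,
                     state_probs = list(taskA = rep(1, 3) / 3),
                     coupling_strength = dibs:::default_coupling_states(2, 3))
  n_segs <- vapply(1:200, function(s)
    nrow(generate_state_sequence(cfg3, seed = s)$segments), numeric(1))
  expect_gt(mean(n_segs), 16 * 0.8)
  expect_lt(mean(n_segs), 16 * 1.2)

  # long-run occupancy converges to the configured targets
  cfg_occ <- sim_config(sampling_rate = 5, n_rois = 2, n_states = 3,
                        session_plan = data.frame(label = "taskA",
                                                  duration = 2000),
                        state_dwell_mean = 20,
                        state_probs = list(taskA = c(0.1, 0.3, 0.6)),
                        coupling_strength = dibs:::default_coupling_states(2, 3))
  labs <- unlist(lapply(1:20, function(s)
    generate_state_sequence(cfg_occ, seed = s)$labels))
  occ <- as.numeric(table(factor(labs, levels = 1:3)) / length(labs))
  expect_lt(max(abs(occ - c(0.1, 0.3, 0.6))), 0.05)

  expect_error(generate_state_sequence(
    small_sim_config(seed = 1, state_dwell_mean = 2)), "dwell")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sampling_rate = 2), "cardiac")
  expect_error(sim_config(coupling_band = c(0.005, 0.2)), "coupling_band")
  expect_error(sim_config(coupling_band = c(0.1, 0.8)), "coupling_band")
  bad <- dibs:::default_coupling_states(4, 3)
  bad[[1]][1, 2] <- 0.5; bad[[1]][2, 1] <- 0.1
  expect_error(sim_config(n_rois = 4, coupling_strength = bad), "symmetric")
  bad2 <- dibs:::default_coupling_states(4, 3)
  diag(bad2[[2]]) <- 0.3
  expect_error(sim_config(n_rois = 4, coupling_strength = bad2), "diagonal")
})

test_that("recordings have the configured shape and anti-correlated HbR", {
  cfg <- small_sim_config(seed = 3)
  rec <- generate_dyad_recording(cfg)
  n <- sum(cfg$session_plan$duration) * cfg$sampling_rate
  expect_equal(dim(rec$hbo[[1]]), c(4, n))
  expect_equal(dim(rec$hbr[[2]]), c(4, n))
  expect_equal(length(rec$truth_states), sum(cfg$session_plan$duration))
  expect_equal(unname(rec$roi_map), paste0("ROI", 1:4))

  # noise-free construction: corr(HbO, HbR) = hbr_ratio exactly -1 after
  # scaling, i.e. perfectly anti-correlated
  cfg0 <- small_sim_config(
    seed = 4,
    noise_amplitudes = c(neural = 0, drift = 0, mayer = 0, respiration = 0,
                         cardiac = 0, white = 0),
    motion_rate = 0)
  rec0 <- generate_dyad_recording(cfg0)
  for (ch in 1:2)
    expect_equal(cor(rec0$hbo[[1]][ch, ], rec0$hbr[[1]][ch, ]), -1,
                 tolerance = 1e-12)

  # determinism
  r1 <- generate_dyad_recording(cfg, seed = 11)
  r2 <- generate_dyad_recording(cfg, seed = 11)
  expect_identical(r1$hbo, r2$hbo)
})

test_that("generated HbO spectra peak at the configured physiological bands", {
  cfg <- sim_config(
    sampling_rate = 10, n_rois = 2,
    session_plan = data.frame(label = "taskA", duration = 200),
    coupling_strength = dibs:::default_coupling_states(2, 3),
    noise_amplitudes = c(neural = 0.2, drift = 0.5, mayer = 1,
                         respiration = 1, cardiac = 1, white = 0.1),
    seed = 5)
  rec <- generate_dyad_recording(cfg)
  x <- rec$hbo[[1]][1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 10), spans = 9,
                          plot = FALSE, detrend = TRUE)
  band_power <- function(f_lo, f_hi) mean(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi])
  ref <- band_power(0.5, 0.7)       # quiet band between respiration and cardiac
  expect_gt(band_power(0.08, 0.12), ref)    # Mayer
  expect_gt(band_power(0.25, 0.35), ref)    # respiration
  expect_gt(band_power(1.0, 1.4), ref)      # cardiac
})

test_that("planted coupling elevates in-band task coherence for the coupled pair", {
  # one isolated strongly coupled pair; compare its in-band task coherence
  # against out-of-band, across a few seeds
  cs <- list(matrix(0, 4, 4))
  cs[[1]][1, 2] <- cs[[1]][2, 1] <- 0.9
  cfg <- sim_config(
    sampling_rate = 5, n_rois = 4, n_states = 1,
    session_plan = data.frame(label = c("rest", "taskA"),
                              duration = c(60, 240)),
    state_probs = list(taskA = 1), coupling_strength = cs,
    rest_coupling_scale = 0, seed = 1)
  spec <- small_wavelet_spec()
  wins <- vapply(1:5, function(s) {
    ss <- generate_state_sequence(cfg, seed = s)
    rec <- generate_dyad_recording(cfg, ss, seed = s)
    roi <- channels_to_roi(rec)
    task <- seq(60 * 5 + 1, 300 * 5)
    co <- wavelet_coherence(roi[[1]][1, task], roi[[2]][2, task], 5, spec)
    inb <- co$freqs >= 0.10 & co$freqs <= 0.19
    mean(co$R2[inb, ]) - mean(co$R2[!inb, ])
  }, numeric(1))
  expect_gt(mean(wins), 0.1)
  expect_true(all(wins > 0))
})

test_that("cohorts share a partly common state script and link behavior to state 1", {
  cfg <- small_sim_config(seed = 9)
  coh <- generate_cohort(4, cfg, seed = 9, state_share = 1)
  # full sharing: all dyads follow the master sequence exactly
  expect_identical(coh[[1]]$state_seq$labels, coh[[2]]$state_seq$labels)
  coh0 <- generate_cohort(4, cfg, seed = 9, state_share = 0)
  expect_false(identical(coh0[[1]]$state_seq$labels,
                         coh0[[2]]$state_seq$labels))
  # behavior logs exist per task with alternating speakers
  expect_named(coh[[1]]$behavior, c("AUT", "OCT"))
  expect_equal(sort(unique(coh[[1]]$behavior$AUT$speaker)), c(1, 2))
  # determinism of the whole cohort
  coh2 <- generate_cohort(4, cfg, seed = 9, state_share = 1)
  expect_identical(coh[[1]]$recording$hbo, coh2[[1]]$recording$hbo)
  expect_identical(coh[[1]]$behavior, coh2[[1]]$behavior)
})
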