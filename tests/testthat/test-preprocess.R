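# Spatial filter, CBSI motion correction, session trimming.

mk_rec <- function(hbo1, hbr1 = -0.5 * hbo1, hbo2 = hbo1, hbr2 = hbr1,
                   fs = 5, plan = data.frame(label = "taskA",
                                             duration = ncol(hbo1) / fs)) {
  ch <- paste0("CH", seq_len(nrow(hbo1)))
  rownames(hbo1) <- rownames(hbr1) <- rownames(hbo2) <- rownames(hbr2) <- ch
  structure(list(dyad_id = "t", fs = fs,
                 hbo = list(hbo1, hbo2), hbr = list(hbr1, hbr2),
                 roi_map = stats::setNames(paste0("ROI", seq_along(ch)), ch),
                 annotations = dibs:::session_annotations(plan),
                 truth_states = NULL, n_time = ncol(hbo1)),
            class = "dyad_recording")
}

test_that("PCA filter removes a pure global signal and is the identity at n = 0", {
  set.seed(1)
  g <- rnorm(400)
  X <- rbind(g, g, g, g) * c(1, 2, 0.5, 1.5)  # rank-1 across channels
  rec <- mk_rec(X)
  out <- pca_spatial_filter(rec, 1)
  expect_lt(max(abs(out$hbo[[1]] - rowMeans(out$hbo[[1]]))), 1e-9)

  out0 <- pca_spatial_filter(rec, 0)
  expect_identical(out0$hbo[[1]], rec$hbo[[1]])
})

test_that("PCA filter preserves channel-unique components", {
  # Unique components are balanced across channels (orthogonal to the
  # uniform global direction), so removing the global component must leave
  # them intact: each channel keeps its own oscillation.
  n <- 1000; t <- seq_len(n) / 5
  g <- sin(2 * pi * 0.05 * t) * 3            # strong global sinusoid
  s1 <- sin(2 * pi * 0.31 * t); s2 <- sin(2 * pi * 0.17 * t)
  uniq <- rbind(s1, -s1, s2, -s2)
  X <- sweep(uniq, 2, -g)                     # g added to every channel
  rec <- mk_rec(X)
  out <- pca_spatial_filter(rec, 1)
  for (ch in 1:4)
    expect_gt(cor(out$hbo[[1]][ch, ], uniq[ch, ]), 0.99)
  # variance never increases
  expect_true(all(apply(out$hbo[[1]], 1, var) <= apply(X, 1, var) + 1e-12))
  # with unbalanced uniques the filter mixes in -1/nch of the channel mean,
  # bounding the attainable correlation at sqrt(1 - 1/nch)
  uniq2 <- rbind(sin(2 * pi * 0.31 * t), sin(2 * pi * 0.17 * t),
                 sin(2 * pi * 0.23 * t), sin(2 * pi * 0.11 * t))
  out2 <- pca_spatial_filter(mk_rec(sweep(uniq2, 2, -g)), 1)
  for (ch in 1:4)
    expect_gt(cor(out2$hbo[[1]][ch, ], uniq2[ch, ]), 0.8)
})

test_that("constant channels are passed through with a warning", {
  set.seed(3)
  X <- rbind(rnorm(200), rnorm(200), rep(1, 200))
  rec <- mk_rec(X)
  # the filter warns once per participant and chromophore
  w <- capture_warnings(out <- pca_spatial_filter(rec, 1))
  expect_true(all(grepl("constant", w)))
  expect_length(w, 4)
  expect_equal(out$hbo[[1]][3, ], rep(1, 200), ignore_attr = TRUE)
})

test_that("CBSI follows the closed form and enforces exact anti-correlation", {
  set.seed(4)
  x <- rnorm(300)
  # hbr = -hbo: alpha = 1 and the signal is returned unchanged
  res <- cbsi_correct(x, -x)
  expect_equal(res$alpha, 1)
  expect_equal(res$hbo, x)
  expect_equal(res$hbr, -x)

  # generic input: corr(hbo', hbr') = -1 exactly
  y <- -0.5 * x + rnorm(300, sd = 0.3)
  res2 <- cbsi_correct(x, y)
  expect_equal(cor(res2$hbo, res2$hbr), -1)
  expect_equal(res2$alpha, sd(x) / sd(y))

  # a shared positive spike (motion) is attenuated in corrected HbO
  base <- rnorm(300); spike <- numeric(300); spike[150:155] <- 6
  res3 <- cbsi_correct(base + spike, -0.5 * base + spike)
  expect_lt(max(res3$hbo[150:155]), max((base + spike)[150:155]) / 2)

  expect_error(cbsi_correct(x, rep(0, 300)), "zero-variance")
})

test_that("trimming removes task edges and keeps rest whole", {
  fs <- 5
  plan <- data.frame(label = c("rest", "taskA", "taskB", "rest"),
                     duration = c(60, 300, 300, 30))
  n <- sum(plan$duration) * fs
  rec <- mk_rec(matrix(rnorm(2 * n), 2, n), fs = fs, plan = plan)
  out <- trim_sessions(rec, preprocess_config(trim_head = 30, trim_tail = 30))
  ann <- out$annotations
  task_dur <- sum(ann$end[ann$label != "rest"] - ann$start[ann$label != "rest"])
  expect_equal(task_dur, 480)                       # 2 x (300 - 60)
  rest_dur <- sum(ann$end[ann$label == "rest"] - ann$start[ann$label == "rest"])
  expect_equal(rest_dur, 90)
  expect_equal(ncol(out$hbo[[1]]), (480 + 90) * fs)

  # zero trims: identity on durations
  out0 <- trim_sessions(rec, preprocess_config(trim_head = 0, trim_tail = 0))
  expect_equal(ncol(out0$hbo[[1]]), n)

  # one 100-s session with 30/30 trims retains 40 s
  plan2 <- data.frame(label = "taskA", duration = 100)
  rec2 <- mk_rec(matrix(rnorm(2 * 100 * fs), 2), fs = fs, plan = plan2)
  out2 <- trim_sessions(rec2, preprocess_config())
  expect_equal(ncol(out2$hbo[[1]]), 40 * fs)

  # sessions shorter than their trims are rejected
  plan3 <- data.frame(label = "taskA", duration = 50)
  rec3 <- mk_rec(matrix(rnorm(2 * 50 * fs), 2), fs = fs, plan = plan3)
  expect_error(trim_sessions(rec3, preprocess_config()), "shorter")
})

test_that("the preprocessing chain is pure and order-logged", {
  cfg <- small_sim_config(seed = 6)
  rec <- generate_dyad_recording(cfg, seed = 6)
  a <- preprocess_recording(rec, small_preprocess_config())
  b <- preprocess_recording(rec, small_preprocess_config())
  expect_identical(a$hbo, b$hbo)
  expect_equal(a$preprocess$order,
               c("pca_spatial_filter", "cbsi", "trim_mask"))
  # the series stays continuous (no splicing); trims travel as masks
  expect_equal(ncol(a$hbo[[1]]), ncol(rec$hbo[[1]]))
  expect_equal(a$trim, list(head = 10, tail = 10))
})
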