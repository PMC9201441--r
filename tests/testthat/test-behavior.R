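# Behavioral scoring: fluency, originality, flexibility, IOC, inter-rater
# consistency.

mk_log <- function(categories, responses = NULL, speakers = NULL,
                   dyad = "dyad1", task = "AUT") {
  n <- length(categories)
  if (is.null(responses))
    responses <- if (n > 0) paste0("resp", seq_len(n)) else character(0)
  if (is.null(speakers)) speakers <- rep_len(c(1, 2), n)
  data.frame(dyad = rep(dyad, n), task = rep(task, n), speaker = speakers,
             t = seq_len(n) * 10, response = responses,
             category = categories, stringsAsFactors = FALSE)
}

test_that("fluency counts non-redundant responses and sums over members", {
  log <- mk_log(rep("a", 5))
  fl <- score_fluency(log)
  expect_equal(as.numeric(fl), c(3, 2))
  expect_equal(attr(fl, "dyad"), 5)

  dup <- mk_log(rep("a", 3), responses = c("cup", "cup", "bowl"),
                speakers = c(1, 1, 1))
  expect_equal(unname(score_fluency(dup)["1"]), 2)

  # normalization: case and whitespace collapse
  norm <- mk_log(rep("a", 2), responses = c("Paper  Weight", "paper weight"),
                 speakers = c(1, 1))
  expect_equal(unname(score_fluency(norm)["1"]), 1)

  # passes do not count
  pss <- mk_log(c("a", NA, "b"), responses = c("cup", "pass", "bowl"),
                speakers = c(1, 2, 1))
  expect_equal(attr(score_fluency(pss), "dyad"), 2)
})

test_that("originality scores responses produced by at most 5% of the cohort", {
  # 54 participants = 27 dyads; one response produced by 1 participant
  # (1.9% -> scores) and one by 3 participants (5.6% -> does not)
  logs <- lapply(1:27, function(d) {
    resp <- c("common thing", if (d == 1) "unicorn holder" else "filler",
              if (d <= 2) "semi rare" else "filler2")
    mk_log(rep("a", 3), responses = resp, speakers = c(1, 2, 1),
           dyad = paste0("dyad", d))
  })
  # "semi rare" appears for speaker-1 participants of dyads 1-2 plus one
  # more to reach 3 producers
  logs[[3]]$response[1] <- "semi rare"
  orig <- score_originality(logs)
  # the unique response scores for dyad1 speaker 2
  expect_equal(orig$originality[orig$dyad == "dyad1" & orig$speaker == 2], 1)
  # "common thing" (27/54 participants) scores for nobody; "semi rare"
  # (3/54 = 5.6%) scores for nobody either
  expect_true(all(orig$originality[orig$dyad == "dyad2"] == 0))
  # 1/54 = 1.9% <= 5%; 3/54 = 5.6% > 5%
  expect_lt(1 / 54, 0.05)
  expect_gt(3 / 54, 0.05)
})

test_that("flexibility is categories over fluency", {
  expect_equal(score_flexibility(mk_log(c("a", "b", "c", "d"))), 1.0)
  expect_equal(score_flexibility(mk_log(c("a", "a", "b", "b"))), 0.5)
  expect_equal(score_flexibility(mk_log(rep(c("a", "b", "c"),
                                            length.out = 10))), 0.3)
  empty <- mk_log(character(0))
  expect_warning(fx <- score_flexibility(empty), "fluency")
  expect_true(is.na(fx))
})

test_that("IOC counts category convergence on the merged chronological log", {
  log <- mk_log(c("A", "A", "B", "B", "C"))
  res <- compute_ioc(log)
  expect_equal(res$converge, 2L)
  expect_equal(res$ioc, 2 / 3)

  none <- mk_log(c("A", "B", "A", "B"))
  expect_equal(compute_ioc(none)$ioc, 0)

  all_same <- mk_log(c("A", "A", "A", "A"))
  res2 <- compute_ioc(all_same)
  expect_equal(res2$converge, 3L)
  expect_equal(res2$ioc, 3)

  # pass turns are skipped; the previous substantive category remains
  with_pass <- mk_log(c("A", NA, "A", "B"),
                      responses = c("cup", "pass", "bowl", "hat"))
  expect_equal(compute_ioc(with_pass)$converge, 1L)

  # converge equal to fluency is impossible to score
  one <- mk_log("A", responses = "cup")
  dup_all <- rbind(one, one)  # duplicate key: fluency 1, converge 1
  expect_error(compute_ioc(dup_all), "IOC undefined")
})

test_that("IOC is invariant to bijective category relabeling", {
  set.seed(3)
  cats <- sample(LETTERS[1:4], 30, replace = TRUE)
  log1 <- mk_log(cats)
  relab <- c(A = "w", B = "x", C = "y", D = "z")
  log2 <- log1
  log2$category <- unname(relab[log1$category])
  expect_equal(compute_ioc(log1), compute_ioc(log2))
})

test_that("two-rater Cronbach's alpha matches the textbook formula and limits", {
  r1 <- c(3, 5, 2, 4)
  expect_equal(interrater_icc(r1, r1)$alpha, 1)

  # hand-computed 4-subject example
  r2 <- c(2, 5, 3, 5)
  v1 <- var(r1); v2 <- var(r2); vt <- var(r1 + r2)
  expect_equal(interrater_icc(r1, r2)$alpha, 2 * (1 - (v1 + v2) / vt))
  expect_equal(interrater_icc(r1, r2)$mean_ratings, (r1 + r2) / 2)

  # independent raters: alpha near zero
  set.seed(11)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(interrater_icc(a, b)$alpha), 0.2)

  expect_warning(res <- interrater_icc(rep(1, 5), rep(1, 5)), "variance")
  expect_true(is.na(res$alpha))
})

test_that("generated logs respect forced convergence settings", {
  # convergence probability 0: no response repeats the previous category
  # is not guaranteed (uniform draws may coincide), but probability 1
  # forces every response after the first into the previous category
  log1 <- generate_behavior(seed = 5, convergence_prob = 1, pass_prob = 0,
                            duration = 120)
  res <- compute_ioc(log1)
  n <- nrow(log1)
  expect_equal(res$converge, n - 1L)
  expect_equal(res$ioc, (n - 1) / (n - (n - 1)))

  # determinism
  log_a <- generate_behavior(seed = 9, convergence_prob = 0.4)
  log_b <- generate_behavior(seed = 9, convergence_prob = 0.4)
  expect_identical(log_a, log_b)

  # alternating speakers
  expect_true(all(abs(diff(log_a$speaker)) == 1))
})

test_that("estimated convergence rises monotonically with the configured probability", {
  probs <- seq(0.05, 0.95, by = 0.15)
  est <- vapply(probs, function(p) {
    vals <- vapply(1:8, function(s) {
      lg <- generate_behavior(seed = 100 * s, convergence_prob = p,
                              pass_prob = 0, duration = 300)
      ioc <- compute_ioc(lg)
      ioc$converge / (nrow(lg) - 1)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gt(cor(probs, est, method = "spearman"), 0.9)
})
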