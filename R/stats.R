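# Inferential layer: one-way repeated-measures ANOVA with partial eta
# squared and Bonferroni post-hocs, Pearson brain-behavior correlations,
# and the pseudo-dyad permutation validation.

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition of a complete subjects x
#' conditions table: `SS_total = SS_conditions + SS_subjects + SS_error`,
#' `F = MS_conditions / MS_error` with df `(c - 1, (c - 1)(s - 1))`, and
#' partial eta squared `SS_conditions / (SS_conditions + SS_error)`.
#' Post-hoc pairwise comparisons are paired t-tests with Bonferroni
#' correction (p multiplied by the number of pairs, capped at 1).
#' Sphericity is not corrected in the reported test; the Greenhouse-Geisser
#' epsilon is computed and returned for transparency.
#'
#' @param Y Numeric matrix, subjects x conditions (complete; no missing
#'   cells).
#' @return An `rm_anova` list: `F`, `df`, `p`, `partial_eta2`, `means`,
#'   `ss` (the decomposition), `posthoc` (data frame), `gg_epsilon`.
#' @export
rm_anova_oneway <- function(Y) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("missing cells: repeated-measures ANOVA needs complete data")
  s <- nrow(Y); k <- ncol(Y)
  if (k < 2 || s < 3) stop("need >= 2 conditions and >= 3 subjects")
  gm <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- s * sum((cond_means - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1
  df_err <- (k - 1) * (s - 1)
  tol <- 1e-12 * max(1, ss_tot)
  if (ss_err <= tol) {            # degenerate: no residual variability
    Fval <- if (ss_cond <= tol) 0 else Inf
    p <- if (ss_cond <= tol) 1 else 0
    eta2 <- if (ss_cond <= tol) 0 else 1
  } else {
    Fval <- (ss_cond / df_cond) / (ss_err / df_err)
    p <- stats::pf(Fval, df_cond, df_err, lower.tail = FALSE)
    eta2 <- ss_cond / (ss_cond + ss_err)
  }
  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(Y)
  J <- diag(k) - matrix(1 / k, k, k)
  D <- J %*% S %*% J
  gg <- sum(diag(D))^2 / (df_cond * sum(D^2))
  pairs <- utils::combn(k, 2)
  posthoc <- data.frame(a = pairs[1, ], b = pairs[2, ])
  posthoc$t <- NA_real_; posthoc$p_bonf <- NA_real_
  for (r in seq_len(ncol(pairs))) {
    tt <- stats::t.test(Y[, pairs[1, r]], Y[, pairs[2, r]], paired = TRUE)
    posthoc$t[r] <- unname(tt$statistic)
    posthoc$p_bonf[r] <- min(1, tt$p.value * ncol(pairs))
  }
  structure(list(F = Fval, df = c(df_cond, df_err), p = p,
                 partial_eta2 = eta2, means = cond_means,
                 ss = c(conditions = ss_cond, subjects = ss_subj,
                        error = ss_err, total = ss_tot),
                 posthoc = posthoc, gg_epsilon = gg,
                 n_subjects = s), class = "rm_anova")
}

#' Pearson correlation between a state property and behavior
#'
#' @param x,y Paired numeric vectors (n >= 4), e.g. per-dyad state-1
#'   occurrence and per-dyad originality.
#' @return List: `r`, `p` (two-sided), `n`.
#' @export
brain_behavior_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need n >= 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Sample a perfect matching of participants that contains no real dyad.
sample_pseudo_pairing <- function(n_dyads, max_tries = 1000) {
  ids <- seq_len(2 * n_dyads)
  real_dyad <- (ids + 1) %/% 2
  for (try in seq_len(max_tries)) {
    perm <- sample(ids)
    a <- perm[seq(1, length(perm), by = 2)]
    b <- perm[seq(2, length(perm), by = 2)]
    if (all(real_dyad[a] != real_dyad[b]))
      return(cbind(a, b))
  }
  stop("could not sample a pseudo pairing avoiding real dyads")
}

#' Pseudo-dyad permutation validation
#'
#' Re-pairs the cohort's participants into sham dyads (never reproducing a
#' real pairing), recomputes windowed inter-brain synchrony for every
#' pseudo-dyad from cached per-participant wavelet transforms, re-clusters
#' at the real analysis's k using the real frequency band of interest, and
#' re-runs the three headline tests: repeated-measures ANOVA on
#' state-centroid global efficiency, RM-ANOVA on state occurrence, and
#' Pearson correlations between state occurrence and dyad originality (sum
#' of the two members). A permutation counts as non-significant when the
#' omnibus p (or all correlation p's) is at least `alpha`.
#'
#' @param cohort A `cohort` of real dyads (>= 2, so sham pairings exist).
#' @param foi The real cohort's [select_foi()] band (reused per
#'   permutation).
#' @param k The real cohort's selected state count.
#' @param n_perm Number of permutations (default 300).
#' @param seed Integer seed.
#' @param spec [wavelet_spec()] used for the coherence computation.
#' @param preprocess [preprocess_config()] applied to each recording.
#' @param window_length,step Sliding-window parameters (s).
#' @param originality Optional per-participant originality table (`dyad`,
#'   `speaker`, `originality`); computed from the cohort's AUT logs when
#'   omitted.
#' @param n_replicates Random restarts for the per-permutation group
#'   clustering (kept modest: each permutation is one draw of a null).
#' @param alpha Significance level defining "no significant difference".
#' @return A `permutation_report`: per-permutation data frame (`perm`,
#'   `test`, `p`, `significant`) and the proportion of non-significant
#'   permutations per test.
#' @export
pseudogroup_permutation <- function(cohort, foi, k, n_perm = 300, seed = 1L,
                                    spec = wavelet_spec(),
                                    preprocess = preprocess_config(),
                                    window_length = 10, step = 1,
                                    originality = NULL,
                                    n_replicates = 50, alpha = 0.05) {
  n_dyads <- length(cohort)
  if (n_dyads < 2) stop("cohort too small: no sham pairing avoids real dyads")
  # participant-level caches from the preprocessed real recordings
  caches <- vector("list", 2 * n_dyads)
  ann <- NULL; fs <- NULL; trim <- NULL
  for (d in seq_len(n_dyads)) {
    rec <- preprocess_recording(cohort[[d]]$recording, preprocess)
    roi <- channels_to_roi(rec, "hbo")
    caches[[2 * d - 1]] <- participant_cwt_cache(roi[[1]], rec$fs, spec)
    caches[[2 * d]] <- participant_cwt_cache(roi[[2]], rec$fs, spec)
    if (is.null(ann)) { ann <- rec$annotations; fs <- rec$fs; trim <- rec$trim }
  }
  if (is.null(originality) && !is.null(cohort[[1]]$behavior$AUT)) {
    originality <- score_originality(lapply(cohort, function(d) d$behavior$AUT))
  }
  participant_orig <- rep(NA_real_, 2 * n_dyads)
  if (!is.null(originality)) {
    for (d in seq_len(n_dyads)) {
      did <- cohort[[d]]$recording$dyad_id
      for (member in 1:2) {
        sel <- originality$dyad == did & originality$speaker == member
        if (any(sel))
          participant_orig[2 * d - 2 + member] <- originality$originality[sel][1]
      }
    }
  }

  set.seed(seed)
  rows <- list()
  for (perm in seq_len(n_perm)) {
    pairing <- sample_pseudo_pairing(n_dyads)
    series <- vector("list", n_dyads)
    for (pd in seq_len(n_dyads)) {
      stub <- structure(list(dyad_id = paste0("pseudo", pd), fs = fs,
                             annotations = ann, trim = trim),
                        class = "dyad_recording")
      dib <- dyad_ibs(stub, spec = spec, window_length = window_length,
                      step = step,
                      caches = list(caches[[pairing[pd, 1]]],
                                    caches[[pairing[pd, 2]]]))
      series[[pd]] <- window_ibs(dib, foi)
    }
    part <- cluster_group_then_dyads(series, k = k,
                                     n_replicates = n_replicates,
                                     seed = seed + perm)
    met <- state_metrics(part)
    # globE per dyad per state (state centroids are task-independent)
    ge_mat <- occ_mat <- matrix(0, n_dyads, k)
    for (d in seq_len(n_dyads)) {
      sel <- met[met$dyad == paste0("dyad", d), ]
      ge_mat[d, ] <- vapply(seq_len(k), function(s)
        sel$globE[sel$state == s][1], numeric(1))
      occ_mat[d, ] <- vapply(seq_len(k), function(s)
        mean(part$labels[[d]] == s), numeric(1))
    }
    p_ge <- tryCatch(rm_anova_oneway(ge_mat)$p, error = function(e) NA_real_)
    p_occ <- tryCatch(rm_anova_oneway(occ_mat)$p, error = function(e) NA_real_)
    p_cor <- NA_real_
    if (!is.null(originality) && !anyNA(participant_orig)) {
      pseudo_orig <- participant_orig[pairing[, 1]] +
        participant_orig[pairing[, 2]]
      p_cor <- min(vapply(seq_len(k), function(s) {
        tryCatch(brain_behavior_correlation(occ_mat[, s], pseudo_orig)$p,
                 error = function(e) 1)
      }, numeric(1)))
    }
    rows[[perm]] <- data.frame(
      perm = perm, test = c("globE_anova", "occurrence_anova",
                            "originality_correlation"),
      p = c(p_ge, p_occ, p_cor))
  }
  tab <- do.call(rbind, rows)
  tab$significant <- !is.na(tab$p) & tab$p < alpha
  prop <- stats::aggregate(significant ~ test, data = tab,
                           FUN = function(x) mean(!x))
  names(prop)[2] <- "prop_nonsignificant"
  structure(list(table = tab, prop_nonsignificant = prop, n_perm = n_perm,
                 alpha = alpha, k = k), class = "permutation_report")
}
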