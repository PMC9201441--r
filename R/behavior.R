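# Communication-performance scoring: fluency, originality, flexibility,
# inter-rater consistency, and the index of cooperation (IOC).

normalize_response <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

is_pass <- function(log) normalize_response(log$response) == "pass"

#' Fluency: number of non-redundant responses per participant
#'
#' Response keys are normalized (case, whitespace); duplicates by the same
#' participant count once; "pass" turns do not count.
#'
#' @param log A `response_log` data frame for one dyad and task.
#' @return Named numeric vector of per-speaker fluency (speakers `1`, `2`),
#'   with attribute `dyad` holding the member sum.
#' @export
score_fluency <- function(log) {
  out <- c(`1` = 0, `2` = 0)
  if (!is.null(log) && nrow(log) > 0) {
    sub <- log[!is_pass(log), , drop = FALSE]
    for (s in c(1, 2)) {
      keys <- normalize_response(sub$response[sub$speaker == s])
      out[as.character(s)] <- length(unique(keys))
    }
  }
  attr(out, "dyad") <- sum(out)
  out
}

#' Originality: statistically infrequent responses across the cohort
#'
#' A response scores one point when the fraction of cohort participants who
#' produced it is at most `threshold` (default 5%); a participant's score
#' is the number of their distinct responses that qualify.
#'
#' @param cohort_logs List of `response_log` data frames (one per dyad for
#'   the same task); participants are identified by dyad and speaker.
#' @param threshold Participant-fraction cutoff for infrequency.
#' @return Data frame: `dyad`, `speaker`, `originality`.
#' @export
score_originality <- function(cohort_logs, threshold = 0.05) {
  recs <- list()
  for (lg in cohort_logs) {
    sub <- lg[!is_pass(lg), , drop = FALSE]
    recs[[length(recs) + 1L]] <- data.frame(
      participant = paste0(sub$dyad, "_s", sub$speaker),
      dyad = sub$dyad, speaker = sub$speaker,
      key = normalize_response(sub$response), stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  recs <- unique(recs)                       # one key per participant
  n_participants <- length(unique(recs$participant))
  if (n_participants < 2) stop("originality needs a cohort of >= 2 participants")
  producers <- table(recs$key)               # participants producing each key
  infrequent <- names(producers)[producers / n_participants <= threshold]
  recs$point <- as.integer(recs$key %in% infrequent)
  agg <- stats::aggregate(point ~ dyad + speaker, data = recs, FUN = sum)
  names(agg)[names(agg) == "point"] <- "originality"
  agg[order(agg$dyad, agg$speaker), ]
}

#' Flexibility: distinct categories divided by fluency
#'
#' @param log A `response_log` for one participant or dyad.
#' @return Ratio in (0, 1]; `NA` with a warning when fluency is zero.
#' @export
score_flexibility <- function(log) {
  sub <- log[!is_pass(log), , drop = FALSE]
  keys <- unique(normalize_response(sub$response))
  fl <- length(keys)
  if (fl == 0) {
    warning("zero fluency: flexibility undefined")
    return(NA_real_)
  }
  cats <- unique(sub$category[match(keys, normalize_response(sub$response))])
  length(cats) / fl
}

#' Index of cooperation (IOC)
#'
#' On the merged chronological dyad log, a response "converges" when its
#' category equals the category of the immediately preceding substantive
#' response ("pass" turns are skipped and do not reset the comparator).
#' `IOC = converge / (group fluency - converge)`.
#'
#' @param log Merged chronological `response_log` for one dyad and task.
#' @return List: `converge` (count) and `ioc`.
#' @export
compute_ioc <- function(log) {
  sub <- log[!is_pass(log), , drop = FALSE]
  sub <- sub[order(sub$t), , drop = FALSE]
  cats <- sub$category
  converge <- if (length(cats) > 1) sum(cats[-1] == cats[-length(cats)]) else 0L
  fl <- attr(score_fluency(log), "dyad")
  if (fl <= converge)
    stop("group fluency (", fl, ") does not exceed converge (", converge,
         "): IOC undefined")
  list(converge = as.integer(converge), ioc = converge / (fl - converge))
}

#' Inter-rater consistency (Cronbach's alpha for two raters)
#'
#' `alpha = 2 * (1 - (var(r1) + var(r2)) / var(r1 + r2))`, the two-item
#' internal consistency coefficient; ratings are averaged afterward for
#' analysis.
#'
#' @param rater1,rater2 Equal-length numeric score vectors (>= 3 subjects).
#' @return List: `alpha` and `mean_ratings` (per-subject average).
#' @export
interrater_icc <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2), length(rater1) >= 3)
  v_tot <- stats::var(rater1 + rater2)
  if (v_tot == 0) {
    warning("zero total variance: alpha undefined")
    return(list(alpha = NA_real_, mean_ratings = (rater1 + rater2) / 2))
  }
  alpha <- 2 * (1 - (stats::var(rater1) + stats::var(rater2)) / v_tot)
  list(alpha = alpha, mean_ratings = (rater1 + rater2) / 2)
}

#' Score a cohort's behavior logs
#'
#' Per-dyad fluency (member sum), flexibility, converge and IOC for each
#' task, plus cohort-wide originality (summed over members per dyad, AUT
#' only by convention: the control task is scored by fluency).
#'
#' @param cohort A `cohort` from [generate_cohort()], or a list of per-dyad
#'   lists with a `behavior` element.
#' @return Data frame with one row per dyad: fluency/flexibility/IOC per
#'   task and dyad originality.
#' @export
score_cohort_behavior <- function(cohort) {
  tasks <- names(cohort[[1]]$behavior)
  nd <- length(cohort)
  rows <- list()
  orig <- NULL
  if ("AUT" %in% tasks) {
    aut_logs <- lapply(cohort, function(d) d$behavior$AUT)
    orig <- score_originality(aut_logs)
  }
  for (d in seq_len(nd)) {
    row <- list(dyad = cohort[[d]]$recording$dyad_id)
    for (tk in tasks) {
      lg <- cohort[[d]]$behavior[[tk]]
      fl <- score_fluency(lg)
      ioc <- compute_ioc(lg)
      row[[paste0("fluency_", tk)]] <- attr(fl, "dyad")
      row[[paste0("flexibility_", tk)]] <- score_flexibility(lg)
      row[[paste0("converge_", tk)]] <- ioc$converge
      row[[paste0("ioc_", tk)]] <- ioc$ioc
    }
    if (!is.null(orig)) {
      sel <- orig[orig$dyad == cohort[[d]]$recording$dyad_id, ]
      row$originality <- sum(sel$originality)
    }
    rows[[d]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
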