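#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' ranked above a random negative, with ties counted one half. Invariant
#' under any strictly monotone transform of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels in \{-1, +1\}; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  check_pm1(labels)
  npos <- as.numeric(sum(labels == 1)); nneg <- as.numeric(sum(labels == -1))
  if (npos == 0 || nneg == 0) stop("both classes are required to compute AUC")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Score of each embryo at a cutoff time
#'
#' For each embryo, the score of its latest frame at or before `t`; if the
#' embryo has no frame that early, its earliest available score is carried
#' back.
#'
#' @param score_table `data.frame` with `embryo_id`, `t_hours`, `score`.
#' @param t cutoff time in hours.
#' @return named numeric vector (names = embryo ids).
#' @export
score_at_time <- function(score_table, t) {
  parts <- split(score_table, score_table$embryo_id)
  vapply(parts, function(d) {
    d <- d[order(d$t_hours), , drop = FALSE]
    k <- findInterval(t, d$t_hours)
    d$score[max(k, 1L)]
  }, numeric(1))
}

#' AUC as a function of time since fertilization
#'
#' @param score_table per-frame scores (`embryo_id`, `t_hours`, `score`).
#' @param labels named per-embryo labels in \{-1, +1\}.
#' @param grid nonempty vector of evaluation times (hours).
#' @return `data.frame` with `t_hours` and `auc`.
#' @export
auc_over_time <- function(score_table, labels, grid) {
  if (length(grid) == 0) stop("empty evaluation grid")
  res <- vapply(grid, function(t) {
    s <- score_at_time(score_table, t)
    auc(unname(s), unname(labels[names(s)]))
  }, numeric(1))
  data.frame(t_hours = grid, auc = res)
}

#' AUC by oocyte-age bin
#'
#' Computes the AUC within each age bin; bins lacking one of the classes
#' are flagged (`ok = FALSE`, `auc = NA`) rather than silently dropped.
#'
#' @param scores numeric embryo scores.
#' @param labels labels in \{-1, +1\}.
#' @param ages oocyte ages (years), same length.
#' @param bin_edges increasing vector of bin edges (left-closed bins; the
#'   last bin is closed on both sides).
#' @return `data.frame` with `age_lo`, `age_hi`, `n_pos`, `n_neg`, `auc`,
#'   `ok`.
#' @export
auc_by_age <- function(scores, labels, ages, bin_edges) {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1
  out <- data.frame(age_lo = bin_edges[-length(bin_edges)],
                    age_hi = bin_edges[-1],
                    n_pos = 0L, n_neg = 0L, auc = NA_real_, ok = FALSE)
  bin <- findInterval(ages, bin_edges, rightmost.closed = TRUE)
  for (b in seq_len(nb)) {
    sel <- bin == b
    out$n_pos[b] <- sum(labels[sel] == 1)
    out$n_neg[b] <- sum(labels[sel] == -1)
    if (out$n_pos[b] > 0 && out$n_neg[b] > 0) {
      out$auc[b] <- auc(scores[sel], labels[sel])
      out$ok[b] <- TRUE
    }
  }
  out
}

#' Minimum-error working point
#'
#' Selects the decision threshold that minimizes the summed false-positive
#' and false-negative counts,
#' \eqn{tH = \arg\min_{tH} \sum_i 1[y_i = -1] 1[s_i \ge tH] + 1[y_i = +1] 1[s_i < tH]},
#' with prediction positive iff `score >= tH`. Candidate thresholds are the
#' midpoints between consecutive sorted unique scores plus below-minimum
#' and above-maximum sentinels — every achievable confusion matrix is
#' visited. Ties are broken toward the smallest threshold (the more
#' sensitive working point).
#'
#' @param scores numeric scores.
#' @param labels labels in \{-1, +1\}; both classes required unless a
#'   degenerate single-class input is given, in which case the sentinel
#'   that classifies everything correctly is returned.
#' @return list of class `threshold_report`: `tH`, `FP` and `FN` (rates),
#'   `accuracy_01` (the 0-1 error, i.e. misclassification rate), `PPV`,
#'   `NPV`, and the raw counts.
#' @export
select_threshold <- function(scores, labels) {
  check_pm1(labels)
  us <- sort(unique(scores))
  cand <- c(us[1] - 1, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
            us[length(us)] + 1)
  obj <- vapply(cand, function(th) {
    sum(labels == -1 & scores >= th) + sum(labels == 1 & scores < th)
  }, numeric(1))
  tH <- cand[which.min(obj)]  # which.min takes the first = smallest tH
  pred <- ifelse(scores >= tH, 1, -1)
  fp <- sum(pred == 1 & labels == -1)
  fn <- sum(pred == -1 & labels == 1)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == -1 & labels == -1)
  npos <- tp + fn; nneg <- tn + fp
  structure(list(
    tH = tH,
    FP = if (nneg > 0) fp / nneg else 0,
    FN = if (npos > 0) fn / npos else 0,
    accuracy_01 = (fp + fn) / length(labels),
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn)
  ), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "working point tH = %.4g | FP %.3f FN %.3f | 0-1 error %.3f | PPV %.3f NPV %.3f\n",
    x$tH, x$FP, x$FN, x$accuracy_01, x$PPV, x$NPV))
  invisible(x)
}

#' Per-stage, per-day AUC report against a chosen negative class
#'
#' Mirrors the clinical evaluation layout: for each cascade stage (A-F)
#' and each evaluation day (end of day 3 = 72 h, end of day 5 = 114 h),
#' the AUC of KIDp embryos against the chosen negative set:
#' `KIDn` (failed single transfers), `aneuploid` (genetically abnormal),
#' `discarded` (all never-transferred embryos) or `hard_discarded` (the
#' flagged subset that reached blastocyst).
#'
#' @param score_tables named list of per-frame score tables, one per stage.
#' @param embryos per-embryo metadata ([embryo_table()]), already
#'   restricted to the evaluation split.
#' @param negatives negative class selector.
#' @param days named evaluation times in hours.
#' @return `data.frame` with `stage`, `day`, `t_hours`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
score_report <- function(score_tables, embryos,
                         negatives = c("KIDn", "aneuploid", "discarded",
                                       "hard_discarded"),
                         days = c(day3 = 72, day5 = 114)) {
  negatives <- match.arg(negatives)
  is_neg <- switch(negatives,
    KIDn = embryos$kid_tag == "KIDn",
    aneuploid = embryos$ploidy_tag == "aneuploid",
    discarded = embryos$kid_tag == "notKID",
    hard_discarded = embryos$hard_discarded
  )
  is_pos <- embryos$kid_tag == "KIDp"
  if (!any(is_neg)) stop("requested negative class '", negatives, "' is empty")
  if (!any(is_pos)) stop("no KIDp embryos to evaluate against")
  lab <- ifelse(is_pos, 1, ifelse(is_neg, -1, NA))
  names(lab) <- embryos$embryo_id
  lab <- lab[!is.na(lab)]
  rows <- list()
  for (stage in names(score_tables)) {
    for (d in seq_along(days)) {
      s <- score_at_time(score_tables[[stage]], days[d])
      s <- s[names(s) %in% names(lab)]
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, day = names(days)[d], t_hours = unname(days[d]),
        auc = auc(unname(s), unname(lab[names(s)])),
        n_pos = sum(lab[names(s)] == 1), n_neg = sum(lab[names(s)] == -1)
      )
    }
  }
  do.call(rbind, rows)
}
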