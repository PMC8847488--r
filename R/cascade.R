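#' Run the six-stage training cascade
#'
#' Orchestrates the full pipeline on a cohort:
#'
#' * **A** — multi-head frame classifier, fully supervised on KIDp vs KIDn
#'   training embryos (all focal planes as independent samples);
#' * **B** — ARMA integration of A's central-focal scores;
#' * **C** — student classifier trained on pseudo-contrastive pairs labeled
#'   by B's end-point scores over *all* training embryos, with the
#'   score-gap gate `theta` estimated from B's KIDp/KIDn histograms;
#' * **D** — ARMA integration of C;
#' * **E** — second pseudo-label round, teacher D, re-estimated `theta`;
#' * **F** — ARMA integration of E.
#'
#' Exactly two pseudo-label rounds are performed. Teacher end scores are
#' computed once per round from the frozen teacher on the central focal
#' plane at the last available time point.
#'
#' @param manifest a [cohort_manifest].
#' @param root directory image/mask paths are relative to.
#' @param clf_cfg a [classifier_config()].
#' @param alpha ARMA coefficient for stages B, D, F.
#' @param theta_o oocyte-age gate in years.
#' @param batch_size pair-training batch size.
#' @param epochs_a epochs for stage A.
#' @param steps_student mini-batch steps for stages C and E.
#' @param lr learning rate (all stages).
#' @param seed integer seed.
#' @param verbose print stage progress.
#' @return object of class `cascade_result`: `models` (A, C, E),
#'   `score_tables` (stages A-F; per-frame central-focal scores for every
#'   embryo in the manifest, with `split` attached), `thetas`
#'   (two pseudo-label rounds), `stage_log`, and the configuration.
#' @export
run_cascade <- function(manifest, root = ".", clf_cfg = classifier_config(),
                        alpha = 0.05, theta_o = 2, batch_size = 24,
                        epochs_a = 15, steps_student = 800, lr = 3e-3,
                        seed = 1, verbose = FALSE) {
  validate_manifest(manifest)
  df <- as.data.frame(manifest)
  emb <- embryo_table(manifest)
  say <- function(...) if (verbose) message(...)
  stage_log <- character(0)
  run_stage <- function(stage, expr) {
    say("stage ", stage)
    out <- tryCatch(expr, error = function(e) {
      stop("cascade stage ", stage, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_log <<- c(stage_log, stage)
    out
  }

  train_rows <- which(df$split == "train")
  central <- central_focal_rows(df)
  feat_train <- run_stage("features", {
    frame_features(manifest, clf_cfg, root = root, rows = train_rows)
  })
  stage_log <- character(0)  # feature caching is not a cascade stage
  feat_eval <- frame_features(manifest, clf_cfg, root = root, rows = central)
  emb_train <- emb[emb$split == "train", ]

  labels <- kid_label(emb$kid_tag)
  names(labels) <- emb$embryo_id

  score_table_of <- function(model) {
    s <- score_frames(model, feat_eval$X, feat_eval$frames$t_hours)
    data.frame(embryo_id = feat_eval$frames$embryo_id,
               t_hours = feat_eval$frames$t_hours,
               score = s,
               split = feat_eval$frames$split)
  }
  end_scores <- function(tab, ids) {
    sub <- tab[tab$embryo_id %in% ids, ]
    vapply(split(sub, sub$embryo_id)[ids], function(d)
      embryo_score(d$score[order(d$t_hours)], alpha = alpha), numeric(1))
  }

  model_a <- run_stage("A", train_model_a(
    feat_train, labels, clf_cfg, epochs = epochs_a,
    batch_size = batch_size, lr = lr, seed = seed))
  tab_a <- score_table_of(model_a)
  tab_b <- run_stage("B", {
    tb <- integrate_score_table(tab_a[c("embryo_id", "t_hours", "score")],
                                alpha = alpha)
    tb$split <- tab_a$split[order(tab_a$embryo_id, tab_a$t_hours)]
    tb
  })

  train_ids <- emb_train$embryo_id
  teacher_b <- end_scores(tab_a, train_ids)  # = B end scores by definition
  theta1 <- run_stage("theta1", estimate_theta(
    teacher_b[emb_train$kid_tag == "KIDp"],
    teacher_b[emb_train$kid_tag == "KIDn"]))
  pair_cfg1 <- pairing_config(theta = theta1, theta_o = theta_o,
                              batch_size = batch_size,
                              m = clf_cfg$m, gamma = clf_cfg$gamma)
  model_c <- run_stage("C", train_student(
    feat_train, emb_train, teacher_b, pair_cfg1, clf_cfg,
    steps = steps_student, lr = lr, seed = seed + 10L))
  tab_c <- score_table_of(model_c)
  tab_d <- run_stage("D", {
    td <- integrate_score_table(tab_c[c("embryo_id", "t_hours", "score")],
                                alpha = alpha)
    td$split <- tab_c$split[order(tab_c$embryo_id, tab_c$t_hours)]
    td
  })

  teacher_d <- end_scores(tab_c, train_ids)
  theta2 <- run_stage("theta2", estimate_theta(
    teacher_d[emb_train$kid_tag == "KIDp"],
    teacher_d[emb_train$kid_tag == "KIDn"]))
  pair_cfg2 <- pairing_config(theta = theta2, theta_o = theta_o,
                              batch_size = batch_size,
                              m = clf_cfg$m, gamma = clf_cfg$gamma)
  model_e <- run_stage("E", train_student(
    feat_train, emb_train, teacher_d, pair_cfg2, clf_cfg,
    steps = steps_student, lr = lr, seed = seed + 20L))
  tab_e <- score_table_of(model_e)
  tab_f <- run_stage("F", {
    tf <- integrate_score_table(tab_e[c("embryo_id", "t_hours", "score")],
                                alpha = alpha)
    tf$split <- tab_e$split[order(tab_e$embryo_id, tab_e$t_hours)]
    tf
  })

  structure(list(
    models = list(A = model_a, C = model_c, E = model_e),
    score_tables = list(A = tab_a, B = tab_b, C = tab_c, D = tab_d,
                        E = tab_e, F = tab_f),
    thetas = c(round1 = theta1, round2 = theta2),
    stage_log = c("A", "B", "C", "D", "E", "F"),
    alpha = alpha, clf_cfg = clf_cfg,
    embryos = emb
  ), class = "cascade_result")
}

# rows of the central focal plane (index 3, or the plane closest to it)
central_focal_rows <- function(df) {
  focals <- sort(unique(df$focal_index))
  central <- focals[which.min(abs(focals - 3))]
  which(df$focal_index == central)
}

#' Held-out AUC of every cascade stage
#'
#' Evaluates each stage's scores at an evaluation time on one split,
#' KIDp (+1) versus KIDn (-1).
#'
#' @param result a `cascade_result`.
#' @param split evaluation split (default `"test"`).
#' @param t_eval evaluation time in hours (default 114, the end of the
#'   clinical culture period).
#' @return named numeric vector of AUCs, stages A-F.
#' @export
cascade_auc <- function(result, split = "test", t_eval = 114) {
  emb <- result$embryos
  keep <- emb$split == split & emb$kid_tag %in% c("KIDp", "KIDn")
  lab <- kid_label(emb$kid_tag[keep])
  names(lab) <- emb$embryo_id[keep]
  vapply(result$score_tables, function(tab) {
    s <- score_at_time(tab[tab$embryo_id %in% names(lab), ], t_eval)
    auc(unname(s), unname(lab[names(s)]))
  }, numeric(1))
}

#' Held-out AUC including hidden KID labels
#'
#' For semi-supervised experiments in which a fraction of KID labels was
#' hidden before training ([hide_kid_labels()]): evaluates each stage on
#' every KID-labeled embryo whose label no trained stage ever saw — the
#' hidden train/val embryos plus the test split.
#'
#' @param result a `cascade_result` run on the label-hidden manifest.
#' @param hidden the `hidden` table returned by [hide_kid_labels()].
#' @param t_eval evaluation time in hours.
#' @return named numeric vector of AUCs, stages A-F.
#' @export
heldout_kid_auc <- function(result, hidden, t_eval = 114) {
  emb <- result$embryos
  lab <- kid_label(emb$kid_tag)
  names(lab) <- emb$embryo_id
  lab[hidden$embryo_id] <- kid_label(hidden$kid_tag)
  keep <- names(lab)[!is.na(lab) &
                       (emb$split == "test" |
                          names(lab) %in% hidden$embryo_id)]
  vapply(result$score_tables, function(tab) {
    s <- score_at_time(tab[tab$embryo_id %in% keep, ], t_eval)
    auc(unname(s), unname(lab[names(s)]))
  }, numeric(1))
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Six-stage cascade result\n")
  cat("  stages:", paste(x$stage_log, collapse = " -> "), "\n")
  cat(sprintf("  theta round 1/2: %.4g / %.4g, alpha = %.3g\n",
              x$thetas[1], x$thetas[2], x$alpha))
  cat("  embryos scored:", length(unique(x$score_tables$A$embryo_id)), "\n")
  invisible(x)
}
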