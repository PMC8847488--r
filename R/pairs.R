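#' Pairing configuration for pseudo-contrastive training
#'
#' @param theta score-gap gate (>= 0): a pair is labeled only when the
#'   teacher's end-point scores differ by more than `theta`. Estimated from
#'   the teacher's class histograms by [estimate_theta()] in the cascade.
#' @param theta_o maximum oocyte-age gap in years for a valid pair
#'   (default 2, about half a standard deviation of clinical oocyte ages).
#' @param batch_size embryos per mini-batch (default 24).
#' @param m,gamma soft hinge parameters of the pair loss.
#' @param double_count count each unordered pair twice, as the literal
#'   ordered double sum would; the soft hinge satisfies
#'   `l(s, y) = l(-s, -y)`, so this only doubles the loss scale (default
#'   `FALSE`: each unordered pair once).
#' @return object of class `pairing_config`.
#' @export
pairing_config <- function(theta = 0, theta_o = 2, batch_size = 24,
                           m = 1, gamma = 1, double_count = FALSE) {
  stopifnot(theta >= 0, theta_o >= 0, batch_size >= 2, gamma > 0)
  structure(list(theta = theta, theta_o = theta_o, batch_size = batch_size,
                 m = m, gamma = gamma, double_count = double_count),
            class = "pairing_config")
}

#' Pair score of a student classifier
#'
#' The joint score of an (i, j) pair is simply the difference of the
#' student's single-frame scores, \eqn{s_{ij} = C(x_i^{t_i}) - C(x_j^{t_j})};
#' the two frames need not share a timestamp.
#'
#' @param c_i,c_j student scores of the two frames.
#' @return `c_i - c_j` (antisymmetric in its arguments).
#' @export
pair_score <- function(c_i, c_j) c_i - c_j

#' Pseudo label for a pair of embryos
#'
#' Derives a \{-1, 0, +1\} ranking label from the teacher's end-point
#' integrated scores: +1 when the teacher favors i over j by more than
#' `theta` *and* j is not KID-positive, -1 symmetrically, otherwise 0.
#' Known-positive embryos are thereby protected from ever sitting on the
#' losing side of a pseudo label, no matter what the teacher says.
#'
#' @param b_i,b_j teacher end-point scores of embryos i and j.
#' @param kid_i,kid_j KID tags of the two embryos.
#' @param theta score-gap gate (>= 0).
#' @return -1, 0 or +1; antisymmetric under swapping (i, j).
#' @export
pair_label <- function(b_i, b_j, kid_i, kid_j, theta) {
  stopifnot(theta >= 0)
  if (b_i - b_j > theta && kid_j != "KIDp") return(1)
  if (b_j - b_i > theta && kid_i != "KIDp") return(-1)
  0
}

#' Oocyte-age gate for a pair
#'
#' Implantation odds are confounded by oocyte age, so only embryos of
#' similar maternal age may be compared: a pair is valid when
#' `|age_i - age_j| <= theta_o`.
#'
#' @param age_i,age_j oocyte ages in years.
#' @param theta_o maximum allowed gap (years).
#' @return logical.
#' @export
valid_pair <- function(age_i, age_j, theta_o) {
  abs(age_i - age_j) <= theta_o
}

#' Estimate the score-gap gate from teacher histograms
#'
#' Builds one `n_bins`-bin histogram of the teacher's end-point scores for
#' each class — each over its own score range — and averages, over the bin
#' indices populated in both histograms, the difference between the mean
#' positive-class score and the mean negative-class score of the matching
#' bins. If no bin index is populated in both, falls back to
#' `mean(pos) - mean(neg)`. The estimate is clamped at 0 (the gate cannot
#' be negative). A degenerate zero-width score range collapses to a single
#' bin.
#'
#' @param teacher_scores_pos teacher end scores of KIDp training embryos.
#' @param teacher_scores_neg teacher end scores of KIDn training embryos.
#' @param n_bins number of histogram bins (default 100).
#' @return scalar theta >= 0.
#' @export
estimate_theta <- function(teacher_scores_pos, teacher_scores_neg,
                           n_bins = 100) {
  if (length(teacher_scores_pos) == 0 || length(teacher_scores_neg) == 0) {
    stop("both classes must provide at least one teacher score")
  }
  bin_means <- function(x) {
    r <- range(x)
    if (diff(r) == 0) {
      means <- rep(NA_real_, n_bins); means[1] <- x[1]
      return(means)
    }
    bins <- pmin(floor((x - r[1]) / diff(r) * n_bins) + 1L, n_bins)
    means <- rep(NA_real_, n_bins)
    agg <- tapply(x, bins, mean)
    means[as.integer(names(agg))] <- agg
    means
  }
  mp <- bin_means(teacher_scores_pos)
  mn <- bin_means(teacher_scores_neg)
  both <- !is.na(mp) & !is.na(mn)
  theta <- if (any(both)) {
    mean(mp[both] - mn[both])
  } else {
    mean(teacher_scores_pos) - mean(teacher_scores_neg)
  }
  max(theta, 0)
}

#' Enumerate labeled pairs within a mini-batch
#'
#' Considers every unordered pair of batch members, drops pairs failing the
#' oocyte-age gate ([valid_pair()]), labels the rest from the teacher's end
#' scores ([pair_label()]), and drops y = 0 pairs (under the soft hinge
#' they contribute a constant with zero gradient).
#'
#' @param batch `data.frame` with one row per batch member and columns
#'   `embryo_id`, `teacher_score`, `kid_tag`, `oocyte_age_years` (frame
#'   identity columns are carried through).
#' @param cfg a [pairing_config()].
#' @return `data.frame` with columns `i`, `j` (row indices into `batch`)
#'   and `y` in \{-1, +1\}; zero rows when no pair survives.
#' @export
build_batch_pairs <- function(batch, cfg) {
  n <- nrow(batch)
  out_i <- integer(0); out_j <- integer(0); out_y <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!valid_pair(batch$oocyte_age_years[i], batch$oocyte_age_years[j],
                        cfg$theta_o)) next
        y <- pair_label(batch$teacher_score[i], batch$teacher_score[j],
                        batch$kid_tag[i], batch$kid_tag[j], cfg$theta)
        if (y != 0) {
          out_i <- c(out_i, i); out_j <- c(out_j, j); out_y <- c(out_y, y)
        }
      }
    }
  }
  data.frame(i = out_i, j = out_j, y = out_y)
}

#' Pseudo-contrastive pair loss
#'
#' Sum of soft-hinge terms over the labeled pairs of a batch,
#' \eqn{L = \sum_{(i,j)} \log(1 + e^{\gamma(m - y_{ij} s_{ij})})} with
#' \eqn{s_{ij}} the student score difference.
#'
#' @param pairs `data.frame` from [build_batch_pairs()] (`i`, `j`, `y`).
#' @param student_scores numeric vector of student scores, indexed by the
#'   pair table's `i`/`j`; `NA` (unscored frame) is an error.
#' @param cfg a [pairing_config()].
#' @return scalar loss (0 for an empty pair list).
#' @export
pair_loss <- function(pairs, student_scores, cfg) {
  if (nrow(pairs) == 0) return(0)
  s_i <- student_scores[pairs$i]
  s_j <- student_scores[pairs$j]
  if (anyNA(s_i) || anyNA(s_j)) stop("missing student score for a paired frame")
  l <- sum(soft_hinge(pair_score(s_i, s_j), pairs$y, m = cfg$m,
                      gamma = cfg$gamma))
  if (isTRUE(cfg$double_count)) 2 * l else l
}

# dL/ds for every batch member, from the pair loss
pair_loss_grad <- function(pairs, student_scores, cfg) {
  g <- numeric(length(student_scores))
  if (nrow(pairs) == 0) return(g)
  d <- pair_score(student_scores[pairs$i], student_scores[pairs$j])
  gd <- soft_hinge_grad(d, pairs$y, m = cfg$m, gamma = cfg$gamma)
  if (isTRUE(cfg$double_count)) gd <- 2 * gd
  for (k in seq_len(nrow(pairs))) {
    g[pairs$i[k]] <- g[pairs$i[k]] + gd[k]
    g[pairs$j[k]] <- g[pairs$j[k]] - gd[k]
  }
  g
}

#' Train a student classifier on pseudo-contrastive pairs
#'
#' Cascade stages C and E: a fresh multi-head classifier is trained on
#' *all* embryos — KID-labeled, ambiguous (KIDu) and untagged alike —
#' using pairwise pseudo labels derived from a frozen teacher's end-point
#' integrated scores. Mini-batches are age-similar: an anchor embryo is
#' drawn, the batch is filled with embryos nearest in oocyte age (the
#' per-pair age gate is still enforced), and each batch member contributes
#' one uniformly random (frame, focal) sample.
#'
#' @param features output of [frame_features()] for the training split
#'   (all focal planes).
#' @param embryos per-embryo metadata ([embryo_table()]) for the same
#'   split.
#' @param teacher_scores named numeric vector: the teacher's end-point
#'   integrated score for every training embryo (names = embryo ids).
#' @param cfg a [pairing_config()] (with `theta` already set).
#' @param clf_cfg a [classifier_config()].
#' @param steps number of mini-batch steps.
#' @param lr Adam learning rate.
#' @param aug_brightness,aug_noise training-time augmentation, as in
#'   [train_model_a()].
#' @param seed integer seed.
#' @return a trained `frame_classifier`.
#' @export
train_student <- function(features, embryos, teacher_scores, cfg,
                          clf_cfg = classifier_config(), steps = 400,
                          lr = 3e-3, aug_brightness = 0.08, aug_noise = 0.03,
                          seed = 1) {
  ids <- unique(features$frames$embryo_id)
  missing <- setdiff(ids, names(teacher_scores))
  if (length(missing)) {
    stop("teacher scores missing for ", length(missing), " embryo(s)")
  }
  emb <- embryos[match(ids, embryos$embryo_id), ]
  frame_rows <- split(seq_len(nrow(features$frames)),
                      features$frames$embryo_id)[ids]
  model <- new_frame_classifier(clf_cfg, d = ncol(features$X), seed = seed)
  model$mu <- colMeans(features$X)
  model$sigma <- pmax(apply(features$X, 2, sd), 1e-6)
  st <- adam_init(model$pars)
  loss_log <- numeric(steps)
  n_pairs_log <- integer(steps)
  with_seed(seed + 1L, {
    for (step in seq_len(steps)) {
      anchor <- sample(length(ids), 1)
      gaps <- abs(emb$oocyte_age_years - emb$oocyte_age_years[anchor])
      take <- order(gaps)[seq_len(min(cfg$batch_size, length(ids)))]
      rows <- vapply(frame_rows[take], function(r)
        if (length(r) == 1L) r else sample(r, 1), integer(1))
      batch <- data.frame(
        embryo_id = ids[take],
        teacher_score = unname(teacher_scores[ids[take]]),
        kid_tag = emb$kid_tag[take],
        oocyte_age_years = emb$oocyte_age_years[take]
      )
      pairs <- build_batch_pairs(batch, cfg)
      n_pairs_log[step] <- nrow(pairs)
      if (nrow(pairs) == 0) next
      Xb <- augment_features(features$X[rows, , drop = FALSE],
                             aug_brightness, aug_noise)
      hb <- features$frames$head[rows]
      fw <- clf_forward(model, Xb, hb)
      loss_log[step] <- pair_loss(pairs, fw$s, cfg)
      ds <- pair_loss_grad(pairs, fw$s, cfg)
      gr <- clf_backward(model, fw, hb, ds)
      upd <- adam_step(model$pars, gr, st, lr, clf_cfg$weight_decay)
      model$pars <- upd$pars; st <- upd$state
    }
  })
  model$log <- list(step_loss = loss_log, n_pairs = n_pairs_log,
                    theta = cfg$theta, lr = lr)
  model
}
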