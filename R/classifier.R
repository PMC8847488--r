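#' Time-window head configuration
#'
#' The frame classifier carries one prediction head per time window of the
#' inspected interval. With the defaults — interval (30, 120) hours post
#' fertilization and 2-h windows — the classifier has exactly 45 heads.
#'
#' @param t0,te interval bounds, hours post fertilization (te > t0).
#' @param window_hours window width; `(te - t0) / window_hours` must be a
#'   positive integer.
#' @return object of class `head_config` with `n_heads` precomputed.
#' @export
head_config <- function(t0 = 30, te = 120, window_hours = 2) {
  stopifnot(te > t0, window_hours > 0)
  n <- (te - t0) / window_hours
  if (abs(n - round(n)) > 1e-9) {
    stop("(te - t0) must be an integer multiple of window_hours")
  }
  structure(list(t0 = t0, te = te, window_hours = window_hours,
                 n_heads = as.integer(round(n))),
            class = "head_config")
}

#' Map a frame time to its prediction head
#'
#' Windows are right-open, `[t0 + (k-1) w, t0 + k w)`, except that `te`
#' itself folds into the last head, so the interval is partitioned exactly.
#' Heads are numbered 1..n_heads.
#'
#' @param t_hours frame time(s), hours post fertilization; must lie in
#'   `[t0, te]` (no extrapolating head exists).
#' @param cfg a [head_config()].
#' @return integer head index (1-based), vectorized over `t_hours`.
#' @export
head_index <- function(t_hours, cfg) {
  if (any(t_hours < cfg$t0 - 1e-9) || any(t_hours > cfg$te + 1e-9)) {
    stop("t_hours outside the classifier interval [", cfg$t0, ", ", cfg$te, "]")
  }
  k <- floor((t_hours - cfg$t0) / cfg$window_hours) + 1L
  as.integer(pmin(k, cfg$n_heads))
}

#' Frame classifier configuration
#'
#' @param head_config a [head_config()].
#' @param m,gamma soft hinge margin and softness of the training losses.
#' @param backbone `"tiny"` (average-pool stem, one shared trainable hidden
#'   layer, per-head linear outputs — the desk-scale default) or `"pooled"`
#'   (no hidden layer: per-head linear model on the pooled stem).
#' @param input_size side length the embryo crop is resized to.
#' @param pool_size side length of the average-pooled stem grid.
#' @param hidden width of the shared hidden layer (tiny backbone).
#' @param weight_decay L2 regularization coefficient (default 1e-5).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(head_config = embryopcl::head_config(),
                              m = 1, gamma = 1,
                              backbone = c("tiny", "pooled"),
                              input_size = 64, pool_size = 16, hidden = 16,
                              weight_decay = 1e-5) {
  stopifnot(m >= 0, gamma > 0, input_size %% pool_size == 0, hidden >= 1)
  structure(list(head_config = head_config, m = m, gamma = gamma,
                 backbone = match.arg(backbone), input_size = input_size,
                 pool_size = pool_size, hidden = hidden,
                 weight_decay = weight_decay),
            class = "classifier_config")
}

# --- feature stem -------------------------------------------------------

# fixed two-channel stem: block-averaged intensity plus block-averaged
# gradient magnitude (texture/edge energy, invariant to global
# illumination) on a pool_size x pool_size grid
pool_stem <- function(image, pool_size) {
  S <- nrow(image)
  gx <- rbind(abs(diff(image)), 0)
  gy <- cbind(abs(t(diff(t(image)))), 0)
  c(block_means(image, pool_size), block_means(gx + gy, pool_size))
}

block_means <- function(image, pool_size) {
  b <- nrow(image) / pool_size
  idx <- rep(seq_len(pool_size), each = b)
  m <- rowsum(image, idx) / b
  as.vector(t(rowsum(t(m), idx) / b))
}

# crop (using the mask when available) + resize + pool: one feature vector
frame_feature_vector <- function(image, mask, cfg) {
  crop <- if (!is.null(mask) && sum(mask) > 0) {
    crop_embryo(image, mask, out_size = cfg$input_size)
  } else if (nrow(image) != cfg$input_size) {
    matrix(as.numeric(EBImage::resize(image, cfg$input_size, cfg$input_size)),
           cfg$input_size, cfg$input_size)
  } else image
  pool_stem(crop, cfg$pool_size)
}

#' Extract classifier features for manifest frames
#'
#' Loads every selected frame, crops it around its mask (when present),
#' and applies the pooling stem once, so the training loops can run on a
#' cached feature matrix.
#'
#' @param manifest a [cohort_manifest].
#' @param cfg a [classifier_config()].
#' @param root directory that `image_path`/`mask_path` are relative to.
#' @param rows optional logical/integer subset of manifest rows.
#' @return list with `X` (frames x features matrix) and `frames` (the
#'   corresponding manifest rows plus `head`).
#' @export
frame_features <- function(manifest, cfg, root = ".", rows = NULL) {
  df <- as.data.frame(manifest)
  if (!is.null(rows)) df <- df[rows, , drop = FALSE]
  n <- nrow(df)
  X <- matrix(0, n, 2 * cfg$pool_size^2)
  for (i in seq_len(n)) {
    fr <- load_frame(file.path(root, df$image_path[i]),
                     if (nzchar(df$mask_path[i]))
                       file.path(root, df$mask_path[i]) else NULL)
    X[i, ] <- frame_feature_vector(fr$image, fr$mask, cfg)
  }
  df$head <- head_index(pmin(df$t_hours, cfg$head_config$te), cfg$head_config)
  list(X = X, frames = df)
}

# --- model --------------------------------------------------------------

new_frame_classifier <- function(cfg, d = 2 * cfg$pool_size^2, seed = 1) {
  K <- cfg$head_config$n_heads
  H <- cfg$hidden
  with_seed(seed, {
    # readouts start at zero: an untrained head is neutral, and the shared
    # readout (W0) keeps score polarity consistent across time windows
    pars <- if (cfg$backbone == "tiny") {
      list(W1 = matrix(rnorm(d * H, 0, sqrt(2 / d)), d, H),
           b1 = numeric(H),
           W0 = numeric(H), b0 = 0,
           W2 = matrix(0, H, K),
           b2 = numeric(K))
    } else {
      list(W2 = matrix(0, d, K), b2 = numeric(K))
    }
    structure(list(cfg = cfg, pars = pars,
                   mu = numeric(d), sigma = rep(1, d), log = list()),
              class = "frame_classifier")
  })
}

clf_forward <- function(model, X, heads) {
  p <- model$pars
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  if (model$cfg$backbone == "tiny") {
    Z <- sweep(Xs %*% p$W1, 2, p$b1, "+")
    A <- pmax(Z, 0)
    # head k's readout = shared readout + dedicated per-head correction
    s <- as.vector(A %*% p$W0) + p$b0 +
      rowSums(A * t(p$W2)[heads, , drop = FALSE]) + p$b2[heads]
    list(s = s, A = A, Z = Z, Xs = Xs)
  } else {
    s <- rowSums(Xs * t(p$W2)[heads, , drop = FALSE]) + p$b2[heads]
    list(s = s, Xs = Xs)
  }
}

# gradient of a scalar loss wrt parameters, given dL/ds per frame
clf_backward <- function(model, fw, heads, ds) {
  p <- model$pars
  K <- model$cfg$head_config$n_heads
  if (model$cfg$backbone == "tiny") {
    gW2 <- matrix(0, nrow(p$W2), K)      # H x K
    gb2 <- numeric(K)
    Ads <- fw$A * ds                     # row b scaled by ds[b]
    for (k in unique(heads)) {
      sel <- heads == k
      gW2[, k] <- colSums(Ads[sel, , drop = FALSE])
      gb2[k] <- sum(ds[sel])
    }
    gW0 <- as.vector(crossprod(fw$A, ds))
    gb0 <- sum(ds)
    GA <- ds * sweep(t(p$W2)[heads, , drop = FALSE], 2, p$W0, "+")  # dL/dA
    GZ <- GA * (fw$Z > 0)
    gW1 <- crossprod(fw$Xs, GZ)
    gb1 <- colSums(GZ)
    list(W1 = gW1, b1 = gb1, W0 = gW0, b0 = gb0, W2 = gW2, b2 = gb2)
  } else {
    gW2 <- matrix(0, nrow(p$W2), K)
    gb2 <- numeric(K)
    GX <- fw$Xs * ds
    for (k in unique(heads)) {
      sel <- heads == k
      gW2[, k] <- colSums(GX[sel, , drop = FALSE])
      gb2[k] <- sum(ds[sel])
    }
    list(W2 = gW2, b2 = gb2)
  }
}

# per-sample constant brightness jitter + iid feature noise, in raw
# intensity units (applied before standardization)
augment_features <- function(X, brightness_sd, noise_sd) {
  if (brightness_sd > 0) X <- X + rnorm(nrow(X), 0, brightness_sd)
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow(X))
  X
}

adam_init <- function(pars) {
  list(m = lapply(pars, function(p) p * 0),
       v = lapply(pars, function(p) p * 0), t = 0)
}

adam_step <- function(pars, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1
  for (nm in names(pars)) {
    g <- grads[[nm]] + weight_decay * pars[[nm]]
    state$m[[nm]] <- 0.9 * state$m[[nm]] + 0.1 * g
    state$v[[nm]] <- 0.999 * state$v[[nm]] + 0.001 * g^2
    mhat <- state$m[[nm]] / (1 - 0.9^state$t)
    vhat <- state$v[[nm]] / (1 - 0.999^state$t)
    pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(pars = pars, state = state)
}

#' Score frames with a trained classifier
#'
#' Routes each frame's pooled features through the shared backbone and the
#' single head owned by its acquisition time ([head_index()]); heads of
#' other time windows never contribute. Deterministic: equal inputs give
#' bit-equal scores, and batch scoring equals per-frame scoring.
#'
#' @param model a `frame_classifier`.
#' @param X feature matrix from [frame_features()] (rows = frames).
#' @param t_hours per-frame times (used to route heads).
#' @return numeric score vector.
#' @export
score_frames <- function(model, X, t_hours) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  heads <- head_index(t_hours, model$cfg$head_config)
  clf_forward(model, X, heads)$s
}

#' Score a single frame image
#'
#' Convenience wrapper: crop/pool one image and score it at time `t_hours`.
#'
#' @param model a `frame_classifier`.
#' @param image intensity matrix (a crop or a full frame).
#' @param t_hours acquisition time, hours post fertilization.
#' @param mask optional embryo mask used for cropping.
#' @return scalar score.
#' @export
score_frame <- function(model, image, t_hours, mask = NULL) {
  x <- frame_feature_vector(image, mask, model$cfg)
  score_frames(model, matrix(x, nrow = 1), t_hours)
}

#' Train the fully supervised frame classifier (cascade stage A)
#'
#' Trains the multi-head classifier on KID-labeled embryos only (KIDp = +1
#' vs KIDn = -1) with the summed soft-hinge loss ([supervised_loss()]),
#' Adam, and L2 weight decay. All focal planes enter as independent
#' training samples; minibatches are uniform random frames.
#'
#' Training batches are augmented with a per-frame global brightness jitter
#' and per-feature noise (the generated data's illumination nuisance;
#' augmentation substitutes for clinical-scale data diversity and keeps the
#' small model from memorizing individual embryos).
#'
#' @param features output of [frame_features()] restricted to the training
#'   split (all focal planes).
#' @param labels named per-embryo labels (+1/-1/NA), e.g.
#'   `kid_label(tags)` named by embryo id; frames of NA embryos are
#'   ignored.
#' @param cfg a [classifier_config()].
#' @param epochs,batch_size,lr optimizer settings.
#' @param aug_brightness sd of the per-sample constant intensity jitter.
#' @param aug_noise sd of iid per-feature intensity jitter.
#' @param seed integer seed (init + shuffling).
#' @return a trained `frame_classifier` with a `log` of per-epoch losses.
#' @export
train_model_a <- function(features, labels, cfg = classifier_config(),
                          epochs = 15, batch_size = 24, lr = 3e-3,
                          aug_brightness = 0.15, aug_noise = 0.06, seed = 1) {
  y <- labels[features$frames$embryo_id]
  keep <- which(!is.na(y))
  if (length(keep) == 0) stop("no KID-labeled frames in the training data")
  if (length(unique(y[keep])) < 2) {
    stop("single-class training set: both KIDp and KIDn embryos are required")
  }
  X <- features$X[keep, , drop = FALSE]
  heads <- features$frames$head[keep]
  y <- y[keep]
  model <- new_frame_classifier(cfg, d = ncol(X), seed = seed)
  model$mu <- colMeans(X)
  model$sigma <- pmax(apply(X, 2, sd), 1e-6)
  st <- adam_init(model$pars)
  losses <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(y))
      tot <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xb <- augment_features(X[b, , drop = FALSE], aug_brightness, aug_noise)
        fw <- clf_forward(model, Xb, heads[b])
        tot <- tot + supervised_loss(fw$s, y[b], m = cfg$m, gamma = cfg$gamma)
        ds <- soft_hinge_grad(fw$s, y[b], m = cfg$m, gamma = cfg$gamma)
        gr <- clf_backward(model, fw, heads[b], ds)
        upd <- adam_step(model$pars, gr, st, lr, cfg$weight_decay)
        model$pars <- upd$pars; st <- upd$state
      }
      losses[ep] <- tot / length(y)
    }
  })
  model$log <- list(epoch_loss = losses, n_frames = length(y),
                    weight_decay = cfg$weight_decay, lr = lr)
  model
}
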