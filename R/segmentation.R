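#' Focal-style per-pixel weights
#'
#' Weights every pixel by how wrong its current score is, normalized so
#' that foreground and background each carry one unit of total weight:
#' \deqn{w_p = \frac{e^{-s_p y_p}}{\sum_{q: y_q = y_p} e^{-s_q y_q}}}
#' Pixels whose scores already agree with their ground truth are
#' underweighted, and the per-class normalization compensates the heavy
#' foreground/background imbalance of embryo masks.
#'
#' Weights are treated as constants in gradient computations (no
#' backpropagation through the normalizer), following the focal-loss
#' convention.
#'
#' @param s numeric array of pixel scores.
#' @param y pixel labels in \{-1, +1\} (+1 = embryo/foreground).
#' @return array of weights, same shape as `s`; each class present sums
#'   to 1.
#' @export
pixel_weights <- function(s, y) {
  check_pm1(y)
  if (length(s) != length(y)) stop("scores and labels differ in length")
  # subtract the per-class max exponent for numerical stability
  z <- -as.vector(s) * as.vector(y)
  w <- numeric(length(z))
  for (cls in c(-1, 1)) {
    idx <- which(y == cls)
    if (length(idx)) {
      e <- exp(z[idx] - max(z[idx]))
      w[idx] <- e / sum(e)
    }
  }
  if (is.matrix(s)) dim(w) <- dim(s)
  w
}

#' Weighted soft-hinge segmentation loss
#'
#' The training objective of the embryo segmenter: the per-pixel soft hinge
#' loss ([soft_hinge()]) multiplied by the focal-style class-normalized
#' weights ([pixel_weights()]) and summed over pixels,
#' \eqn{l = \sum_p w_p(s_p, y_p)\, l_p(s_p, y_p)}.
#'
#' @param s numeric array of pixel scores.
#' @param y pixel labels in \{-1, +1\}.
#' @param m,gamma soft hinge margin and softness (both default 1).
#' @param weighted set `FALSE` for the plain (mean) soft hinge, the
#'   unweighted ablation baseline.
#' @return scalar loss.
#' @export
segmentation_loss <- function(s, y, m = 1, gamma = 1, weighted = TRUE) {
  l <- soft_hinge(s, y, m = m, gamma = gamma)
  if (!weighted) return(mean(l))
  sum(pixel_weights(s, y) * l)
}

#' Embryo detection metrics from a predicted mask
#'
#' Compares a predicted binary mask with the ground-truth embryo mask.
#' Positive predictions are split into 8-connected clusters; the reported
#' `iou` is the intersection-over-union of the *largest* cluster with the
#' ground truth. A detection is a true positive when that IoU exceeds 0.9;
#' any predicted cluster with IoU below 0.5 counts as a false-positive
#' detection (a spurious object).
#'
#' @param pred_mask binary (0/1 or logical) matrix of predicted foreground.
#' @param gt_mask binary matrix of the true embryo; must be nonempty.
#' @return list with `is_TP`, `is_FP`, `iou` (largest-cluster IoU) and
#'   `cluster_ious` (IoU of every predicted cluster).
#' @export
detection_metrics <- function(pred_mask, gt_mask) {
  pred_mask <- (pred_mask > 0) + 0
  gt_mask <- (gt_mask > 0) + 0
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("mask shapes differ")
  if (sum(gt_mask) == 0) stop("empty ground-truth mask")
  if (sum(pred_mask) == 0) {
    return(list(is_TP = FALSE, is_FP = FALSE, iou = 0, cluster_ious = numeric(0)))
  }
  labels <- EBImage::bwlabel(pred_mask)
  n_cl <- max(labels)
  ious <- numeric(n_cl)
  sizes <- integer(n_cl)
  for (c in seq_len(n_cl)) {
    cl <- labels == c
    sizes[c] <- sum(cl)
    ious[c] <- sum(cl & gt_mask == 1) / sum(cl | gt_mask == 1)
  }
  iou <- ious[which.max(sizes)]
  list(is_TP = iou > 0.9, is_FP = any(ious < 0.5), iou = iou,
       cluster_ious = ious)
}

#' Crop the embryo sub-image
#'
#' Cuts a square window centered on the mask centroid — sized to the mask's
#' bounding box plus a margin — pads out-of-frame regions with the median
#' border intensity, and resizes to `out_size` x `out_size`. This is the
#' input normalization step feeding the frame classifier.
#'
#' @param image 2-D intensity matrix.
#' @param mask nonempty binary matrix, same shape.
#' @param out_size output side length in pixels (default 256).
#' @param pad_frac margin around the mask bounding box, as a fraction of
#'   its larger side.
#' @return `out_size` x `out_size` numeric matrix.
#' @export
crop_embryo <- function(image, mask, out_size = 256, pad_frac = 0.15) {
  mask <- (mask > 0) + 0
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (sum(mask) == 0) stop("empty mask: nothing to crop")
  idx <- which(mask == 1, arr.ind = TRUE)
  ci <- mean(idx[, 1]); cj <- mean(idx[, 2])
  ext <- max(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
  side <- max(8L, as.integer(ceiling(ext * (1 + 2 * pad_frac))))
  half <- side / 2
  ri <- as.integer(round(ci - half)) + seq_len(side)
  rj <- as.integer(round(cj - half)) + seq_len(side)
  border <- median(c(image[1, ], image[nrow(image), ],
                     image[, 1], image[, ncol(image)]))
  out <- matrix(border, side, side)
  ok_i <- ri >= 1 & ri <= nrow(image)
  ok_j <- rj >= 1 & rj <= ncol(image)
  out[ok_i, ok_j] <- image[ri[ok_i], rj[ok_j]]
  if (side != out_size) {
    out <- EBImage::resize(out, w = out_size, h = out_size)
    out <- matrix(as.numeric(out), out_size, out_size)
  }
  out
}

# --- pixelwise segmenter -----------------------------------------------

# multi-scale local feature bank: a fixed filter-bank front end over which
# a 1x1 convolution (linear pixel scorer) is trained
pixel_features <- function(image) {
  m3 <- box_mean(image, 1)
  m9 <- box_mean(image, 4)
  m17 <- box_mean(image, 8)
  sq <- box_mean(image^2, 2)
  sd5 <- sqrt(pmax(sq - box_mean(image, 2)^2, 0))
  cbind(1, as.vector(image), as.vector(m3), as.vector(m9), as.vector(m17),
        as.vector(sd5), as.vector(image - m17))
}

# integral-image box mean with clipped-at-edge windows, radius r
box_mean <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  cs <- matrix(0, n + 1, m + 1)
  cs[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  i1 <- pmax(seq_len(n) - r, 1); i2 <- pmin(seq_len(n) + r, n)
  j1 <- pmax(seq_len(m) - r, 1); j2 <- pmin(seq_len(m) + r, m)
  S <- cs[i2 + 1, j2 + 1] - cs[i1, j2 + 1] - cs[i2 + 1, j1] + cs[i1, j1]
  area <- outer(i2 - i1 + 1, j2 - j1 + 1)
  S / area
}

#' Train the pixelwise embryo segmenter
#'
#' Fits a linear per-pixel scorer over a fixed multi-scale local feature
#' bank (intensity, box means at three scales, local standard deviation,
#' and a center-surround contrast channel) by Adam gradient descent on the
#' weighted soft-hinge objective ([segmentation_loss()]). One training step
#' consumes one frame; per-pixel weights are recomputed every step and held
#' constant within the gradient.
#'
#' @param images list of intensity matrices.
#' @param masks list of matching binary masks (foreground = embryo).
#' @param m,gamma soft hinge parameters.
#' @param weighted use the focal-style per-class weights (default `TRUE`);
#'   `FALSE` trains on the plain mean soft hinge.
#' @param epochs passes over the frames (0 returns the untrained model).
#' @param lr Adam learning rate.
#' @param seed integer seed for frame order shuffling.
#' @return an object of class `pixel_segmenter`.
#' @export
train_segmenter <- function(images, masks, m = 1, gamma = 1, weighted = TRUE,
                            epochs = 20, lr = 0.05, seed = 1) {
  stopifnot(length(images) == length(masks))
  if (length(images) == 0) stop("no masked frames to train on")
  d <- ncol(pixel_features(images[[1]]))
  beta <- numeric(d)
  mstate <- numeric(d); vstate <- numeric(d); step <- 0
  feats <- lapply(images, pixel_features)
  ys <- lapply(masks, function(mk) ifelse(as.vector(mk > 0), 1, -1))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (k in sample(seq_along(feats))) {
        X <- feats[[k]]; y <- ys[[k]]
        s <- as.vector(X %*% beta)
        gl <- soft_hinge_grad(s, y, m = m, gamma = gamma)
        gs <- if (weighted) pixel_weights(s, y) * gl else gl / length(gl)
        g <- as.vector(crossprod(X, gs))
        step <- step + 1
        mstate <- 0.9 * mstate + 0.1 * g
        vstate <- 0.999 * vstate + 0.001 * g^2
        mhat <- mstate / (1 - 0.9^step)
        vhat <- vstate / (1 - 0.999^step)
        beta <- beta - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  })
  structure(list(beta = beta, m = m, gamma = gamma, weighted = weighted,
                 epochs = epochs),
            class = "pixel_segmenter")
}

#' Pixel scores from a trained segmenter
#'
#' @param object a `pixel_segmenter`.
#' @param image intensity matrix.
#' @param type `"score"` for the real-valued score map, `"mask"` for the
#'   thresholded (score > 0) binary mask.
#' @param ... unused.
#' @return matrix of scores or a 0/1 mask.
#' @export
predict.pixel_segmenter <- function(object, image, type = c("score", "mask"),
                                    ...) {
  type <- match.arg(type)
  s <- matrix(pixel_features(image) %*% object$beta, nrow(image), ncol(image))
  if (type == "mask") (s > 0) + 0 else s
}
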