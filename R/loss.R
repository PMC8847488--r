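#' Binary soft hinge loss
#'
#' The smooth upper bound of the margin hinge loss used throughout the
#' package, for pixels, frames and pairs alike:
#' \deqn{l(s, y) = \log(1 + e^{\gamma (m - y s)})}
#' with margin `m` and softness `gamma`. With `m = 0`, `gamma = 1` it reduces
#' exactly to the binary cross-entropy of a logistic link on \eqn{\pm 1}
#' labels, \eqn{-\log \sigma(y s)}.
#'
#' @param s numeric vector/matrix of prediction scores.
#' @param y labels in \{-1, +1\}, same shape as `s` (or length 1, recycled).
#' @param m margin (default 1).
#' @param gamma softness, must be > 0 (default 1).
#' @return elementwise loss, same shape as `s`; strictly positive and
#'   decreasing in `y * s`.
#' @examples
#' soft_hinge(1, 1)            # ln 2 at the margin
#' soft_hinge(0.3, 1, m = 0) + log(plogis(0.3))  # ~0: BCE limit
#' @export
soft_hinge <- function(s, y, m = 1, gamma = 1) {
  check_pm1(y)
  stopifnot(gamma > 0)
  if (length(y) == 1L) y <- rep(y, length(s))
  if (length(s) != length(y)) stop("scores and labels differ in length")
  z <- gamma * (m - y * s)
  out <- log1p(exp(-abs(z))) + pmax(z, 0)  # numerically stable softplus
  if (is.matrix(s)) dim(out) <- dim(s)
  out
}

# derivative of soft_hinge wrt s (labels held fixed)
soft_hinge_grad <- function(s, y, m = 1, gamma = 1) {
  -y * gamma * plogis(gamma * (m - y * s))
}

check_pm1 <- function(y) {
  if (!all(y %in% c(-1, 1))) {
    stop("labels must take values in {-1, +1}")
  }
  invisible(TRUE)
}

#' Supervised frame-classification loss
#'
#' Sum of soft-hinge terms over all scored (embryo, time) frames in a batch,
#' the fully supervised objective used to train the first cascade stage on
#' KID-positive versus KID-negative embryos. The reduction is a sum, not a
#' mean, so learning rates must be set with the batch size in mind.
#'
#' @param scores numeric vector of frame scores.
#' @param labels per-frame labels in \{-1, +1\} (+1 = KIDp embryo). `NA`
#'   (unlabeled embryo) is an error: only KID-labeled frames may enter.
#' @param m,gamma soft hinge parameters.
#' @return scalar loss.
#' @export
supervised_loss <- function(scores, labels, m = 1, gamma = 1) {
  if (anyNA(labels)) stop("unlabeled embryo in supervised batch")
  sum(soft_hinge(scores, labels, m = m, gamma = gamma))
}
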