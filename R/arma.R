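#' First-order ARMA score integration
#'
#' Blends each new frame score into a running embryo score,
#' \deqn{B_t = \alpha A_t + (1 - \alpha) B_{t-1},}
#' the temporal integration used by cascade stages B, D and F. The default
#' coefficient \eqn{\alpha = 0.05} keeps a long score memory. The recursion
#' is initialized with the first raw score (`out[1] = in[1]`), which keeps
#' every output a convex combination of the inputs seen so far; it steps
#' once per available frame (the previous *acquisition*, not a wall-clock
#' tick), so missing frames are simply skipped.
#'
#' @param scores numeric vector of per-frame scores, time-ordered.
#' @param alpha ARMA coefficient in (0, 1]; `alpha = 1` returns the input.
#' @param t_hours optional timestamps; if supplied they must be strictly
#'   increasing (validation only).
#' @return numeric vector of integrated scores, same length.
#' @export
arma_integrate <- function(scores, alpha = 0.05, t_hours = NULL) {
  if (length(scores) == 0) stop("empty score series")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (!is.null(t_hours)) {
    if (length(t_hours) != length(scores)) stop("t_hours length mismatch")
    if (any(diff(t_hours) <= 0)) stop("score series must be time-sorted")
  }
  n <- length(scores)
  if (n == 1L || alpha == 1) return(scores)
  rest <- stats::filter(alpha * scores[-1], 1 - alpha,
                        method = "recursive", init = scores[1])
  c(scores[1], as.numeric(rest))
}

#' End-point embryo score
#'
#' The embryo-level score of an integrated series: the ARMA output at the
#' last available time point.
#'
#' @inheritParams arma_integrate
#' @return scalar score.
#' @export
embryo_score <- function(scores, alpha = 0.05, t_hours = NULL) {
  out <- arma_integrate(scores, alpha = alpha, t_hours = t_hours)
  out[length(out)]
}

#' Integrate a per-embryo score table
#'
#' Applies [arma_integrate()] per embryo to a long score table.
#'
#' @param score_table `data.frame` with columns `embryo_id`, `t_hours`,
#'   `score`.
#' @param alpha ARMA coefficient.
#' @return `data.frame` of the same shape with integrated `score`.
#' @export
integrate_score_table <- function(score_table, alpha = 0.05) {
  stopifnot(all(c("embryo_id", "t_hours", "score") %in% names(score_table)))
  parts <- split(score_table, score_table$embryo_id)
  out <- lapply(parts, function(d) {
    d <- d[order(d$t_hours), , drop = FALSE]
    d$score <- arma_integrate(d$score, alpha = alpha, t_hours = d$t_hours)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
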