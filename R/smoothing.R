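assert_one_hot <- function(m) {
  if (!is.matrix(m)) stop("targets must be a matrix")
  if (!all(m %in% c(0, 1)) || any(abs(rowSums(m) - 1) > 0))
    stop("target rows must be one-hot")
  invisible(m)
}

#' Uniform label smoothing
#'
#' Replaces each one-hot target row by the convex combination
#' `(1 - alpha) * one-hot + alpha / K`: the classical smoothing that pulls
#' every target toward the uniform distribution, improving calibration at
#' the cost of ignoring how the scorers actually disagreed.
#'
#' @param one_hot_targets T x K matrix of one-hot rows.
#' @param alpha Smoothing weight in `(0, 0.5]`. Values above 0.5 would let
#'   the uniform component dominate the target and are rejected.
#' @param K Number of classes (default `ncol(one_hot_targets)`).
#' @return T x K row-stochastic matrix.
#' @examples
#' smooth_uniform(one_hot("W"), alpha = 0.5)   # 0.6 0.1 0.1 0.1 0.1
#' @export
smooth_uniform <- function(one_hot_targets, alpha, K = ncol(one_hot_targets)) {
  assert_one_hot(one_hot_targets)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    stop("uniform smoothing requires alpha in (0, 0.5]")
  one_hot_targets * (1 - alpha) + alpha / K
}

#' Soft-consensus label smoothing
#'
#' Replaces each one-hot consensus target row by the convex combination
#' `(1 - alpha) * one-hot + alpha * soft-consensus row`, injecting the
#' empirical distribution of scorer votes into the training target. At
#' `alpha = 1` the target is the soft-consensus itself; `alpha = 0` is the
#' identity and is accepted only as the documented boundary case.
#'
#' @param one_hot_targets T x K matrix of one-hot rows (the consensus
#'   labels).
#' @param sc A [soft_consensus()] object or a T x K row-stochastic matrix.
#' @param alpha Smoothing weight in `[0, 1]`.
#' @return T x K row-stochastic matrix.
#' @examples
#' rec <- multi_scored_recording(matrix(c("W","W","W","N1","N2"), 1, 5))
#' smooth_soft_consensus(one_hot("W"), soft_consensus(rec), alpha = 0.5)
#' # 0.8 0.1 0.1 0 0
#' @export
smooth_soft_consensus <- function(one_hot_targets, sc, alpha) {
  assert_one_hot(one_hot_targets)
  scm <- if (inherits(sc, "soft_consensus")) sc$matrix else as.matrix(sc)
  if (!identical(dim(one_hot_targets), dim(scm)))
    stop("dimension mismatch: targets are ", nrow(one_hot_targets), "x",
         ncol(one_hot_targets), ", soft-consensus is ", nrow(scm), "x",
         ncol(scm))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("soft-consensus smoothing requires alpha in [0, 1]")
  if (alpha == 0) return(one_hot_targets)
  one_hot_targets * (1 - alpha) + alpha * scm
}

#' Cross-entropy between target distributions and predictions
#'
#' Mean over epochs of `-sum_k target * log(pred)` with natural logarithm;
#' predictions are clamped at 1e-12 before the log so that a zero predicted
#' probability yields a large finite loss rather than infinity.
#'
#' @param target T x K matrix of (possibly smoothed) target rows.
#' @param predicted T x K row-stochastic matrix of model outputs.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(target, predicted) {
  target <- as.matrix(target); predicted <- as.matrix(predicted)
  if (!identical(dim(target), dim(predicted)))
    stop("dimension mismatch between target and predicted matrices")
  mean(-rowSums(target * log(pmax(predicted, 1e-12))))
}
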