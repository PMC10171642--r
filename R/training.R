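# weighted F1 on integer class indices; used for early stopping / alpha search
weighted_f1_idx <- function(pred, truth) {
  cm <- table(factor(truth, levels = seq_len(N_STAGES)),
              factor(pred, levels = seq_len(N_STAGES)))
  tp <- diag(cm); rt <- rowSums(cm); ct <- colSums(cm)
  f1 <- ifelse(rt + ct > 0, 2 * tp / (rt + ct), 0)
  sum(f1 * rt) / length(truth)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

forward_stager <- function(par, x, dropout = 0, training = FALSE) {
  h <- pmax(x %*% par$W1 + rep(par$b1, each = nrow(x)), 0)
  if (training && dropout > 0) {
    keep <- matrix(stats::runif(length(h)) >= dropout, nrow(h))
    h <- h * keep / (1 - dropout)        # inverted dropout
  }
  softmax_rows(h %*% par$W2 + rep(par$b2, each = nrow(x)))
}

#' Fit the reference probabilistic sleep stager
#'
#' A single-hidden-layer feed-forward softmax network trained by mini-batch
#' Adam on the cross-entropy against arbitrary row-stochastic targets —
#' one-hot consensus labels or their smoothed variants. Training stops when
#' the validation weighted F1 has not improved for `patience` consecutive
#' passes over the data; the parameters with the best validation F1 are
#' kept. This is a deliberately minimal architecture-agnostic stand-in for
#' a signal-based stager: it consumes per-epoch feature vectors, and the
#' target-construction machinery under study is independent of it.
#'
#' @param x n x d feature matrix.
#' @param targets n x K row-stochastic target matrix.
#' @param x_val,val_labels Validation features and reference stage tokens
#'   (or class indices) for early stopping.
#' @param hidden Hidden-layer width.
#' @param dropout Hidden-layer dropout rate in `[0, 1)`; also enables
#'   MC-dropout at prediction time.
#' @param lr Adam learning rate (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
#' @param batch_size Mini-batch size.
#' @param max_iterations Maximum passes over the training data.
#' @param patience Early-stopping patience, in validation evaluations
#'   (one per pass); must be below `max_iterations`.
#' @param seed Optional seed for initialisation, shuffling, and dropout.
#' @return Object of class `stager` with the fitted parameters and a
#'   per-pass `trace` (training loss, validation F1).
#' @export
train_stager <- function(x, targets, x_val, val_labels, hidden = 16L,
                         dropout = 0.2, lr = 0.01, batch_size = 512L,
                         max_iterations = 40L, patience = 5L, seed = NULL) {
  x <- as.matrix(x); targets <- as.matrix(targets)
  stopifnot(nrow(x) == nrow(targets), ncol(targets) == N_STAGES,
            dropout >= 0, dropout < 1, patience < max_iterations)
  if (any(abs(rowSums(targets) - 1) > 1e-9))
    stop("targets must be row-stochastic")
  vl <- if (is.numeric(val_labels)) as.integer(val_labels)
        else stage_index(val_labels)
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(x); n <- nrow(x)
  par <- list(W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d),
              b1 = rep(0, hidden),
              W2 = matrix(stats::rnorm(hidden * N_STAGES,
                                       sd = sqrt(2 / hidden)), hidden),
              b2 = rep(0, N_STAGES))
  m <- v <- lapply(par, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; step <- 0L
  best <- list(f1 = -Inf, par = par, pass = 0L)
  trace <- data.frame(pass = integer(), loss = numeric(), val_f1 = numeric())
  wait <- 0L
  for (pass in seq_len(max_iterations)) {
    ord <- sample.int(n)
    loss_acc <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]; yb <- targets[idx, , drop = FALSE]
      h_lin <- xb %*% par$W1 + rep(par$b1, each = length(idx))
      h <- pmax(h_lin, 0)
      if (dropout > 0) {
        keep <- matrix(stats::runif(length(h)) >= dropout, nrow(h))
        h <- h * keep / (1 - dropout)
      }
      p <- softmax_rows(h %*% par$W2 + rep(par$b2, each = length(idx)))
      loss <- mean(-rowSums(yb * log(pmax(p, 1e-12))))
      if (!is.finite(loss))
        stop("training failure: non-finite loss at pass ", pass,
             " (lr = ", lr, "); inspect feature scaling")
      loss_acc <- loss_acc + loss; nb <- nb + 1L
      dz <- (p - yb) / length(idx)                      # softmax + CE gradient
      grad <- list(W2 = crossprod(h, dz), b2 = colSums(dz))
      dh <- dz %*% t(par$W2)
      if (dropout > 0) dh <- dh * keep / (1 - dropout)
      dh <- dh * (h_lin > 0)
      grad$W1 <- crossprod(xb, dh); grad$b1 <- colSums(dh)
      step <- step + 1L
      for (nm in names(par)) {
        m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * grad[[nm]]
        v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * grad[[nm]]^2
        mhat <- m[[nm]] / (1 - b1m^step)
        vhat <- v[[nm]] / (1 - b2m^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    pv <- forward_stager(par, x_val)
    f1 <- weighted_f1_idx(max.col(pv, ties.method = "first"), vl)
    trace <- rbind(trace, data.frame(pass = pass, loss = loss_acc / nb,
                                     val_f1 = f1))
    if (f1 > best$f1 + 1e-9) {
      best <- list(f1 = f1, par = par, pass = pass); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(par = best$par, dropout = dropout, hidden = hidden,
                 best_val_f1 = best$f1, best_pass = best$pass, trace = trace),
            class = "stager")
}

#' @export
print.stager <- function(x, ...) {
  cat(sprintf(paste0("Feed-forward softmax stager: %d -> %d -> %d, dropout ",
                     "%.2f\nBest validation weighted F1 %.4f at pass %d/%d\n"),
              nrow(x$par$W1), x$hidden, N_STAGES, x$dropout, x$best_val_f1,
              x$best_pass, nrow(x$trace)))
  invisible(x)
}

#' Predict stage probabilities
#'
#' `mc_passes = 0` gives one deterministic pass with dropout off;
#' `mc_passes = S > 0` averages S stochastic passes with dropout active
#' (MC-dropout), yielding softer, ensemble-like probabilities. Rows are
#' renormalised to sum to 1.
#'
#' @param object A fitted [train_stager()] model.
#' @param newdata n x d feature matrix.
#' @param mc_passes Number of MC-dropout passes (0 = deterministic).
#' @param ... Unused.
#' @return n x 5 row-stochastic prediction matrix.
#' @export
predict.stager <- function(object, newdata, mc_passes = 0L, ...) {
  x <- as.matrix(newdata)
  if (mc_passes <= 0L) {
    p <- forward_stager(object$par, x)
  } else {
    p <- 0
    for (s in seq_len(mc_passes))
      p <- p + forward_stager(object$par, x, dropout = object$dropout,
                              training = TRUE)
    p <- p / mc_passes
  }
  p / rowSums(p)
}
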