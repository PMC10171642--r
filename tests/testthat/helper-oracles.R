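# Independent brute-force oracles: plain per-epoch loops written against the
# defining formulas, sharing no code with the package internals.

# leave-one-out probabilistic consensus for scorer j (K x T)
oracle_prob_consensus <- function(labels, j) {
  T_ <- nrow(labels)
  z <- matrix(0, N_STAGES, T_)
  valid <- logical(T_)
  for (t in seq_len(T_)) {
    votes <- labels[t, -j]
    votes <- votes[votes %in% SLEEP_STAGES]
    if (length(votes) == 0) next
    counts <- sapply(SLEEP_STAGES, function(s) sum(votes == s))
    z[, t] <- counts / max(counts)
    valid[t] <- TRUE
  }
  list(z = z, valid = valid)
}

oracle_soft_agreement <- function(labels, j) {
  pc <- oracle_prob_consensus(labels, j)
  vals <- c()
  for (t in seq_len(nrow(labels))) {
    lab <- labels[t, j]
    if (lab %in% SLEEP_STAGES && pc$valid[t])
      vals <- c(vals, pc$z[match(lab, SLEEP_STAGES), t])
  }
  mean(vals)
}

oracle_soft_consensus <- function(labels) {
  t(apply(labels, 1L, function(row) {
    votes <- row[row %in% SLEEP_STAGES]
    sapply(SLEEP_STAGES, function(s) sum(votes == s)) / length(votes)
  }))
}

# per-sample-loop ECE
oracle_ece <- function(conf, correct, M) {
  edges_lo <- (seq_len(M) - 1) / M
  edges_hi <- seq_len(M) / M
  total <- 0
  for (m in seq_len(M)) {
    in_bin <- if (m == 1) conf <= edges_hi[1] else
      conf > edges_lo[m] & conf <= edges_hi[m]
    if (!any(in_bin)) next
    total <- total + sum(in_bin) / length(conf) *
      abs(mean(correct[in_bin]) - mean(conf[in_bin]))
  }
  total
}

# per-class loop F1 and accuracy, coded independently of performance()
oracle_f1 <- function(pred, ref) {
  f1 <- numeric(N_STAGES)
  for (k in seq_len(N_STAGES)) {
    s <- SLEEP_STAGES[k]
    tp <- sum(pred == s & ref == s)
    fp <- sum(pred == s & ref != s)
    fn <- sum(pred != s & ref == s)
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  f1
}

# random recording over a reduced or full stage alphabet, with sentinels;
# guarantees >= 1 valid label per epoch
random_recording <- function(T_, J, stages = SLEEP_STAGES, p_nc = 0,
                             p_missing = 0) {
  repeat {
    labels <- matrix(sample(stages, T_ * J, replace = TRUE), T_, J)
    u <- matrix(stats::runif(T_ * J), T_, J)
    labels[u < p_nc] <- "NC"
    labels[u >= p_nc & u < p_nc + p_missing] <- "-"
    if (all(apply(labels, 1L, function(r) any(r %in% SLEEP_STAGES)))) break
  }
  multi_scored_recording(labels, paste0("S", seq_len(J)))
}

# random row-stochastic matrix
random_stochastic <- function(T_, K = N_STAGES) {
  m <- matrix(stats::rexp(T_ * K), T_, K)
  m / rowSums(m)
}
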