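#' Validate a prediction matrix
#'
#' @param m T x K numeric matrix; rows must sum to 1 within `tol`.
#' @param tol Row-sum tolerance.
#' @return The matrix, with stage column names attached.
#' @export
prediction_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (ncol(m) != N_STAGES) stop("prediction matrix must have ", N_STAGES,
                                " columns")
  if (any(m < 0) || any(m > 1)) stop("prediction entries must lie in [0, 1]")
  bad <- which(abs(rowSums(m) - 1) > tol)
  if (length(bad)) stop("prediction row ", bad[1L], " does not sum to 1")
  colnames(m) <- SLEEP_STAGES
  m
}

#' Averaged cosine similarity to the consensus hypnodensity
#'
#' Mean over epochs of the cosine similarity between the soft-consensus row
#' and the predicted probability row. 1 means the model's hypnodensity
#' coincides (up to per-epoch scale) with the scorer group's; 0 means the
#' supports are disjoint. For row-stochastic inputs the value lies in
#' `[0, 1]`.
#'
#' @param sc A [soft_consensus()] object or T x K matrix.
#' @param pred T x K row-stochastic prediction matrix.
#' @return Scalar averaged cosine similarity.
#' @export
acs <- function(sc, pred) {
  scm <- if (inherits(sc, "soft_consensus")) sc$matrix else as.matrix(sc)
  pred <- as.matrix(pred)
  if (!identical(dim(scm), dim(pred)))
    stop("soft-consensus and prediction matrices differ in shape")
  if (nrow(scm) < 1L) stop("ACS needs at least one epoch")
  na <- sqrt(rowSums(scm^2)); nb <- sqrt(rowSums(pred^2))
  zero <- which(na == 0 | nb == 0)
  if (length(zero)) stop("zero-norm row at epoch ", zero[1L])
  mean(rowSums(scm * pred) / (na * nb))
}

#' Expected calibration error
#'
#' Predictions are assigned to `n_bins` equally spaced confidence bins
#' `((m-1)/M, m/M]` by their maximum predicted probability; a confidence of
#' exactly 0 (impossible after argmax over 5 classes) would fall in bin 1.
#' ECE is the bin-size-weighted mean absolute gap between per-bin accuracy
#' and per-bin mean confidence; empty bins contribute 0.
#'
#' @param pred T x K row-stochastic prediction matrix.
#' @param true_labels Length-T stage tokens (or class indices 1..5).
#' @param n_bins Number of bins M (default 10, the calibration-literature
#'   convention).
#' @return Object of class `calibration_report`: `ece`, `mean_confidence`
#'   (over all predictions), and `bins` (data.frame with `lower`, `upper`,
#'   `n`, `accuracy`, `confidence`).
#' @export
ece <- function(pred, true_labels, n_bins = 10L) {
  pred <- prediction_matrix(pred)
  truth <- if (is.numeric(true_labels)) as.integer(true_labels)
           else stage_index(true_labels)
  if (length(truth) != nrow(pred))
    stop("length(true_labels) must equal nrow(pred)")
  if (anyNA(truth)) stop("true labels must be valid sleep stages")
  if (!is.numeric(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  n_bins <- as.integer(n_bins)
  conf <- apply(pred, 1L, max)
  correct <- max.col(pred, ties.method = "first") == truth
  bin <- pmin(n_bins, pmax(1L, ceiling(conf * n_bins - 1e-12)))
  n <- tabulate(bin, nbins = n_bins)
  acc_b <- conf_b <- rep(NA_real_, n_bins)
  occ <- which(n > 0)
  acc_b[occ] <- vapply(occ, function(m) mean(correct[bin == m]), numeric(1))
  conf_b[occ] <- vapply(occ, function(m) mean(conf[bin == m]), numeric(1))
  ece_val <- sum((n[occ] / length(conf)) * abs(acc_b[occ] - conf_b[occ]))
  bins <- data.frame(lower = (seq_len(n_bins) - 1) / n_bins,
                     upper = seq_len(n_bins) / n_bins,
                     n = n, accuracy = acc_b, confidence = conf_b)
  structure(list(ece = ece_val, mean_confidence = mean(conf), bins = bins),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("ECE = %.4f  (mean confidence %.4f, %d predictions, %d bins)\n",
              x$ece, x$mean_confidence, sum(x$bins$n), nrow(x$bins)))
  occ <- x$bins[x$bins$n > 0, ]
  if (nrow(occ)) print(format(occ, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Per-subject staging performance
#'
#' Standard multiclass agreement between a predicted hypnogram and a
#' reference hypnogram: overall accuracy, per-class F1, macro and
#' weighted (by true-class prevalence) F1, and Cohen's kappa. Classes
#' absent from both prediction and reference get F1 = 0 with a warning.
#'
#' @param pred Length-T predicted stage tokens (or a
#'   [consensus_hypnogram][majority_vote]).
#' @param ref Length-T reference stage tokens (or a consensus hypnogram).
#'   Neither side may contain NC/missing.
#' @return Object of class `staging_performance` with fields `accuracy`,
#'   `macro_f1`, `weighted_f1`, `cohens_kappa`, `per_class_f1`,
#'   `confusion` (5 x 5 table, rows = reference).
#' @export
performance <- function(pred, ref) {
  if (inherits(pred, "consensus_hypnogram")) pred <- pred$labels
  if (inherits(ref, "consensus_hypnogram")) ref <- ref$labels
  if (length(pred) != length(ref))
    stop("predicted and reference hypnograms differ in length")
  pi_ <- stage_index(pred); ri <- stage_index(ref)
  if (anyNA(pi_) || anyNA(ri))
    stop("hypnograms must be NC/missing-free valid stages")
  cm <- table(factor(ref, levels = SLEEP_STAGES),
              factor(pred, levels = SLEEP_STAGES))
  n <- length(ref)
  tp <- diag(cm); row_tot <- rowSums(cm); col_tot <- colSums(cm)
  f1 <- ifelse(row_tot + col_tot > 0, 2 * tp / (row_tot + col_tot), 0)
  absent <- row_tot + col_tot == 0
  if (any(absent))
    warning("stage(s) absent from both hypnograms scored F1 = 0: ",
            paste(SLEEP_STAGES[absent], collapse = ", "))
  po <- sum(tp) / n
  pe <- sum(row_tot * col_tot) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)  # both constant, same class
  structure(list(accuracy = po,
                 macro_f1 = mean(f1),
                 weighted_f1 = sum(f1 * row_tot) / n,
                 cohens_kappa = kappa,
                 per_class_f1 = stats::setNames(as.numeric(f1), SLEEP_STAGES),
                 confusion = cm),
            class = "staging_performance")
}

#' @export
print.staging_performance <- function(x, ...) {
  cat(sprintf("Accuracy %.4f | MF1 %.4f | wF1 %.4f | kappa %.4f\n",
              x$accuracy, x$macro_f1, x$weighted_f1, x$cohens_kappa))
  cat("Per-class F1:\n")
  print(round(x$per_class_f1, 4))
  invisible(x)
}

#' Evaluate every scorer against the group consensus
#'
#' Each scorer's hypnogram (restricted to the epochs where that scorer gave
#' a valid label) is scored against the majority-vote consensus, and paired
#' with the scorer's Soft-Agreement and reliability rank.
#'
#' @param rec A [multi_scored_recording] (NC-filtered).
#' @return Object of class `scorer_evaluation`: data.frame `summary` with
#'   one row per scorer (`scorer_id`, `soft_agreement`, `rank`, `accuracy`,
#'   `macro_f1`, `weighted_f1`, `cohens_kappa`, `best`) plus the list of
#'   full [performance()] reports.
#' @export
evaluate_scorers <- function(rec) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  ranking <- rank_scorers(rec)
  consensus <- majority_vote(rec, ranking)
  reports <- lapply(rec$scorer_ids, function(s) {
    lab <- rec$labels[, match(s, rec$scorer_ids)]
    ok <- is_valid_stage(lab)
    performance(lab[ok], consensus$labels[ok])
  })
  names(reports) <- rec$scorer_ids
  sa <- ranking$soft_agreement[match(rec$scorer_ids, ranking$scorer_id)]
  rk <- ranking$rank[match(rec$scorer_ids, ranking$scorer_id)]
  summ <- data.frame(scorer_id = rec$scorer_ids,
                     soft_agreement = sa, rank = rk,
                     accuracy = vapply(reports, `[[`, 0, "accuracy"),
                     macro_f1 = vapply(reports, `[[`, 0, "macro_f1"),
                     weighted_f1 = vapply(reports, `[[`, 0, "weighted_f1"),
                     cohens_kappa = vapply(reports, `[[`, 0, "cohens_kappa"),
                     row.names = NULL, stringsAsFactors = FALSE)
  summ$best <- summ$rank == 1L
  structure(list(summary = summ, reports = reports, consensus = consensus),
            class = "scorer_evaluation")
}

#' @export
print.scorer_evaluation <- function(x, ...) {
  cat("Scorer evaluation against majority-vote consensus:\n")
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 4)
  print(s, row.names = FALSE)
  invisible(x)
}
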