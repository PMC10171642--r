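# epochs x K matrix of valid-vote counts, optionally excluding one scorer
vote_counts <- function(rec, exclude = NULL) {
  keep <- seq_along(rec$scorer_ids)
  if (!is.null(exclude)) {
    j <- match(exclude, rec$scorer_ids)
    if (is.na(j)) stop("unknown scorer id: ", exclude)
    keep <- keep[-j]
  }
  T_ <- n_epochs(rec)
  counts <- matrix(0L, nrow = T_, ncol = N_STAGES,
                   dimnames = list(NULL, SLEEP_STAGES))
  for (j in keep) {
    idx <- stage_index(rec$labels[, j])
    ok <- which(!is.na(idx))
    counts[cbind(ok, idx[ok])] <- counts[cbind(ok, idx[ok])] + 1L
  }
  counts
}

#' Leave-one-out probabilistic consensus
#'
#' For each epoch, counts the valid votes of the J-1 scorers other than
#' `excluded` and divides by the per-epoch maximum count, so the stage(s)
#' holding the majority — or involved in a tie for it — score exactly 1 and
#' every other voted stage scores its vote fraction of the winner's.
#'
#' @param rec A [multi_scored_recording] with J >= 2 scorers.
#' @param excluded Scorer id left out of the vote.
#' @return Object of class `probabilistic_consensus`: `matrix` (K x T, each
#'   valid column with max exactly 1), `valid` (length-T logical, `FALSE`
#'   where the remaining scorers cast no valid vote), `excluded_scorer`.
#' @seealso [soft_agreement()], which evaluates this consensus at a scorer's
#'   own labels.
#' @export
probabilistic_consensus <- function(rec, excluded) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  if (length(rec$scorer_ids) < 2L)
    stop("probabilistic consensus needs J >= 2 scorers")
  counts <- vote_counts(rec, exclude = excluded)
  mx <- apply(counts, 1L, max)
  valid <- mx > 0
  z <- counts
  z[valid, ] <- counts[valid, , drop = FALSE] / mx[valid]
  structure(list(matrix = t(z), valid = valid, excluded_scorer = excluded),
            class = "probabilistic_consensus")
}

#' Soft-Agreement reliability of one scorer
#'
#' The leave-one-out probabilistic consensus evaluated at the scorer's own
#' labels, averaged over the epochs where both that scorer and at least one
#' other scorer gave a valid annotation. 1 means the scorer always sits in
#' the majority (or a tie for it); 0 means the scorer never matches any
#' stage voted by the others.
#'
#' @inheritParams probabilistic_consensus
#' @param scorer Scorer id to evaluate.
#' @return A number in `[0, 1]`.
#' @export
soft_agreement <- function(rec, scorer) {
  z <- probabilistic_consensus(rec, excluded = scorer)
  idx <- stage_index(rec$labels[, match(scorer, rec$scorer_ids)])
  contrib <- which(!is.na(idx) & z$valid)
  if (length(contrib) == 0L)
    stop("soft_agreement undefined: scorer '", scorer,
         "' has no epoch with both its own and another valid annotation")
  mean(z$matrix[cbind(idx[contrib], contrib)])
}

#' Rank scorers by Soft-Agreement
#'
#' Scorers sorted by Soft-Agreement, most reliable first; ties keep the
#' input scorer order (stable sort), making the ranking deterministic.
#'
#' @inheritParams probabilistic_consensus
#' @return A `data.frame` of class `scorer_reliability` with columns
#'   `scorer_id`, `soft_agreement`, `rank` (1 = most reliable).
#' @export
rank_scorers <- function(rec) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  sa <- vapply(rec$scorer_ids, function(s) soft_agreement(rec, s), numeric(1))
  ord <- order(-sa)                      # order() is stable: ties keep input order
  out <- data.frame(scorer_id = rec$scorer_ids[ord],
                    soft_agreement = unname(sa[ord]),
                    rank = seq_along(sa), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("scorer_reliability", "data.frame")
  out
}

#' Soft-consensus distribution of scorer votes
#'
#' Per-epoch empirical distribution over the five stages: occurrences of
#' each stage divided by the number of valid observations M at that epoch.
#' NC and missing annotations are excluded from both numerator and
#' denominator, so M varies per epoch in partially annotated data. Doubles
#' as the ground-truth hypnodensity of the scorer group.
#'
#' @inheritParams probabilistic_consensus
#' @return Object of class `soft_consensus`: `matrix` (T x K, rows summing
#'   to 1) and `observation_count` (length-T integer M).
#' @examples
#' rec <- multi_scored_recording(matrix(c("W","W","W","N1","N2"), 1, 5))
#' soft_consensus(rec)$matrix     # 0.6 0.2 0.2 0 0
#' @export
soft_consensus <- function(rec) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  counts <- vote_counts(rec)
  m <- rowSums(counts)
  if (any(m == 0))
    stop("epoch ", which(m == 0)[1L],
         " has no valid annotation; run filter_nc_epochs() first")
  structure(list(matrix = counts / m, observation_count = as.integer(m)),
            class = "soft_consensus")
}

#' @export
print.soft_consensus <- function(x, ...) {
  cat(sprintf("Soft-consensus: %d epochs, observations per epoch %d-%d\n",
              nrow(x$matrix), min(x$observation_count),
              max(x$observation_count)))
  cat("Mean stage probabilities:\n")
  print(round(colMeans(x$matrix), 4))
  invisible(x)
}

#' @export
plot.soft_consensus <- function(x, ...) {
  plot(build_hypnodensity(x$matrix, source = "soft_consensus"), ...)
}

#' Majority-vote consensus hypnogram
#'
#' Per-epoch argmax of the soft-consensus. Where two or more stages tie at
#' the maximum vote share, the label comes from the most reliable scorer
#' (highest Soft-Agreement) whose own label is one of the tied stages,
#' descending the reliability ranking past scorers with NC/missing labels
#' or labels outside the tie.
#'
#' @inheritParams probabilistic_consensus
#' @param ranking Optional precomputed [rank_scorers()] result.
#' @return Object of class `consensus_hypnogram`: `labels` (length-T stage
#'   tokens), `tie_flags` (length-T logical), `tiebreak_scorer` (the
#'   top-ranked scorer id).
#' @export
majority_vote <- function(rec, ranking = rank_scorers(rec)) {
  sc <- soft_consensus(rec)
  mx <- apply(sc$matrix, 1L, max)
  is_max <- sc$matrix >= mx - 1e-12
  ties <- rowSums(is_max) > 1L
  labels <- argmax_stages(sc$matrix)
  ranked_cols <- match(ranking$scorer_id, rec$scorer_ids)
  for (t in which(ties)) {
    tied <- SLEEP_STAGES[is_max[t, ]]
    for (j in ranked_cols) {
      lab <- rec$labels[t, j]
      if (lab %in% tied) { labels[t] <- lab; break }
    }
  }
  structure(list(labels = labels, tie_flags = ties,
                 tiebreak_scorer = ranking$scorer_id[1L]),
            class = "consensus_hypnogram")
}

#' @export
print.consensus_hypnogram <- function(x, ...) {
  cat(sprintf("Consensus hypnogram: %d epochs, %d tie epochs (tie-break: %s)\n",
              length(x$labels), sum(x$tie_flags), x$tiebreak_scorer))
  print(table(factor(x$labels, levels = SLEEP_STAGES)))
  invisible(x)
}
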