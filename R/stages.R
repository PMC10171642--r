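#' softstage: multi-scorer sleep-stage fusion and calibration
#'
#' Tools for multiply-annotated hypnograms: Soft-Agreement scorer-reliability
#' ranking, majority-vote and soft-consensus construction, label smoothing
#' with the empirical scorer distribution, hypnodensity graphs, and an
#' evaluation suite (per-subject performance, expected calibration error,
#' averaged cosine similarity). A seeded multi-scored-database simulator and
#' a minimal probabilistic reference stager support end-to-end experiments.
#'
#' @keywords internal
"_PACKAGE"

#' AASM sleep-stage alphabet
#'
#' The five scoreable stages, in the fixed order used for every matrix and
#' one-hot encoding in this package: W (wake), N1, N2, N3 (non-REM depths),
#' R (REM). Column/row k of any K-wide object always refers to
#' `SLEEP_STAGES[k]`.
#'
#' @format Character vector of length 5.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "R")

#' @rdname SLEEP_STAGES
#' @export
N_STAGES <- 5L

# Sentinel tokens: NC = scored as "not classified", "-" = no annotation.
# Both are excluded from every vote count; they differ only in provenance.
TOKEN_NC <- "NC"
TOKEN_MISSING <- "-"
VALID_TOKENS <- c(SLEEP_STAGES, TOKEN_NC, TOKEN_MISSING)

#' Map stage labels to class indices
#'
#' @param labels Character vector of stage tokens.
#' @return Integer vector of indices into [SLEEP_STAGES] (1..5); `NA` for
#'   NC/MISSING or unknown tokens.
#' @export
stage_index <- function(labels) match(labels, SLEEP_STAGES)

#' @rdname stage_index
#' @param idx Integer vector of class indices (1..5).
#' @export
stage_label <- function(idx) SLEEP_STAGES[idx]

is_valid_stage <- function(labels) labels %in% SLEEP_STAGES

#' One-hot encode a stage-label vector
#'
#' @param labels Character vector of stage tokens (NC/MISSING allowed; their
#'   rows are all zero).
#' @return A `length(labels)` x 5 matrix in `{0,1}`; valid rows sum to 1.
#' @export
one_hot <- function(labels) {
  idx <- stage_index(labels)
  m <- matrix(0, nrow = length(labels), ncol = N_STAGES,
              dimnames = list(NULL, SLEEP_STAGES))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a row-stochastic or one-hot matrix to stage labels
#'
#' Per-row argmax; ties resolve to the first (lowest-index) stage.
#'
#' @param m Numeric matrix with 5 columns in stage order.
#' @return Character vector of stage tokens.
#' @export
argmax_stages <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == N_STAGES)
  SLEEP_STAGES[max.col(m, ties.method = "first")]
}
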