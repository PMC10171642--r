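#' Construct a multi-scored recording
#'
#' Container for one night scored independently by several physicians: a
#' T x J character matrix with one 30-s epoch per row and one scorer per
#' column, over the tokens W, N1, N2, N3, R, NC (scored "not classified")
#' and "-" (no annotation from that scorer).
#'
#' @param labels Character matrix (epochs x scorers) of tokens, or a
#'   data.frame coercible to one.
#' @param scorer_ids Character vector of J >= 2 unique scorer identifiers;
#'   defaults to the column names of `labels`.
#' @param recording_id Identifier for the recording.
#' @param epoch_duration_s Epoch length in seconds (carried as metadata; all
#'   computations are epoch-wise).
#' @return An object of class `multi_scored_recording`.
#' @examples
#' rec <- multi_scored_recording(
#'   cbind(A = c("W", "N1", "N2"), B = c("W", "N1", "N1")))
#' rec
#' @export
multi_scored_recording <- function(labels, scorer_ids = colnames(labels),
                                   recording_id = "recording",
                                   epoch_duration_s = 30) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "character"
  if (is.null(scorer_ids)) scorer_ids <- paste0("scorer_", seq_len(ncol(labels)))
  if (ncol(labels) < 2L) stop("a multi-scored recording needs J >= 2 scorers")
  if (nrow(labels) < 1L) stop("a multi-scored recording needs T >= 1 epochs")
  if (anyDuplicated(scorer_ids)) stop("scorer ids must be unique")
  if (length(scorer_ids) != ncol(labels))
    stop("length(scorer_ids) must equal ncol(labels)")
  bad <- matrix(!(labels %in% VALID_TOKENS), nrow(labels))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown label token '%s' at epoch %d, scorer '%s'",
                 labels[w[1L], w[2L]], w[1L], scorer_ids[w[2L]]))
  }
  if (!is.numeric(epoch_duration_s) || epoch_duration_s <= 0)
    stop("epoch_duration_s must be positive")
  dimnames(labels) <- list(NULL, scorer_ids)
  structure(list(recording_id = recording_id, scorer_ids = scorer_ids,
                 labels = labels, epoch_duration_s = epoch_duration_s),
            class = "multi_scored_recording")
}

#' @export
print.multi_scored_recording <- function(x, ...) {
  cat(sprintf("Multi-scored recording '%s': %d epochs (%gs) x %d scorers\n",
              x$recording_id, nrow(x$labels), x$epoch_duration_s,
              length(x$scorer_ids)))
  cat("Scorers:", paste(x$scorer_ids, collapse = ", "), "\n")
  tab <- table(factor(x$labels, levels = VALID_TOKENS))
  cat("Label counts:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.multi_scored_recording <- function(object, ...) {
  valid <- matrix(is_valid_stage(object$labels), nrow = nrow(object$labels))
  cat(sprintf("Recording '%s': T = %d, J = %d\n", object$recording_id,
              nrow(object$labels), length(object$scorer_ids)))
  cat(sprintf("Epochs with all scorers NC/missing: %d\n",
              sum(rowSums(valid) == 0)))
  cat("Valid annotations per scorer:\n")
  print(stats::setNames(colSums(valid), object$scorer_ids))
  invisible(object)
}

# epochs x scorers logical matrix of scoreable-stage cells
valid_mask <- function(rec) {
  matrix(is_valid_stage(rec$labels), nrow = nrow(rec$labels))
}

n_epochs <- function(rec) nrow(rec$labels)

#' Read a multi-scorer annotation table
#'
#' Delimited text (comma or tab, autodetected from the header line) with
#' header `epoch,<scorer_1>,...,<scorer_J>` and one row per 30-s epoch.
#' Row order is authoritative; the `epoch` column is ignored on read.
#'
#' @param path Path to the file.
#' @param recording_id Identifier; defaults to the file name.
#' @return A [multi_scored_recording].
#' @export
read_annotations <- function(path, recording_id = basename(path)) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("annotation file needs a header and >= 1 epoch row")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(cells[[1L]])
  if (length(header) < 3L || tolower(header[1L]) != "epoch")
    stop("header must be 'epoch,<scorer_1>,...,<scorer_J>' with J >= 2")
  scorer_ids <- header[-1L]
  ncol_exp <- length(header)
  body <- cells[-1L]
  lens <- lengths(body)
  if (any(lens != ncol_exp))
    stop(sprintf("ragged row %d: expected %d fields, got %d",
                 which(lens != ncol_exp)[1L], ncol_exp,
                 lens[lens != ncol_exp][1L]))
  labels <- t(vapply(body, function(r) trimws(r[-1L]), character(ncol_exp - 1L)))
  bad <- matrix(!(labels %in% VALID_TOKENS), nrow(labels))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown label token '%s' at data row %d, column '%s'",
                 labels[w[1L], w[2L]], w[1L], scorer_ids[w[2L]]))
  }
  multi_scored_recording(labels, scorer_ids, recording_id = recording_id)
}

#' Write a multi-scorer annotation table
#'
#' Inverse of [read_annotations()]; the epoch column is written 0-based.
#'
#' @param rec A [multi_scored_recording].
#' @param path Output path.
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_annotations <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "multi_scored_recording"))
  header <- paste(c("epoch", rec$scorer_ids), collapse = sep)
  rows <- apply(rec$labels, 1L, paste, collapse = sep)
  writeLines(c(header, paste(seq_len(n_epochs(rec)) - 1L, rows, sep = sep)),
             path)
  invisible(path)
}

#' Read / write a single hypnogram
#'
#' Plain-text format: one stage token per line.
#'
#' @param path File path.
#' @return Character vector of stage tokens.
#' @export
read_hypnogram <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  bad <- !(x %in% VALID_TOKENS)
  if (any(bad))
    stop(sprintf("unknown stage token '%s' at line %d", x[bad][1L],
                 which(bad)[1L]))
  x
}

#' @rdname read_hypnogram
#' @param labels Character vector of stage tokens.
#' @export
write_hypnogram <- function(labels, path) {
  writeLines(labels, path)
  invisible(path)
}

#' Remove epochs with no valid annotation
#'
#' Epochs where every scorer gave NC or no annotation carry no information
#' and are dropped; epochs with at least one scoreable label are kept
#' unchanged (partial annotations count with reduced per-epoch observation
#' totals downstream). Idempotent.
#'
#' @param rec A [multi_scored_recording].
#' @return List with `recording` (the filtered recording) and
#'   `removed_indices` (1-based epoch indices in the original recording).
#' @export
filter_nc_epochs <- function(rec) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  keep <- rowSums(valid_mask(rec)) > 0
  removed <- which(!keep)
  if (length(removed) == 0L)
    return(list(recording = rec, removed_indices = integer(0)))
  if (!any(keep))
    warning("all epochs removed: no epoch has a valid annotation")
  out <- rec
  out$labels <- rec$labels[keep, , drop = FALSE]
  list(recording = out, removed_indices = removed)
}

#' One-hot annotation matrix for one scorer
#'
#' @param rec A [multi_scored_recording].
#' @param scorer A scorer id.
#' @return List of class `one_hot_annotations` with `matrix` (K x T in
#'   `{0,1}`; invalid columns all-zero) and `valid` (length-T logical,
#'   `FALSE` where the scorer gave NC or no annotation).
#' @export
to_one_hot <- function(rec, scorer) {
  stopifnot(inherits(rec, "multi_scored_recording"))
  j <- match(scorer, rec$scorer_ids)
  if (is.na(j)) stop("unknown scorer id: ", scorer)
  lab <- rec$labels[, j]
  structure(list(matrix = t(one_hot(lab)), valid = is_valid_stage(lab),
                 scorer_id = scorer),
            class = "one_hot_annotations")
}
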