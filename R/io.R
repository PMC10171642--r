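#' Read / write probability matrices
#'
#' Delimited text with header `epoch,pW,pN1,pN2,pN3,pR` (plus `M`, the
#' per-epoch observation count, for soft-consensus files). One row per
#' 30-s epoch; comma or tab autodetected on read.
#'
#' @param path File path.
#' @return For `read_probabilities`: a list with `matrix` (T x 5) and `M`
#'   (integer vector or `NULL`).
#' @export
read_probabilities <- function(path) {
  if (!file.exists(path)) stop("probability file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  need <- paste0("p", SLEEP_STAGES)
  if (!all(need %in% names(df)))
    stop("probability file must have columns ", paste(need, collapse = ","))
  m <- as.matrix(df[, need])
  colnames(m) <- SLEEP_STAGES
  list(matrix = m, M = if ("M" %in% names(df)) as.integer(df$M) else NULL)
}

#' @rdname read_probabilities
#' @param m T x 5 probability matrix, or a [soft_consensus()] object (its
#'   observation counts are written as an `M` column).
#' @param sep Field separator.
#' @export
write_probabilities <- function(m, path, sep = ",") {
  M <- NULL
  if (inherits(m, "soft_consensus")) { M <- m$observation_count; m <- m$matrix }
  df <- as.data.frame(m)
  names(df) <- paste0("p", SLEEP_STAGES)
  df <- cbind(epoch = seq_len(nrow(df)) - 1L, df)
  if (!is.null(M)) df$M <- M
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# provenance sidecar: every artifact-producing CLI run records what made it
write_provenance <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
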