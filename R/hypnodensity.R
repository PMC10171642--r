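#' Build a hypnodensity series
#'
#' A hypnodensity is the per-epoch probability distribution over the five
#' sleep stages across a night — either a model's predicted probabilities or
#' the scorer group's soft-consensus. Rows off stochastic by more than 1e-6
#' are rejected (with the offending epoch); rows off by at most 1e-6 are
#' renormalised.
#'
#' @param matrix T x K matrix, or a [soft_consensus()] object.
#' @param source `"model"` or `"soft_consensus"`.
#' @param epoch_duration_s Epoch length in seconds (drives the time axis).
#' @return Object of class `hypnodensity`.
#' @export
build_hypnodensity <- function(matrix, source = c("model", "soft_consensus"),
                               epoch_duration_s = 30) {
  source <- match.arg(source)
  if (inherits(matrix, "soft_consensus")) {
    source <- "soft_consensus"
    matrix <- matrix$matrix
  }
  m <- as.matrix(matrix)
  if (ncol(m) != N_STAGES) stop("hypnodensity needs ", N_STAGES, " columns")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad))
    stop("row ", bad[1L], " sums to ", format(rs[bad[1L]]),
         ", not 1: not a probability distribution")
  off <- abs(rs - 1) > 1e-12
  if (any(off)) m[off, ] <- m[off, , drop = FALSE] / rs[off]
  colnames(m) <- SLEEP_STAGES
  structure(list(probabilities = m, epoch_duration_s = epoch_duration_s,
                 source = source),
            class = "hypnodensity")
}

#' @export
print.hypnodensity <- function(x, ...) {
  cat(sprintf("Hypnodensity (%s): %d epochs of %gs (%.1f min)\n", x$source,
              nrow(x$probabilities), x$epoch_duration_s,
              nrow(x$probabilities) * x$epoch_duration_s / 60))
  invisible(x)
}

# stage palette, W -> R stacked bottom to top
stage_palette <- function() {
  c(W = "#d9d9d9", N1 = "#fdd49e", N2 = "#74a9cf", N3 = "#045a8d",
    R = "#c51b7d")
}

#' Plot a hypnodensity graph
#'
#' Stacked bands of cumulative stage probabilities against time in minutes,
#' W at the bottom through R at the top; optionally with an aligned discrete
#' hypnogram panel above and an ACS value in the title.
#'
#' @param x A [build_hypnodensity()] series.
#' @param hypnogram Optional length-T stage tokens (or a consensus
#'   hypnogram) drawn as a step trace in a top panel.
#' @param acs_label Optional ACS value appended to the title.
#' @param palette Named stage colours.
#' @param main Title.
#' @param ... Unused.
#' @export
plot.hypnodensity <- function(x, hypnogram = NULL, acs_label = NULL,
                              palette = stage_palette(),
                              main = sprintf("Hypnodensity (%s)", x$source),
                              ...) {
  p <- x$probabilities
  tmin <- (seq_len(nrow(p)) - 0.5) * x$epoch_duration_s / 60
  if (!is.null(acs_label))
    main <- sprintf("%s  ACS = %.3f", main, acs_label)
  if (!is.null(hypnogram)) {
    if (inherits(hypnogram, "consensus_hypnogram")) hypnogram <- hypnogram$labels
    op <- graphics::par(mfrow = c(2, 1), mar = c(1.5, 4, 2.5, 1))
    on.exit(graphics::par(op), add = TRUE)
    graphics::plot(tmin, stage_index(hypnogram), type = "s", ylim = c(5.2, 0.8),
                   yaxt = "n", xlab = "", ylab = "stage", main = main)
    graphics::axis(2, at = 1:5, labels = SLEEP_STAGES, las = 1)
    main <- ""
    graphics::par(mar = c(4, 4, 1, 1))
  }
  cum <- t(apply(p, 1L, cumsum))
  graphics::plot(NA, xlim = range(0, tmin + x$epoch_duration_s / 120),
                 ylim = c(0, 1), xlab = "time (min)",
                 ylab = "cumulative probability", main = main)
  lower <- rep(0, nrow(p))
  for (k in seq_len(N_STAGES)) {
    graphics::polygon(c(tmin, rev(tmin)), c(cum[, k], rev(lower)),
                      col = palette[SLEEP_STAGES[k]], border = NA)
    lower <- cum[, k]
  }
  graphics::legend("topright", legend = SLEEP_STAGES, fill = palette,
                   bty = "n", cex = 0.8, horiz = TRUE)
  invisible(x)
}

#' Render a hypnodensity graph to an image file
#'
#' @param series A [build_hypnodensity()] series.
#' @param path Output path ending in `.png` or `.svg`.
#' @param hypnogram,acs_label Passed to [plot.hypnodensity()].
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return The path, invisibly.
#' @export
render_hypnodensity <- function(series, path, hypnogram = NULL,
                                acs_label = NULL, width = 900, height = 400) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width, height = height)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width / 96, height = height / 96)
  } else stop("unsupported output format: .", ext, " (use .png or .svg)")
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(series, hypnogram = hypnogram, acs_label = acs_label)
  invisible(path)
}
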