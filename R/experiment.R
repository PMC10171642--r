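#' Run the base / uniform-smoothing / soft-consensus-smoothing experiment
#'
#' Subject-level k-fold cross-validation on a synthetic multi-scored
#' database: fold f supplies the test subjects, the next fold the
#' validation subjects, the rest the training subjects. For each smoothing
#' mode the smoothing weight alpha is grid-searched on validation (one
#' alpha retained per mode, by mean validation weighted F1 across folds, or
#' mean validation ACS with `select_by = "acs"`); `"base"` trains on the
#' raw one-hot consensus labels. Training targets are the majority-vote
#' consensus of each training subject's scorer panel — never the hidden
#' simulation truth — smoothed per mode. Test predictions, pooled per
#' subject across folds, are scored against the majority-vote consensus
#' (accuracy, F1, kappa), calibrated (ECE, mean confidence), and compared
#' to the soft-consensus hypnodensity (ACS), with a paired two-sided
#' Wilcoxon signed-rank test on per-subject ACS against the base model.
#'
#' @param dataset A [simulate_dataset()] result (or an equivalent list of
#'   subjects with `recording` and `features`).
#' @param folds Number of CV folds (>= 3, so that test, validation and
#'   training subjects are disjoint).
#' @param modes Subset of `c("base", "uniform", "soft_consensus")`.
#' @param alpha_grid_uniform,alpha_grid_sc Candidate smoothing weights.
#' @param select_by Validation criterion for choosing alpha.
#' @param mc_passes MC-dropout passes at test time (0 = deterministic).
#' @param n_bins ECE bin count.
#' @param seed Seed governing fold assignment and all training runs.
#' @param ... Passed to [train_stager()] (hidden, lr, batch_size, ...).
#' @return Object of class `staging_experiment`: per mode a list with
#'   `alpha`, `per_subject` (data.frame of accuracy, macro/weighted F1,
#'   kappa, ECE, mean confidence, ACS), `aggregate` (mean and sd of each),
#'   `predictions` (per-subject matrices), `acs_vs_base_p` (Wilcoxon
#'   p-value, `NA` for base); plus `fold_assignment` and `seed`.
#' @export
run_experiment <- function(dataset, folds = 4L,
                           modes = c("base", "uniform", "soft_consensus"),
                           alpha_grid_uniform = seq(0.1, 0.5, by = 0.1),
                           alpha_grid_sc = seq(0.1, 1.0, by = 0.1),
                           select_by = c("f1", "acs"),
                           mc_passes = 0L, n_bins = 10L, seed = 1L, ...) {
  select_by <- match.arg(select_by)
  modes <- match.arg(modes, c("base", "uniform", "soft_consensus"),
                     several.ok = TRUE)
  subjects <- dataset$subjects
  ns <- length(subjects)
  if (folds < 3L) stop("need folds >= 3 for disjoint train/validation/test")
  if (ns < folds) stop("fewer subjects (", ns, ") than folds (", folds, ")")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), ns))

  # per-subject references, computed once
  prep <- lapply(subjects, function(s) {
    cons <- majority_vote(s$recording)
    list(features = s$features,
         consensus_idx = stage_index(cons$labels),
         onehot = one_hot(cons$labels),
         sc = soft_consensus(s$recording)$matrix)
  })
  stack <- function(idx, what) do.call(rbind, lapply(prep[idx], `[[`, what))
  stack_vec <- function(idx, what)
    unlist(lapply(prep[idx], `[[`, what), use.names = FALSE)

  settings <- list()
  for (mode in modes) {
    grid <- switch(mode, base = NA_real_, uniform = alpha_grid_uniform,
                   soft_consensus = alpha_grid_sc)
    for (a in grid) settings[[length(settings) + 1L]] <-
        list(mode = mode, alpha = a)
  }

  run_id <- 0L
  results <- lapply(settings, function(st) {
    val_scores <- numeric(folds)
    preds <- vector("list", ns)
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      val_idx <- which(fold_of == (f %% folds) + 1L)
      train_idx <- setdiff(seq_len(ns), c(test_idx, val_idx))
      x_tr <- stack(train_idx, "features")
      y_tr <- stack(train_idx, "onehot")
      if (st$mode == "uniform") {
        y_tr <- smooth_uniform(y_tr, st$alpha)
      } else if (st$mode == "soft_consensus") {
        y_tr <- smooth_soft_consensus(y_tr, stack(train_idx, "sc"), st$alpha)
      }
      run_id <<- run_id + 1L
      fit <- train_stager(x_tr, y_tr, stack(val_idx, "features"),
                          stack_vec(val_idx, "consensus_idx"),
                          seed = (seed %% 10000L) * 100000L + run_id, ...)
      pv <- predict(fit, stack(val_idx, "features"), mc_passes = mc_passes)
      val_scores[f] <- if (select_by == "f1") {
        weighted_f1_idx(max.col(pv, ties.method = "first"),
                        stack_vec(val_idx, "consensus_idx"))
      } else {
        acs(stack(val_idx, "sc"), pv)
      }
      for (i in test_idx)
        preds[[i]] <- predict(fit, prep[[i]]$features, mc_passes = mc_passes)
    }
    list(setting = st, val_score = mean(val_scores), predictions = preds)
  })

  score_mode <- function(preds) {
    per <- do.call(rbind, lapply(seq_len(ns), function(i) {
      p <- prep[[i]]
      pm <- preds[[i]]
      ref <- SLEEP_STAGES[p$consensus_idx]
      perf <- suppressWarnings(performance(argmax_stages(pm), ref))
      cal <- ece(pm, ref, n_bins = n_bins)
      data.frame(subject = names(subjects)[i], accuracy = perf$accuracy,
                 macro_f1 = perf$macro_f1, weighted_f1 = perf$weighted_f1,
                 cohens_kappa = perf$cohens_kappa, ece = cal$ece,
                 mean_confidence = cal$mean_confidence,
                 acs = acs(p$sc, pm), stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
    per
  }

  out <- list()
  for (mode in modes) {
    cand <- Filter(function(r) r$setting$mode == mode, results)
    best <- cand[[which.max(vapply(cand, `[[`, 0, "val_score"))]]
    per <- score_mode(best$predictions)
    num <- per[, setdiff(names(per), "subject")]
    out[[mode]] <- list(alpha = best$setting$alpha,
                        val_score = best$val_score,
                        per_subject = per,
                        aggregate = list(mean = colMeans(num),
                                         sd = apply(num, 2L, stats::sd)),
                        predictions = best$predictions)
  }
  if ("base" %in% modes) {
    for (mode in setdiff(modes, "base")) {
      out[[mode]]$acs_vs_base_p <- stats::wilcox.test(
        out[[mode]]$per_subject$acs, out[["base"]]$per_subject$acs,
        paired = TRUE, exact = FALSE)$p.value
    }
    out[["base"]]$acs_vs_base_p <- NA_real_
  }
  structure(list(models = out, fold_assignment = fold_of, folds = folds,
                 modes = modes, select_by = select_by, seed = seed),
            class = "staging_experiment")
}

#' @export
print.staging_experiment <- function(x, ...) {
  cat(sprintf("Staging experiment: %d-fold CV, seed %d, alpha selected by %s\n",
              x$folds, x$seed, x$select_by))
  for (mode in x$modes) {
    m <- x$models[[mode]]
    ag <- m$aggregate$mean
    cat(sprintf(paste0("%-14s alpha=%-4s Acc %.3f  MF1 %.3f  wF1 %.3f  ",
                       "kappa %.3f  ECE %.3f  conf %.3f  ACS %.3f+-%.3f"),
                mode, ifelse(is.na(m$alpha), "-", m$alpha), ag["accuracy"],
                ag["macro_f1"], ag["weighted_f1"], ag["cohens_kappa"],
                ag["ece"], ag["mean_confidence"], ag["acs"],
                x$models[[mode]]$aggregate$sd["acs"]))
    if (!is.null(m$acs_vs_base_p) && !is.na(m$acs_vs_base_p))
      cat(sprintf("  (ACS vs base: p = %.4f)", m$acs_vs_base_p))
    cat("\n")
  }
  invisible(x)
}
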