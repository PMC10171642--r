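#' Reference sleep-stage marginals
#'
#' Whole-night stage prevalences typical of a healthy-adult multi-scored
#' database (W 12.5%, N1 5.9%, N2 48.7%, N3 14.0%, R 19.0%), used as the
#' stationary distribution of the default transition matrix.
#'
#' @format Named numeric vector over the five stages, summing to 1.
#' @export
DEFAULT_STAGE_MARGINALS <- c(W = 0.125, N1 = 0.059, N2 = 0.487,
                             N3 = 0.140, R = 0.190)

# Symmetric stage-affinity weights: which transitions are physiologically
# common (W<->N1, N1<->N2, N2<->N3, N2<->R) vs rare (W<->N3, N1<->N3, N3<->R).
default_stage_affinity <- function() {
  s <- matrix(0, N_STAGES, N_STAGES, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  s["W", "N1"] <- 4;   s["W", "N2"] <- 0.5; s["W", "N3"] <- 0.1; s["W", "R"] <- 0.5
  s["N1", "N2"] <- 3;  s["N1", "N3"] <- 0.1; s["N1", "R"] <- 1
  s["N2", "N3"] <- 1.5; s["N2", "R"] <- 1
  s["N3", "R"] <- 0.3
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  s
}

#' Stage-transition matrix with prescribed stationary distribution
#'
#' Builds a reversible first-order Markov kernel over the five stages whose
#' stationary distribution equals `marginals` exactly: off-diagonal
#' `P[i, j] = mixing * marginals[j] * affinity[i, j]` with symmetric
#' `affinity`, diagonal set to the row remainder. Detailed balance
#' `pi_i P[i,j] = pi_j P[j,i]` holds by construction, so `marginals` is
#' stationary regardless of `mixing` or `affinity`. The default affinity
#' favours the transitions common in real hypnograms and gives epoch-scale
#' self-transition probabilities of 0.57 (N1, the least persistent stage)
#' to 0.88.
#'
#' @param marginals Target stationary distribution (length 5, sums to 1).
#' @param mixing Overall transition rate scale in (0, 1); larger means
#'   shorter stage bouts.
#' @param affinity Symmetric 5 x 5 nonnegative weight matrix.
#' @return 5 x 5 row-stochastic matrix.
#' @export
sleep_transition_matrix <- function(marginals = DEFAULT_STAGE_MARGINALS,
                                    mixing = 0.2,
                                    affinity = default_stage_affinity()) {
  stopifnot(length(marginals) == N_STAGES, abs(sum(marginals) - 1) < 0.01,
            all(marginals > 0), isTRUE(all.equal(affinity, t(affinity))))
  marginals <- marginals / sum(marginals)  # printed prevalences may round to 100.1%
  P <- mixing * sweep(affinity, 2L, marginals, `*`)
  diag(P) <- 0
  d <- 1 - rowSums(P)
  if (any(d < 0))
    stop("mixing too large: negative self-transition probability")
  diag(P) <- d
  dimnames(P) <- list(SLEEP_STAGES, SLEEP_STAGES)
  P
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the kernel for eigenvalue 1, normalised to sum to 1.
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(P))
}

# Default scorer error kernel: when a scorer errs on true stage s, the wrong
# label is drawn from row s. Errors concentrate on the adjacent-stage
# confusions that dominate human inter-scorer disagreement.
default_confusion_template <- function() {
  tm <- matrix(0, N_STAGES, N_STAGES,
               dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  tm["W", ]  <- c(0,    0.70, 0.10, 0,    0.20)
  tm["N1", ] <- c(0.35, 0,    0.45, 0,    0.20)
  tm["N2", ] <- c(0.05, 0.40, 0,    0.35, 0.20)
  tm["N3", ] <- c(0.05, 0.05, 0.85, 0,    0.05)
  tm["R", ]  <- c(0.30, 0.40, 0.30, 0,    0)
  tm
}

#' Simulation configuration for a synthetic multi-scored database
#'
#' Bundles every knob of the simulator: the stage-transition process, the
#' scorer panel (size, reliabilities, error kernel, missing/NC rates) and
#' the class-conditional feature model. Defaults emulate a 5-scorer
#' healthy-adult database: marginals from [DEFAULT_STAGE_MARGINALS],
#' reliabilities spanning 0.6-0.9, no missing annotations. Use
#' `sim_config_partial()` for a 6-scorer panel with partial annotations.
#'
#' @param n_subjects Number of recordings.
#' @param epochs_per_subject Epochs per recording (960 = 8 h of 30-s
#'   epochs).
#' @param transition_matrix 5 x 5 row-stochastic stage kernel.
#' @param initial_distribution Length-5 start distribution; defaults to the
#'   kernel's stationary distribution.
#' @param n_scorers Panel size J.
#' @param scorer_reliabilities Length-J probabilities that a scorer copies
#'   the true stage (otherwise the label is drawn from the confusion
#'   template row of the true stage).
#' @param confusion_template 5 x 5 row-stochastic error kernel.
#' @param missing_rate,nc_rate Per-cell i.i.d. probabilities of "-" and NC.
#' @param feature_dim Feature dimension d.
#' @param class_means 5 x d matrix of per-stage feature centroids; default
#'   `2.5 * I_5` gives a nearest-centroid accuracy around 0.87 at unit
#'   noise, comparable to human staging accuracy.
#' @param feature_sd Isotropic feature noise scale.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 40L, epochs_per_subject = 960L,
                       transition_matrix = sleep_transition_matrix(),
                       initial_distribution = stationary_distribution(transition_matrix),
                       n_scorers = 5L,
                       scorer_reliabilities = seq(0.6, 0.9,
                                                  length.out = n_scorers),
                       confusion_template = default_confusion_template(),
                       missing_rate = 0, nc_rate = 0,
                       feature_dim = 5L,
                       class_means = 2.5 * diag(N_STAGES)[, seq_len(feature_dim),
                                                          drop = FALSE],
                       feature_sd = 1) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1, n_scorers >= 2,
            length(scorer_reliabilities) == n_scorers,
            all(scorer_reliabilities >= 0 & scorer_reliabilities <= 1),
            missing_rate >= 0, missing_rate < 1, nc_rate >= 0, nc_rate < 1,
            nrow(class_means) == N_STAGES, ncol(class_means) == feature_dim,
            feature_sd > 0)
  check_stochastic(transition_matrix, "transition_matrix")
  check_stochastic(confusion_template, "confusion_template")
  if (abs(sum(initial_distribution) - 1) > 1e-9 || any(initial_distribution < 0))
    stop("initial_distribution must be a probability vector")
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 transition_matrix = transition_matrix,
                 initial_distribution = initial_distribution,
                 n_scorers = as.integer(n_scorers),
                 scorer_reliabilities = scorer_reliabilities,
                 confusion_template = confusion_template,
                 missing_rate = missing_rate, nc_rate = nc_rate,
                 feature_dim = as.integer(feature_dim),
                 class_means = class_means, feature_sd = feature_sd),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @export
sim_config_partial <- function(...) {
  defaults <- list(n_scorers = 6L,
                   scorer_reliabilities = seq(0.52, 0.92, length.out = 6L),
                   missing_rate = 0.10, nc_rate = 0.02)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

check_stochastic <- function(P, what) {
  if (!is.matrix(P) || nrow(P) != N_STAGES || ncol(P) != N_STAGES ||
      any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop(what, " must be a ", N_STAGES, "x", N_STAGES,
         " row-stochastic matrix")
  invisible(P)
}

#' Simulate a true hypnogram
#'
#' First-order Markov chain over the five stages. Uses the current RNG
#' state; seed with [set.seed()] or via [simulate_dataset()].
#'
#' @param n_epochs Number of 30-s epochs T.
#' @param transition_matrix 5 x 5 row-stochastic kernel.
#' @param initial_distribution Length-5 start distribution.
#' @return Character vector of T stage tokens.
#' @export
simulate_hypnogram <- function(n_epochs,
                               transition_matrix = sleep_transition_matrix(),
                               initial_distribution =
                                 stationary_distribution(transition_matrix)) {
  check_stochastic(transition_matrix, "transition_matrix")
  s <- integer(n_epochs)
  s[1L] <- sample.int(N_STAGES, 1L, prob = initial_distribution)
  for (t in seq_len(n_epochs - 1L))
    s[t + 1L] <- sample.int(N_STAGES, 1L, prob = transition_matrix[s[t], ])
  SLEEP_STAGES[s]
}

#' Simulate a scorer panel for a true hypnogram
#'
#' Scorer j copies the true stage with probability `r_j`; otherwise its
#' label is drawn from the confusion-template row of the true stage. NC and
#' missing markers are then inserted i.i.d. at the configured rates. If any
#' epoch ends with no valid annotation the draw is rejected with an error
#' (raise reliability or lower the rates).
#'
#' @param truth Character vector of true stage tokens.
#' @param config A [sim_config()].
#' @param recording_id Identifier for the returned recording.
#' @return A [multi_scored_recording] with scorers `S1..SJ`.
#' @export
simulate_scorers <- function(truth, config, recording_id = "synthetic") {
  T_ <- length(truth); J <- config$n_scorers
  ti <- stage_index(truth)
  if (anyNA(ti)) stop("truth must contain only valid stages")
  labels <- matrix(TOKEN_MISSING, T_, J)
  for (j in seq_len(J)) {
    copy <- stats::runif(T_) < config$scorer_reliabilities[j]
    lab <- ti
    if (any(!copy)) {
      wrong <- which(!copy)
      lab[wrong] <- vapply(ti[wrong], function(s)
        sample.int(N_STAGES, 1L, prob = config$confusion_template[s, ]),
        integer(1))
    }
    tok <- SLEEP_STAGES[lab]
    u <- stats::runif(T_)
    tok[u < config$nc_rate] <- TOKEN_NC
    tok[u >= config$nc_rate &
          u < config$nc_rate + config$missing_rate] <- TOKEN_MISSING
    labels[, j] <- tok
  }
  rec <- multi_scored_recording(labels, paste0("S", seq_len(J)),
                                recording_id = recording_id)
  if (any(rowSums(valid_mask(rec)) == 0))
    stop("simulated epoch with zero valid annotations; ",
         "reduce missing_rate/nc_rate or increase J")
  rec
}

#' Simulate class-conditional feature vectors
#'
#' One isotropic Gaussian draw per epoch, centred on the true stage's
#' centroid. The centroid spacing relative to `feature_sd` controls the
#' achievable staging accuracy of any classifier trained on these features.
#'
#' @inheritParams simulate_scorers
#' @return T x d numeric matrix.
#' @export
simulate_features <- function(truth, config) {
  ti <- stage_index(truth)
  if (anyNA(ti)) stop("truth must contain only valid stages")
  mu <- config$class_means[ti, , drop = FALSE]
  mu + matrix(stats::rnorm(length(mu), sd = config$feature_sd),
              nrow = nrow(mu))
}

#' Simulate a full multi-scored database
#'
#' Per subject: a true hypnogram, a multi-scorer annotation table, and a
#' feature matrix. Bit-reproducible from `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return Object of class `synthetic_dataset`: list `subjects` (each with
#'   `truth`, `recording`, `features`), plus `config` and `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    truth <- simulate_hypnogram(config$epochs_per_subject,
                                config$transition_matrix,
                                config$initial_distribution)
    rec <- simulate_scorers(truth, config,
                            recording_id = sprintf("subj-%03d", i))
    feats <- simulate_features(truth, config)
    list(truth = truth, recording = rec, features = feats)
  })
  names(subjects) <- vapply(subjects, function(s) s$recording$recording_id, "")
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic multi-scored database: %d subjects x %d ",
                     "epochs, J = %d scorers (seed %d)\n"),
              cfg$n_subjects, cfg$epochs_per_subject, cfg$n_scorers, x$seed))
  cat(sprintf("Scorer reliabilities: %s\n",
              paste(round(cfg$scorer_reliabilities, 3), collapse = ", ")))
  marg <- table(factor(unlist(lapply(x$subjects, `[[`, "truth")),
                       levels = SLEEP_STAGES))
  cat("Empirical stage marginals:\n")
  print(round(marg / sum(marg), 4))
  invisible(x)
}
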