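test_that("ACS matches hand-evaluated cosine similarities", {
  sc <- random_stochastic(20)
  expect_equal(acs(sc, sc), 1)                       # identical hypnodensities
  expect_equal(acs(matrix(c(0, 1, 0, 0, 0), 1), matrix(c(1, 0, 0, 0, 0), 1)),
               0)                                    # disjoint supports
  expect_equal(acs(matrix(c(0.6, 0.2, 0.2, 0, 0), 1),
                   matrix(c(1, 0, 0, 0, 0), 1)),
               0.6 / sqrt(0.44))

  # per-epoch scale invariance of the cosine
  set.seed(31)
  a <- random_stochastic(10); b <- random_stochastic(10)
  expect_equal(acs(a, b), acs(a * 3, b))
  expect_true(acs(a, b) >= 0 && acs(a, b) <= 1)

  expect_error(acs(rbind(rep(0, 5)), random_stochastic(1)), "zero-norm.*1")
  expect_error(acs(random_stochastic(2), random_stochastic(3)), "shape")
})

test_that("ECE is zero when every bin's accuracy equals its confidence", {
  # ten predictions at confidence 0.60, exactly six correct
  p <- matrix(0.1, 10, 5); p[, 1] <- 0.6
  truth <- c(rep("W", 6), rep("N1", 4))
  rep_ <- ece(p, truth, n_bins = 10)
  expect_equal(rep_$ece, 0)
  expect_equal(rep_$mean_confidence, 0.6)
  expect_equal(sum(rep_$bins$n), 10)
})

test_that("ECE weights per-bin accuracy-confidence gaps by bin size", {
  # one correct prediction at 0.95, one wrong at 0.55, M = 10:
  # ECE = 1/2 * |1 - 0.95| + 1/2 * |0 - 0.55| = 0.30
  p <- rbind(c(0.95, 0.0125, 0.0125, 0.0125, 0.0125),
             c(0.55, 0.15, 0.15, 0.15, 0))
  truth <- c("W", "N1")
  rep_ <- ece(p, truth, n_bins = 10)
  expect_equal(rep_$ece, 0.30)
  # the report's bins recompute to the same ECE
  occ <- rep_$bins[rep_$bins$n > 0, ]
  expect_equal(sum(occ$n / sum(occ$n) * abs(occ$accuracy - occ$confidence)),
               rep_$ece)
})

test_that("binned ECE equals the per-sample brute-force oracle", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    p <- random_stochastic(n)
    truth <- sample(SLEEP_STAGES, n, replace = TRUE)
    m <- sample(c(1, 5, 10, 15), 1)
    rep_ <- ece(p, truth, n_bins = m)
    conf <- apply(p, 1, max)
    correct <- SLEEP_STAGES[max.col(p, ties.method = "first")] == truth
    expect_equal(rep_$ece, oracle_ece(conf, correct, m))
    expect_true(rep_$ece >= 0 && rep_$ece <= 1)
  }
})

test_that("performance reproduces analytic agreement values", {
  ref <- sample(SLEEP_STAGES, 40, replace = TRUE)
  perf <- suppressWarnings(performance(ref, ref))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$cohens_kappa, 1)
  expect_true(all(perf$per_class_f1[unique(ref)] == 1))

  # constant-W prediction against a 50% W reference: accuracy 1/2, kappa 0
  ref <- rep(c("W", "N2"), each = 25)
  perf <- suppressWarnings(performance(rep("W", 50), ref))
  expect_equal(perf$accuracy, 0.5)
  expect_equal(perf$cohens_kappa, 0)

  expect_error(performance(c("W", "W"), "W"), "length")
  expect_error(performance(c("W", "NC"), c("W", "W")), "NC")
  expect_warning(performance(c("W", "N1"), c("W", "N1")), "absent")
})

test_that("performance agrees with independent implementations", {
  skip_if_not_installed("e1071")
  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    pred <- sample(SLEEP_STAGES, n, replace = TRUE)
    ref <- sample(SLEEP_STAGES, n, replace = TRUE)
    perf <- suppressWarnings(performance(pred, ref))
    f1 <- oracle_f1(pred, ref)
    expect_equal(unname(perf$per_class_f1), f1, tolerance = 1e-9)
    expect_equal(perf$macro_f1, mean(f1), tolerance = 1e-9)
    counts <- sapply(SLEEP_STAGES, function(s) sum(ref == s))
    expect_equal(perf$weighted_f1, sum(f1 * counts) / n, tolerance = 1e-9)
    ag <- e1071::classAgreement(table(factor(ref, levels = SLEEP_STAGES),
                                      factor(pred, levels = SLEEP_STAGES)))
    expect_equal(perf$cohens_kappa, ag$kappa, tolerance = 1e-9)
    expect_equal(perf$accuracy, ag$diag, tolerance = 1e-9)
  }
})

test_that("scorer evaluation pairs consensus agreement with Soft-Agreement", {
  # unanimous panel: every scorer perfect on both scales
  rec <- multi_scored_recording(matrix(rep(c("W", "N2", "R", "N2"), 4), 4, 4))
  ev <- suppressWarnings(evaluate_scorers(rec))  # N1/N3 absent by design
  expect_equal(ev$summary$accuracy, rep(1, 4))
  expect_equal(ev$summary$soft_agreement, rep(1, 4))

  # two faithful scorers and one random one: the random scorer ranks last
  # in both Soft-Agreement and weighted F1
  set.seed(34)
  truth <- sample(SLEEP_STAGES, 300, replace = TRUE,
                  prob = c(0.2, 0.1, 0.4, 0.15, 0.15))
  rec <- multi_scored_recording(cbind(
    good1 = truth, good2 = truth,
    rnd = sample(SLEEP_STAGES, 300, replace = TRUE)))
  ev <- evaluate_scorers(rec)$summary
  expect_equal(ev$rank[ev$scorer_id == "rnd"], 3L)
  expect_true(ev$weighted_f1[ev$scorer_id == "rnd"] <
                min(ev$weighted_f1[ev$scorer_id != "rnd"]))
  expect_true(ev$soft_agreement[ev$scorer_id == "rnd"] <
                min(ev$soft_agreement[ev$scorer_id != "rnd"]))

  # epoch-order permutation leaves every summary number unchanged
  rec2 <- multi_scored_recording(rec$labels[sample(300), ], rec$scorer_ids)
  ev2 <- evaluate_scorers(rec2)$summary
  expect_equal(ev2, ev)
})
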