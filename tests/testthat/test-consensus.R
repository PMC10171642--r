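test_that("probabilistic consensus assigns 1 to majority and tied stages", {
  # two remaining voters disagree -> both stages score 1 (a tie)
  rec <- multi_scored_recording(cbind(A = "W", B = "N1", C = "N2"))
  z <- probabilistic_consensus(rec, excluded = "C")
  expect_equal(z$matrix[, 1], c(1, 1, 0, 0, 0), ignore_attr = TRUE)

  # unanimity
  rec <- multi_scored_recording(matrix("N2", 1, 5))
  z <- probabilistic_consensus(rec, excluded = "scorer_5")
  expect_equal(z$matrix[, 1], c(0, 0, 1, 0, 0), ignore_attr = TRUE)

  # votes [W, W, N1]: counts/max = [1, 0.5, 0, 0, 0]
  rec <- multi_scored_recording(cbind(A = "W", B = "W", C = "N1", D = "N3"))
  z <- probabilistic_consensus(rec, excluded = "D")
  expect_equal(z$matrix[, 1], c(1, 0.5, 0, 0, 0), ignore_attr = TRUE)

  # valid columns always have max exactly 1
  set.seed(11)
  for (i in 1:25) {
    rec <- random_recording(sample(1:8, 1), sample(2:6, 1),
                            p_nc = 0.2, p_missing = 0.1)
    for (s in rec$scorer_ids) {
      z <- probabilistic_consensus(rec, s)
      if (any(z$valid))
        expect_equal(unname(apply(z$matrix[, z$valid, drop = FALSE], 2, max)),
                     rep(1, sum(z$valid)))
    }
  }
})

test_that("Soft-Agreement hits its analytic anchors and stays in [0,1]", {
  # scorer identical to a unanimous panel -> 1
  rec <- multi_scored_recording(matrix(rep(c("W", "N2", "R"), 4), 3, 4))
  for (s in rec$scorer_ids) expect_equal(soft_agreement(rec, s), 1)

  # scorer always alone against a unanimous majority -> 0
  rec <- multi_scored_recording(cbind(A = c("R", "R"), B = c("W", "W"),
                                      C = c("W", "W"), D = c("W", "W")))
  expect_equal(soft_agreement(rec, "A"), 0)

  # 3 scorers, T = 2: S1 = [W,W], S2 = [W,N1], S3 = [N1,N1]
  # epoch 1: others vote W,N1 (tie) -> z[W] = 1; epoch 2: others vote N1,N1
  # -> z[W] = 0; SA(S1) = 0.5
  rec <- multi_scored_recording(cbind(S1 = c("W", "W"), S2 = c("W", "N1"),
                                      S3 = c("N1", "N1")))
  expect_equal(soft_agreement(rec, "S1"), 0.5)

  set.seed(12)
  for (i in 1:25) {
    rec <- random_recording(sample(2:8, 1), sample(3:6, 1), p_nc = 0.1)
    sa <- vapply(rec$scorer_ids, function(s) soft_agreement(rec, s), 0)
    expect_true(all(sa >= 0 & sa <= 1))
  }
})

test_that("soft_agreement errors when no epoch contributes", {
  rec <- multi_scored_recording(cbind(A = c("NC", "NC"), B = c("W", "W"),
                                      C = c("N1", "N2")))
  expect_error(soft_agreement(rec, "A"), "undefined")
})

test_that("scorer ranking sorts by Soft-Agreement with stable ties", {
  # identical panels: every SA = 1, ranking keeps input order
  rec <- multi_scored_recording(matrix(rep(c("W", "N2"), 3), 2, 3,
                                       dimnames = list(NULL, c("X", "Y", "Z"))))
  rk <- rank_scorers(rec)
  expect_equal(rk$scorer_id, c("X", "Y", "Z"))
  expect_equal(rk$soft_agreement, rep(1, 3))
  expect_equal(rk$rank, 1:3)

  # permuting scorer columns permutes ids but preserves each SA value
  set.seed(13)
  for (i in 1:10) {
    rec <- random_recording(6, 4, p_nc = 0.1)
    rk <- rank_scorers(rec)
    perm <- sample(4)
    rec2 <- multi_scored_recording(rec$labels[, perm],
                                   rec$scorer_ids[perm])
    rk2 <- rank_scorers(rec2)
    for (s in rec$scorer_ids)
      expect_equal(rk2$soft_agreement[rk2$scorer_id == s],
                   rk$soft_agreement[rk$scorer_id == s])
  }
})

test_that("soft-consensus is the per-epoch vote distribution", {
  # five annotations [W,W,W,N1,N2] -> [0.6, 0.2, 0.2, 0, 0]
  rec <- multi_scored_recording(matrix(c("W", "W", "W", "N1", "N2"), 1, 5))
  sc <- soft_consensus(rec)
  expect_equal(sc$matrix[1, ], c(0.6, 0.2, 0.2, 0, 0), ignore_attr = TRUE)
  expect_equal(sc$observation_count, 5L)

  # unanimity
  rec <- multi_scored_recording(matrix("R", 1, 5))
  expect_equal(soft_consensus(rec)$matrix[1, ], c(0, 0, 0, 0, 1),
               ignore_attr = TRUE)

  # [W, N1, -, NC, N1]: M = 3, [1/3, 2/3, 0, 0, 0]
  rec <- multi_scored_recording(matrix(c("W", "N1", "-", "NC", "N1"), 1, 5))
  sc <- soft_consensus(rec)
  expect_equal(sc$observation_count, 3L)
  expect_equal(sc$matrix[1, ], c(1 / 3, 2 / 3, 0, 0, 0), ignore_attr = TRUE)

  # all-invalid epoch is a named precondition error
  rec <- multi_scored_recording(rbind(c("W", "N1"), c("NC", "-")))
  expect_error(soft_consensus(rec), "epoch 2")

  # rows sum to 1 and entries are multiples of 1/M
  set.seed(14)
  for (i in 1:25) {
    rec <- random_recording(sample(1:10, 1), sample(2:6, 1),
                            p_nc = 0.2, p_missing = 0.1)
    sc <- soft_consensus(rec)
    expect_equal(rowSums(sc$matrix), rep(1, nrow(sc$matrix)),
                 tolerance = 1e-12)
    mult <- sc$matrix * sc$observation_count
    expect_equal(mult, round(mult), tolerance = 1e-9)
  }
})

test_that("majority vote takes the most voted stage, ties to reliability", {
  rec <- multi_scored_recording(matrix(c("W", "W", "W", "N1", "N2"), 1, 5))
  mv <- majority_vote(rec)
  expect_identical(mv$labels, "W")
  expect_false(mv$tie_flags)

  # tie epoch [W,W,N1,N1,N2]: the label must come from the top-ranked scorer
  # (whose vote is among the tied stages)
  rec <- multi_scored_recording(rbind(c("W", "W", "N1", "N1", "N2"),
                                      c("N2", "N2", "N2", "N2", "N2")),
                                scorer_ids = c("A", "B", "C", "D", "E"))
  rk <- rank_scorers(rec)
  mv <- majority_vote(rec, rk)
  expect_true(mv$tie_flags[1])
  top <- rk$scorer_id[1]
  expect_identical(mv$labels[1], unname(rec$labels[1, top]))

  # consensus label always attains the soft-consensus row max
  set.seed(15)
  for (i in 1:25) {
    rec <- random_recording(sample(2:10, 1), sample(3:6, 1), p_nc = 0.1)
    mv <- majority_vote(rec)
    sc <- soft_consensus(rec)
    idx <- stage_index(mv$labels)
    mx <- apply(sc$matrix, 1, max)
    expect_equal(sc$matrix[cbind(seq_along(idx), idx)], mx)
  }
})

test_that("majority vote ignores scorer column order on non-tie epochs", {
  set.seed(16)
  for (i in 1:10) {
    rec <- random_recording(10, 5)
    mv <- majority_vote(rec)
    perm <- sample(5)
    rec2 <- multi_scored_recording(rec$labels[, perm], rec$scorer_ids[perm])
    mv2 <- majority_vote(rec2)
    keep <- !mv$tie_flags
    expect_identical(mv$labels[keep], mv2$labels[keep])
  }
})

test_that("vectorised consensus equations match the brute-force oracle", {
  set.seed(17)
  for (i in 1:100) {
    rec <- random_recording(sample(1:6, 1), sample(2:4, 1),
                            p_nc = 0.15, p_missing = 0.1)
    sc <- soft_consensus(rec)
    expect_equal(unname(sc$matrix), unname(oracle_soft_consensus(rec$labels)))
    for (j in seq_along(rec$scorer_ids)) {
      pc <- probabilistic_consensus(rec, rec$scorer_ids[j])
      o <- oracle_prob_consensus(rec$labels, j)
      expect_equal(unname(pc$matrix), unname(o$z))
      expect_equal(pc$valid, o$valid)
      lab <- rec$labels[, j]
      if (any(lab %in% SLEEP_STAGES & o$valid))
        expect_equal(soft_agreement(rec, rec$scorer_ids[j]),
                     oracle_soft_agreement(rec$labels, j))
    }
  }
})
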