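# softstage

Multi-scorer sleep-stage label fusion, soft-consensus label smoothing, and
calibration/similarity metrics for probabilistic sleep stagers.

## Why

Reference sleep databases are scored in 30-s epochs by panels of five or six
physicians who frequently disagree (N1 most of all). Anyone training or
evaluating an automatic stager on such data needs to (a) rank scorer
reliability, (b) fuse the panel into a consensus, (c) decide whether the
training target should carry the panel's disagreement, and (d) evaluate not
only argmax agreement but calibration and similarity to the panel's
probability profile. `softstage` implements that chain for researchers in
automated sleep staging and, more generally, for anyone fusing
multi-annotator categorical labels on sequences.

## The statistics at the core

With one-hot annotations `y^j ∈ {0,1}^{K×T}` from scorer `j` of `J`:

* **Probabilistic consensus (leave-one-out)**
  `z^j[·,t] = Σ_{i≠j} y^i[·,t] / max_k Σ_{i≠j} y^i[k,t]` — majority and tied
  stages score exactly 1.
* **Soft-Agreement** `SA_j = (1/T) Σ_t z^j[y_j(t), t] ∈ [0,1]` — scorer
  reliability; 1 when always in the majority/ties, 0 when never matching any
  voted stage. Scorers are ranked per recording by SA.
* **Soft-consensus** `SC_{i,k} = #(Y_i = k) / M_i` — the per-epoch empirical
  vote distribution (`M_i` = valid observations at epoch `i`); also the
  panel's hypnodensity.
* **Consensus hypnogram** — per-epoch argmax of SC, ties broken by the most
  reliable scorer.
* **Soft-consensus label smoothing**
  `y^{LS_SC}_{i,k} = y_{i,k}(1−α) + α·SC_{i,k}` — the training target for a
  probabilistic stager (uniform variant: `α/K` in place of `SC`).
* **ACS** — mean per-epoch cosine similarity between predicted and
  soft-consensus probability rows; **ECE** — bin-weighted gap between
  accuracy and confidence over 10 equal confidence bins.

A seeded simulator (Markov stage sequences with prescribed stationary
marginals, scorers with configurable reliabilities and confusion structure,
Gaussian class-conditional features) and a minimal feed-forward softmax
stager (Adam, early stopping, MC-dropout) make the whole pipeline runnable
end to end without any PSG data.

## Worked example

The five-physician panel `[W, W, W, N1, N2]` for one epoch:

```r
library(softstage)
rec <- multi_scored_recording(matrix(c("W", "W", "W", "N1", "N2"), 1, 5))
soft_consensus(rec)$matrix
#>        W  N1  N2 N3 R
#> [1,] 0.6 0.2 0.2  0 0
smooth_soft_consensus(one_hot("W"), soft_consensus(rec), alpha = 0.5)
#>        W  N1  N2 N3 R
#> [1,] 0.8 0.1 0.1  0 0
```

Three votes out of five make `p(W) = 0.6`; smoothing the one-hot W target
half-way toward that distribution gives `0.8 = 1·0.5 + 0.6·0.5`.

An end-to-end synthetic experiment (smaller than the defaults, for speed):

```r
ds <- simulate_dataset(sim_config(n_subjects = 8, epochs_per_subject = 200), seed = 5)
ex <- run_experiment(ds, folds = 4, modes = c("base", "soft_consensus"),
                     alpha_grid_sc = c(0.3, 0.7, 1.0), seed = 11,
                     max_iterations = 20, patience = 4)
ex
#> Staging experiment: 4-fold CV, seed 11, alpha selected by f1
#> base           alpha=-    Acc 0.835  MF1 0.727  wF1 0.827  kappa 0.745  ECE 0.060  conf 0.783  ACS 0.849+-0.015
#> soft_consensus alpha=0.3  Acc 0.836  MF1 0.737  wF1 0.829  kappa 0.749  ECE 0.092  conf 0.751  ACS 0.852+-0.034  (ACS vs base: p = 0.7263)
```

Per-subject metrics are computed against the majority-vote consensus; `ACS`
measures how closely each model's hypnodensity tracks the scorer panel's
soft-consensus. At the default scale (40 subjects × 960 epochs, 5 seeds) the
soft-consensus-smoothed model's mean test ACS exceeds the base model's in
every seed. See `vignettes/multi-scorer-consensus.Rmd` for the model,
its assumptions, and what the synthetic test bed does and does not show.

## Command line

A thin front end over the same functions ships in `inst/cli/softstage.R`:

```sh
Rscript inst/cli/softstage.R consensus --annotations night.csv \
    --out-hypnogram hyp.txt --out-softconsensus sc.csv --report-reliability rel.csv
Rscript inst/cli/softstage.R simulate --n-subjects 5 --out-dir data/ --seed 7
Rscript inst/cli/softstage.R hypnodensity --probs sc.csv --hypnogram hyp.txt --out night.png
```

Annotation files are delimited text with header `epoch,<scorer>,...` and
tokens `W,N1,N2,N3,R,NC,-`; every artifact-producing run writes a
`.provenance.json` sidecar recording the effective options and seed.

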