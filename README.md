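# ddifuse

Multi-scale drug–drug interaction (DDI) prediction in R. Adverse
interactions between co-administered drugs are a leading cause of
preventable harm, and signals about them live at different scales: in the
molecule itself, in what a drug touches locally (proteins, diseases, side
effects), and in the global structure of biomedical knowledge graphs.
`ddifuse` builds one representation per scale and lets a transformer decide
how to weigh them per drug:

- **a_i** — atomic: a message-passing network over the heavy-atom graph,
  pretrained by attribute masking (15% of atoms masked, a linear head
  recovers their types), mean-pooled per molecule;
- **l_i** — local: relation-typed propagation over the drug–entity
  association graph, `E_v = sum_r sigmoid(W_r [E_v ; mean(N_r(v))])`,
  pretrained by link reconstruction;
- **g_i** — global: the real part of a ComplEx knowledge-graph
  factorisation, `phi(h,r,t) = Re(sum_k w_rk e_hk conj(e_tk))`, trained on
  the regularised logistic loss;
- **fusion** — the three vectors as tokens through a pre-norm transformer
  encoder block (multi-head self-attention + feedforward, residuals,
  layer norm), with concat / Hadamard / average baselines;
- **pair head** — an MLP on `concat(x_i, x_j)`, scores averaged over both
  orders; binary cross-entropy, or a phased cross-entropy→focal-loss
  (gamma = 2) schedule for long-tailed event classes with strict
  rare-class filtering (< 10 instances) and stratified K-fold evaluation.

Everything — including all gradient training — is implemented in base R
(no deep-learning framework), and a seeded synthetic-data module generates
molecules, block-model association graphs, planted low-rank knowledge
graphs and plantable pair labels so the whole pipeline is testable offline.

## Worked example

```r
library(ddifuse)

# a fully synthetic world: 80 drugs, 4 hidden communities, planted labels
cfg <- synth_config(seed = 1, n_drugs = 80,
                    n_entities_per_relation = 24, n_kg_entities = 100)
simulate_dataset(cfg, "demo")

run <- load_run_config(overrides = list(
  paths = list(drugs = "demo/drugs.tsv", associations = "demo/associations.tsv",
               triples = "demo/triples.tsv", pairs = "demo/pairs.tsv",
               out_dir = "demo/out"),
  training = list(attr_epochs = 40, local_epochs = 40, kg_epochs = 40,
                  epochs = 120)))
res <- run_pipeline(run)
#> stage=pretrain-attr epochs=40
#> stage=pretrain-attr final_loss=0.7636
#> stage=pretrain-local epochs=40
#> stage=pretrain-local final_loss=0.3225
#> stage=train-kg epochs=40 rank=32
#> stage=train-kg final_loss=0.0746
#> stage=train mode=binary strategy=transformer epochs=120
#> stage=train final_loss=3e-04
#> stage=evaluate metric=auroc value=0.7325
round(unlist(res$report), 3)
#> accuracy precision  recall     f1  auroc   aupr
#>    0.645     0.676   0.590  0.630  0.733  0.788
```

The log lines are the stage trace: each encoder's final self-supervised
loss, then the fusion/head training loss, then the held-out fold's AUROC.
At this tiny scale (80 drugs, 40-epoch pretraining) the model recovers part
of the planted interaction rule; the acceptance-scale run (300 drugs,
default epochs) reaches held-out AUROC ≈ 0.93. `demo/out/` contains
`predictions.tsv` (per-pair scores), `eval.json` (the metric report) and
`model.rds`.

A command-line wrapper with the same stages is installed as `exec/ddifuse`
(subcommands `simulate`, `pretrain-attr`, `pretrain-local`, `train-kg`,
`train`, `predict`, `evaluate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full stagewise pipeline from scratch on a freshly simulated
dataset (all randomness driven by `--seed`), prints the held-out metrics,
and writes the JSON report to `--out`.
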