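# seq2site

Residue-level prediction of protein–ligand binding sites from sequence
alone. Given per-residue embedding vectors of a protein, `seq2site`
predicts, for every residue, the probability that it belongs to a binding
site — the task at the core of sequence-based druggability mapping across
drug modalities (proteins, peptides, small molecules, carbohydrates,
DNA, RNA). The package is aimed at computational biologists who want a
self-contained, CPU-scale implementation of this model family, with the
surrounding machinery — structure-derived labelling, redundancy
reduction, imbalance-aware evaluation, calibration — included and tested.

## The model

For a protein with embedding matrix $P \in \mathbb{R}^{L_p \times d_p}$:

* **Encoder** — a gated convolutional network: affine projection to
  $d_{hid}$, then $n$ blocks of Conv1D (kernel $k$, padding $(k-1)/2$)
  producing $2d_{hid}$ channels gated by a GLU
  ($a \odot \sigma(b)$), with scaled residual connections
  ($s = \sqrt{0.5}$) and a final layer norm, giving global features
  $H_p = \mathrm{Encoder}(P)$.
* **Decoder** — for each residue, a window of $L_l$ projected embeddings
  passes through $n$ layers of self-attention (within the window),
  cross-attention against $H_p$
  ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, multi-head, no causal mask),
  and a position-wise feed-forward network, each with residual + layer
  norm.
* **Aggregation and classifier** — window features are combined with
  norm-softmax significance weights
  $w_j = \exp(\lVert H_{l_j}\rVert)/\sum_k \exp(\lVert H_{l_k}\rVert)$,
  and a $d_{hid} \to 64 \to 32 \to 2$ ReLU stack yields the binding
  probability.
* **Training** — class-weighted cross-entropy
  $-\sum_i [\,w\,y_i\log\hat y_i + (1-y_i)\log(1-\hat y_i)\,]$
  (the positive class up-weighted because binding residues are rare),
  RAdam + Lookahead, residue-level minibatches, early stopping on
  validation MCC with patience 10.

Defaults follow the published architecture ($d_{hid}=128$, 3+3 layers,
8 heads, $d_{ff}=256$, $k=7$, weight decay $10^{-4}$). The forward and
backward passes are hand-implemented in RcppArmadillo and verified
against a pure-R reference and finite differences in the test suite.

Because real benchmarks need curated structure databases and large
protein-language-model inference, the package ships a synthetic
benchmark generator (`make_benchmark()`) that plants a local linear
binding rule in deterministic synthetic embeddings, with realistic class
imbalance — every stage of the pipeline runs and is tested without any
download. Structure-derived labelling (`label_by_cutoff()` at 6.5 Å /
4.2 Å heavy-atom, `label_by_vdw_margin()` at 0.5 Å + van der Waals
radii) and greedy sequence-identity clustering (`greedy_cluster()`)
cover dataset construction when complexes are available.

## Worked example

```r
library(seq2site)

# a small synthetic benchmark: 60 training proteins, planted binding rule
bench <- make_benchmark(n_train = 60, n_valid = 15, n_test = 15,
                        d_p = 32, length_range = c(40, 80),
                        pi_target = 0.15, rho = 0.02, seed = 42)
print(bench)
#> <synthetic_benchmark> 60/15/15 proteins, d_p=32, pi=0.15, rho=0.02, seed=42
#>   realized positive fraction: train=0.165, valid=0.173, test=0.169

cfg <- run_config(d_hid = 32L, d_ff = 64L, max_epochs = 10L, seed = 42L)
model <- train_model(bench$train$proteins, bench$train$labels,
                     bench$valid$proteins, bench$valid$labels,
                     config = cfg, embeddings = bench$train$embeddings,
                     valid_embeddings = bench$valid$embeddings)
print(model)
#> <binding_model> d_hid=32, d_p=32, w=5.043, best epoch 6/10 (valid metric 0.3847)

preds <- predict_proteins(bench$test$proteins, model,
                          embeddings = bench$test$embeddings)
head(preds, 5)
#>   protein_id position residue probability call
#> 1        te1        1       R   0.8705839    1
#> 2        te1        2       I   0.8469458    1
#> 3        te1        3       H   0.6973766    1
#> 4        te1        4       F   0.6883092    1
#> 5        te1        5       Y   0.5930354    1

rep <- pooled_metrics(preds, bench$test$labels)
cat(sprintf("AUROC %.3f | AUPRC %.3f | MCC %.3f | F1 %.3f | Brier %.3f\n",
            rep$AUROC, rep$AUPRC, rep$MCC, rep$F1, rep$Brier))
#> AUROC 0.825 | AUPRC 0.478 | MCC 0.414 | F1 0.509 | Brier 0.190
```

The realized positive fraction (~0.17) reflects the planted imbalance;
`w` is the automatic class-ratio loss weight; and the held-out metrics
come from a deliberately small run — at the package's study scale
(200/50/50 proteins, `d_hid = 64`, 15 epochs) held-out AUROC is ≈ 0.92
and MCC ≈ 0.7 against a label-noise ceiling of ≈ 0.93.

A thin command-line wrapper with `simulate` / `train` / `predict` /
`evaluate` / `annotate` subcommands is installed at
`inst/cli/seq2site.R`.

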