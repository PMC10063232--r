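# protfun

Protein function prediction from unaligned amino-acid sequences with a
dilated residual convolutional network, in R.

Annotating a protein with its function — an Enzyme Commission (EC) number or
Gene Ontology (GO) terms — is classically done by alignment (copy the labels
of the nearest annotated sequence) or by scanning libraries of family
profiles.  `protfun` implements the neural alternative: one convolutional
network reads the raw sequence and emits a probability for every label of a
hierarchical vocabulary in a single pass.  The package covers the full
experimental loop around that model:

* **ontology** — *is_a* label hierarchies (EC-style trees, GO-style DAGs),
  ancestor closure of leaf annotations (`parse_ontology`, `propagate`);
* **corpus** — FASTA + label-table ingestion, standard-residue/fragment
  filtering, random 80/10/10 and cluster-aware train/dev/test splits with
  "impossible pair" statistics (`read_corpus`, `random_split`,
  `clustered_split`, `split_stats`);
* **synthetic** — seeded synthetic proteomes with planted, hierarchy-linked
  motifs and ground-truth spans, so everything is testable offline
  (`make_ontology`, `make_corpus`);
* **model/trainer** — the dilated residual CNN (one-hot input → residual
  dilated convolutions → masked mean pool → per-label sigmoid) with
  hand-written forward/backward in RcppArmadillo, Adam, warmup + exponential
  decay, gradient clipping, length-dynamic batching (`model_config`,
  `build_model`, `train_model`);
* **metrics** — micro precision/recall over thresholds, Fmax, bootstrap
  CIs, ensembles, and the naive frequency baseline (`pr_curve`, `fmax`,
  `bootstrap_ci`, `ensemble_mean`, `naive_baseline`);
* **align_baseline** — Smith–Waterman (BLOSUM62, affine gaps) top-hit label
  transfer with bit-score confidence, optional external `blastp` backend,
  and the bit-score × probability ensemble (`align_baseline`,
  `combine_predictions`);
* **interpret** — exact class-activation maps for mean-pool/affine-head
  models, cross-class normalisation, centre-of-mass domain ordering, pooled
  embeddings and an embedding probe (`cam`, `order_domains`, `embed`).

The model: a sequence is one-hot encoded and lifted to `F` channels by a
width-9 convolution, then passed through pre-activation bottleneck residual
blocks `x + P(relu(N(D(relu(N(x))))))` whose dilated convolutions `D` widen
the receptive field geometrically (dilations 1, 3, 9, 27, 81 at defaults).
Per-residue features are averaged into one embedding `e`, and an affine head
gives logits `z = W'e + b`, squashed element-wise to per-label probabilities.
Because the pool is a mean and the head affine, each logit decomposes
exactly over residues — the property the interpretation module exploits.
Evaluation is by Fmax: the maximum micro-averaged F1 over the confidence
threshold sweep.

## Worked example

A miniature end-to-end run — build a 12-leaf ontology, plant motifs, train a
small model, and evaluate:

```r
library(protfun)

ont  <- make_ontology(levels = 3, branching = c(3, 4))   # 12 leaves, 16 labels
syn  <- make_corpus(ont, n = 400, length_range = c(80, 200), seed = 1)
sp   <- random_split(syn$corpus, seed = 1)
tr   <- corpus_fold(syn$corpus, sp, "train")
te   <- corpus_fold(syn$corpus, sp, "test")

cfg  <- model_config(ont$labels, filters = 48, num_res_layers = 2)
fit  <- train_model(build_model(cfg, seed = 1), tr,
                    train_config(train_steps = 2000, warmup_steps = 200,
                                 learning_rate = 5e-3, token_budget = 2048,
                                 seed = 1))

fmax_score(prediction_set(fit$model, te), corpus_truth(te))
#> Fmax = 0.9459 at threshold 0.02465 (precision 0.9722, recall 0.9211)

naive <- naive_baseline(tr, te$accession)
fmax_score(naive, corpus_truth(te))
#> Fmax = 0.5435 at threshold 0.3047 (precision 0.4630, recall 0.6579)
```

After a two-minute training run the network recovers the planted function
labels well (Fmax 0.95: at the best confidence threshold, 97% of predicted
example–label pairs are correct and 92% of true pairs are retrieved), while
the label-frequency control is stuck near 0.54 — it can only exploit the
hierarchy's class priors.  The larger reference study
(`run_desk_study()`, 2000 records, 5000 steps) reaches test Fmax ≈ 0.96.  `order_domains()` on a bifunctional record then reports which
function sits N-terminal of the other, from the class-activation maps alone.

A thin command-line interface over the same functions ships at
`system.file("cli", "protfun.R", package = "protfun")` with subcommands
`synth`, `split`, `train`, `predict`, `eval`, `blast-baseline`, `combine`,
`cam`, `order-domains`, `embed`; every run writes a JSON manifest (seed,
flags, input checksums) next to its outputs.

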