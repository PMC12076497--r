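# fewshotmol

Few-shot molecular bioactivity prediction in R: score query molecules for
activity against a new target given only a handful of known actives and
inactives — no per-target training, no fine-tuning.

## Who this is for

Early-stage virtual screening works in a regime classical QSAR cannot
reach: a team has, say, 4 known actives and 4 known inactives and wants a
ranked screening list. `fewshotmol` implements an embedding-based
few-shot predictor for that regime, together with the benchmark protocol
used to validate this model class against a from-scratch random-forest
baseline, and a synthetic bioactivity-database generator so everything
runs and is tested offline.

## The method

For a query molecule $q$ and a labeled support set
$\{(x_s, y_s)\}_{s=1}^{S}$ (both featurized as a 1024-bit ECFP4
fingerprint plus standardized physicochemical descriptors):

1. **Encode**: $e = \mathrm{LN}(Wx)$, a row-wise linear map with layer
   normalization.
2. **Context enrichment**: one Hopfield-style attention update per
   molecule over a frozen context set $C$ of 512 reference molecules,
   $z' = \mathrm{LN}(z + \mathrm{softmax}(\beta\, zW_q (CW_k)^\top)\, CW_v)$ —
   each molecule independently.
3. **Cross-attention**: joint self-attention over $\{q\} \cup$ support
   (per query; labels not visible).
4. **Similarity scoring**:
   $\hat p = \sigma\big(\tfrac{\gamma}{S}\sum_s \cos(q', s'_s)(2y_s-1)\big)$ —
   a similarity-weighted vote over support labels.

The model is meta-trained episodically on a corpus of small tasks and
then conditions on new support sets at prediction time ("in-context").
Because labels enter only in step 4, flipping all support labels maps
every score $p \mapsto 1-p$ exactly — one of several architectural
contracts the test suite enforces.

The benchmark harness recasts a long-format bioactivity table
(`smiles, group_id, label[, source_size]`) into few-shot tasks (HTS-size
cap, conflict removal, SMILES validation, minimum class counts), draws
three support sets per task at sizes 8/16 and active:inactive ratios
1:7, 1:3, 1:1, serves identical draws to every method, and compares
methods with five virtual-screening metrics (ROC-AUC, ΔAUC-PR, BEDROC,
balanced accuracy, MCC) and a two-sided paired Wilcoxon test.

## Worked example

Train the default model on the synthetic reference corpus and score
held-out queries against a four-active / four-inactive prompt (about
13 minutes on one CPU, almost all of it meta-training):

```r
library(fewshotmol)

db <- generate_database(synth_config(seed = 1))   # 270 tasks, ~22k molecules
ts <- split_tasks(db)
model <- train_fewshot(ts$train, ts$val, db$features,
                       train_config(),
                       model_config(feature_dim = ncol(db$features)),
                       seed = 1)

task <- ts$test[[1]]                               # a held-out task
actives   <- task$smiles[task$label == 1][1:4]
inactives <- task$smiles[task$label == 0][1:4]
queries   <- c(task$smiles[task$label == 1][5:7],  # unseen actives
               task$smiles[task$label == 0][5:7])  # unseen inactives
predict_fewshot(model, actives, inactives, queries)
```

```
                      smiles prediction
1                  OCCC=CCBr  0.3420681
2       O=C(C(Cl)C)Oc1cccnc1  0.7440188
3 OC(=O)c1cccc(c1)CCc1cccnc1  0.7751521
4               O=COC(OC=O)F  0.3238692
5           CCOS(=O)(=O)CSCN  0.2335341
6                  FCCCCCC#N  0.3104689
```

Queries 1–3 are truly active, 4–6 truly inactive in the generator's
ground truth: two of the three actives separate cleanly from the
inactives given only eight labeled molecules. Scores are sigmoid
probabilities conditioned on *this* support set. Checkpoints round-trip
with `save_checkpoint()` / `load_checkpoint()`, and `cli_main()` /
`inst/cli/fewshotmol` expose `predict`, `train`, `benchmark` and `synth`
subcommands.

Benchmark the model against the random-forest baseline on the 50
held-out test tasks:

```r
tdb <- build_taskdb(db$records[db$records$split == "test", ],
                    mode = "by_target", min_active = 20, min_inactive = 20)
res <- evaluate_fewshot(tdb,
                        list(fewshot = fewshot_method(model), rf = rf_method()),
                        db$features, model$standardizer, sizes = 8, seed = 1)
compare_methods(res, "fewshot", "rf", metrics = "auc")
```

```
  support_size ratio metric  median_a  median_b n_pairs      p_value star
1            8   1:1    auc 0.7256646 0.6107197     150 1.569872e-18 TRUE
2            8   1:3    auc 0.7263883 0.5877660     150 1.069058e-22 TRUE
3            8   1:7    auc 0.7189810 0.5724979     150 8.084825e-22 TRUE
   winner
1 fewshot
2 fewshot
3 fewshot
```

With only 8 labeled molecules per task the few-shot model reaches a
median ROC-AUC of about 0.72 across 50 unseen targets — roughly 0.11–0.15
above a random forest trained from scratch on the same supports, and the
paired Wilcoxon test marks every ratio as significant.

## Package layout

| Area | Functions |
|---|---|
| Molecule I/O | `parse_smiles`, `canonicalize_smiles`, `featurize_smiles`, `fit_standardizer`, `read_molecule_csv`, `write_predictions_csv` |
| Model | `model_config`, `init_fewshot_model`, `encode`, `context_enrich`, `cross_attend`, `similarity_predict`, `predict_scores`, `predict_fewshot` |
| Training | `train_config`, `sample_episode`, `episode_loss`, `train_fewshot`, `save_checkpoint`, `load_checkpoint` |
| Metrics | `metric_auc`, `metric_delta_auc_pr`, `metric_bedroc`, `metric_bacc_mcc`, `metric_vector`, `paired_wilcoxon` |
| Benchmark | `build_taskdb`, `draw_support`, `rf_baseline`, `evaluate_fewshot`, `compare_methods` |
| Synthetic data | `synth_config`, `generate_database`, `generate_context`, `split_tasks`, `write_database` |
| CLI | `cli_main`, script `inst/cli/fewshotmol` |

See the vignette (`vignettes/fewshot-bioactivity.Rmd`) for the model,
the benchmark protocol, the generator's assumptions and the package's
numerical conventions.
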