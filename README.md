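# fedlorasim

A desk-scale R simulator for **communication-efficient federated
fine-tuning of a Vision Transformer on binary chest-radiograph
classification**. It is aimed at researchers who want to study — on a
single CPU, with fully synthetic data — how parameter-efficient updates
(LoRA) and proximal regularisation (FedProx) interact when hospital-style
clients hold non-IID data.

## What it implements

**Model.** A DeiT-tiny classifier: 224×224×3 input split into 16×16
patches (196 patches), linear patch embedding with a learnable CLS token
and positional table,

```
Z0 = [x_cls; x_p^1 E; …; x_p^196 E] + E_pos ,
```

12 pre-norm encoder blocks (3-head self-attention
`softmax(QKᵀ/√(d/h))V`, GELU MLP at 4× width), final layer-norm, and a
linear head on the CLS token. The forward pass **and its reverse-mode
gradients** are written in base R matrix code and verified against
numerical differentiation in the test suite.

**LoRA.** Frozen base weights `W0` receive a trainable low-rank update
`ΔW = AB` (`A`: d×r, `B`: r×k), applied to the query and value slices of
each block's fused QKV projection and scaled by `s = α/r` (the literal
`s = α` convention is available). With the default r=16, α=32 this gives
exactly **147,456 trainable parameters of 5,672,258 total (2.6%), a
97.40% reduction**, transmitted at 32-bit as **0.56 MiB per client per
round** versus 21.64 MiB for the full model.

**Federation.** Clients minimise the FedProx objective

```
L = CE(w) + (μ/2)‖w − w_global‖² ,
```

with AdamW (lr 1e-4, weight decay 0.01, cosine annealing) and the server
aggregates updates by sample-weighted averaging
`w ← Σᵢ (nᵢ/n) wᵢ`. Four strategy arms: `fedavg`, `fedavg_lora`,
`fedprox`, `fedprox_lora`.

**Data.** A synthetic chest-radiograph generator (elliptical lung fields;
pneumonia adds Gaussian opacity blobs inside them), Dirichlet label-skew
client partitioning, the pooled train/validation re-split, and a
PCA-based inter-client heterogeneity score. Image folders in the
`split/class` layout (PNG/TIFF) can be loaded directly.

**Metrics & explainability.** Confusion-matrix metrics (accuracy,
per-class precision/recall/F1), rank-based ROC AUC, average precision,
the Youden-J optimal threshold, communication-cost accounting in both
binary (2²⁰) and decimal (10⁶) conventions, attention-rollout heatmaps
and RISE randomised-mask saliency.

## Worked example

```r
library(fedlorasim)

model <- build_model(vit_config(), seed = 1)
count_parameters(model)
#> [1] 5524802

model <- inject_lora(model, lora_config(), seed = 2)
count_parameters(model, trainable_only = TRUE)
#> [1] 147456
round(communication_cost(147456, 32, "binary_mib"), 2)
#> [1] 0.56

# published confusion counts for the federated test run
classification_metrics(confusion_matrix(tp = 384, fp = 66, tn = 168, fn = 6))
#> accuracy 88.46%
#> pneumonia: recall 98.46%  precision 85.33%  F1 91.43%
#> normal:    recall 71.79%  precision 96.55%  F1 82.35%
```

A full federated comparison on the packaged synthetic benchmark
(10 clients, Dirichlet(0.5) label skew, pretrained reduced backbone):

```r
bm <- synthetic_benchmark(seed = 11)
prox <- run_benchmark_arm(bm, "fedprox_lora", seed = 42)
avg  <- run_benchmark_arm(bm, "fedavg", seed = 42)
tail(prox$history$accuracy, 1)   # 0.98
tail(avg$history$accuracy, 1)    # 0.84
```

The proximal LoRA arm holds the pretrained accuracy while full-model
FedAvg drifts under label skew — the qualitative ordering the framework
is designed to produce.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/fedlora.R", package="fedlorasim"))') \
    simulate --strategy fedprox_lora --clients 10 --rounds 20 --seed 1 \
    --data synthetic --out run/
```

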