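---
title: "Simulating communication-efficient federated fine-tuning of a Vision Transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating communication-efficient federated fine-tuning of a Vision Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedlorasim)
```

## The problem

Hospitals cannot pool chest radiographs, yet a pneumonia classifier
trained at one site generalises poorly to others. Federated learning
trains a shared model by exchanging weight updates instead of images, but
two obstacles dominate in medical settings: **statistical heterogeneity**
(each site's label mix and acquisition characteristics differ, so local
updates drift apart) and **communication cost** (a full Vision
Transformer update is tens of megabytes per client per round).

`fedlorasim` simulates the combined remedy: clients fine-tune only
low-rank LoRA adapters inside a frozen DeiT-tiny backbone, under a
FedProx proximal penalty that anchors local training to the broadcast
global weights. Everything — the transformer, its gradients, the round
loop, the metrics, the saliency maps — runs desk-scale in R on synthetic
data, so every quantitative claim in the package is reproducible in
minutes on one CPU.

## Model

The backbone is DeiT-tiny adapted to two classes with a single CLS token:
patch size 16, embedding dimension $d = 192$, 12 pre-norm encoder blocks,
3 heads, MLP ratio 4. The input tokens are

$$Z_0 = [x_{\mathrm{cls}};\, x_p^1 E;\, \dots;\, x_p^{196} E] + E_{pos},$$

and each block applies $x \leftarrow x + \mathrm{MHSA}(\mathrm{LN}(x))$
followed by $x \leftarrow x + \mathrm{MLP}(\mathrm{LN}(x))$ with
$\mathrm{softmax}(QK^\top/\sqrt{d/h})V$ attention and a GELU MLP. The
head reads the CLS token after a final layer-norm. Patch flattening is
row-major (within a patch: row-major pixels, channel slowest); this
ordering is a convention the token algebra does not fix, so it is pinned
down here and tested against a brute-force extractor.

Two architectural choices deserve a note. First, the **pre-norm block
order**: descriptions of "add & normalize" after the sub-layer are
ambiguous between pre- and post-norm; the DeiT convention (LN before the
sub-layer) is used, and parameter counts are identical either way.
Second, **no distillation token**: the audited counts (5,672,258 total,
147,456 trainable) are consistent only with a single CLS token and a
two-class head, so that architecture is adopted throughout.

With these choices the base model has exactly 5,524,802 parameters
(patch projection 147,648 + CLS 192 + positional 37,824 + 12 × 444,864
per block + final LN 384 + head 386), verified in the tests both by
closed form and by per-tensor enumeration.

The forward pass and its reverse-mode gradients are hand-written base R
matrix code (no deep-learning runtime is used). The gradient
implementation is verified against central-difference numerical
differentiation on every tensor, which is the load-bearing correctness
check for the whole simulator.

## LoRA adapters

A frozen projection $W_0 \in \mathbb{R}^{d\times k}$ is adapted as
$W = W_0 + s\,AB$ with $A \in \mathbb{R}^{d\times r}$,
$B \in \mathbb{R}^{r\times k}$. Defaults follow the audited
configuration: $r = 16$, $\alpha = 32$, dropout 0.1 on the adapter path,
targets = the query and value slices of each block's fused QKV weight.
$A$ is initialised $\mathcal{N}(0, 1/r^2)$ and $B$ to zero, so the
adapted model reproduces the base model exactly at injection — a
property the tests assert for arbitrary architectures.

**Scaling convention.** The adapted weight is sometimes written with a
literal $\alpha$ multiplier; standard LoRA practice scales by
$\alpha/r$. With $\alpha = 32, r = 16$ the literal reading multiplies
the update by 32, which is numerically aggressive; the package defaults
to `alpha_over_r` ($s = 2$) and exposes `alpha_literal`. Parameter
counts — the audited quantities — are identical under both.

**Head policy.** With adapters only, the trainable set is exactly
$12 \times 2 \times (192\cdot 16 + 16\cdot 192) = 147{,}456$ elements,
which at 32 bits is 589,824 bytes = 0.56 MiB — precisely the audited
per-client payload. The classifier head is therefore *frozen and
excluded from the exchanged state by default* (`lora_config()`'s
`train_head = FALSE`). The federation simulator's LoRA arms instead set
`train_head = TRUE` and exchange the head too: a head that no client
ever updates cannot adapt to the task, and the head adds only
$192\cdot 2 + 2$ floats. Both switches are explicit so audit arithmetic
and simulation behaviour never contaminate each other.

## Federated optimisation

Each selected client minimises

$$F_k(w) + \frac{\mu}{2}\lVert w - w_t \rVert^2,$$

where $F_k$ is the mean cross-entropy on its shard and $w_t$ the
broadcast global weights; the proximal gradient is $\mu(w - w_t)$. The
norm is taken **over the trainable (exchanged) tensors only** — adapters
plus head in LoRA arms, all weights in full-model arms — since that is
the only weight set both parties share. Optimisation is AdamW
(lr $10^{-4}$, weight decay 0.01, cosine annealing across the local
epochs); the decoupled weight decay and the proximal term coexist as
configured, without de-duplication. The server aggregates
$w \leftarrow \sum_i (n_i/n)\, w_i$ per tensor. For LoRA arms the $A$
and $B$ matrices are averaged entrywise — note that
$\bar{A}\bar{B} \neq \overline{AB}$ in general; entrywise averaging is
the standard choice and keeps aggregation linear in the exchanged state.

Proximal anchoring is tested against the closed form on a 2-D quadratic
local loss ($w^\star = (H+\mu I)^{-1}(Hw_d + \mu w_g)$): the minimiser's
distance to the global anchor shrinks strictly monotonically in
$\mu \in \{0, 0.5, 5, 50\}$, and $\mu = 0$ reproduces the FedAvg arm
bit-for-bit.

Payload accounting counts exchanged tensor elements × bits/8 per
direction; uplink, downlink and totals are logged separately because
"parameters transmitted" is direction-ambiguous. Megabytes are reported
in both the binary ($2^{20}$; reproduces 0.56/21.64) and decimal
($10^6$; gives 0.589824 for the adapter state) conventions.

## Synthetic data and the packaged benchmark

The generator emulates the gross structure of a frontal radiograph: dark
background (0.1), two bright elliptical lung fields (+0.45), and — for
the pneumonia class — 2–4 Gaussian opacity blobs (sd 6% of the image
side) planted inside the lung fields with amplitude `effect_size`, plus
i.i.d. Gaussian pixel noise. Labels are stratified to the requested
prevalence. The lung mask ships with each set as ground truth for
saliency checks. What it does **not** emulate: anatomy (ribs,
mediastinum, devices), scanner physics, label noise, or the long-tailed
heterogeneity of real hospital archives — so passing tests demonstrate
correct mechanics and qualitative orderings, not clinical performance.

Client heterogeneity combines **label skew** — per-class client
proportions drawn from $\mathrm{Dirichlet}(\beta\,\mathbf{1}_K)$,
$\beta = 0.5$ by default, the standard simulation of biased label
distributions — with a mild per-client intensity offset (feature skew).
The heterogeneity score embeds client features in 2-D and averages
pairwise centroid distances; the embedding is PCA (deterministic,
reproducible) with an identity mode that makes the centroid arithmetic
exactly testable. t-SNE would serve equally for visualisation, but a
stochastic embedding has no place in a quantity the tests pin down.

The packaged benchmark (`synthetic_benchmark()`) uses a reduced
transformer (64-px input, 4 blocks, $d = 48$, 3 heads — 16 patches), 400
images (300 train / 100 test, prevalence 0.5), `effect_size` 0.3 = 6× the
pixel noise sd, and 10 clients. These sizes were chosen so a full
two-arm comparison completes in a few minutes on one CPU while every
mechanism (multi-head attention, multi-block rollout, skewed shards with
singleton clients) is still exercised.

**Pretraining protocol.** LoRA is a fine-tuning method: it assumes the
frozen backbone already encodes useful features, as in the full-scale
setting where the backbone is ImageNet-pretrained. Starting all arms
from a random backbone makes the comparison meaningless (full-model
training wins trivially, because adapters cannot build features from
scratch). The benchmark therefore pretrains the backbone centrally to
convergence on a *disjoint* synthetic sample, and every strategy arm
starts from that common checkpoint. On this benchmark the proximal LoRA
arm holds test accuracy ≈ 0.98 over 10 rounds while full-model FedAvg
drifts to ≈ 0.84 under the label skew — the qualitative ordering, not
the magnitudes, is the tested claim. The fine-tuning rate is the
configured $10^{-4}$: at 10× that, continued training erodes the
pretrained solution for *every* arm and final rankings are noise.

## Metrics

Confusion-based metrics use pneumonia as the positive class; the
normal-class row swaps the roles (normal precision = TN/(TN+FN), normal
recall = specificity). Zero denominators return 0 with a degeneracy
flag. Percentages are reported to two decimals, rounding half up. AUC is
the rank statistic with half-credit ties (equivalently the trapezoidal
ROC area), average precision is the step-wise sum of precision ×
recall increments, and the Youden threshold maximises
sensitivity + specificity − 1 with ties broken toward the higher cutoff.
Each has a brute-force twin in the tests (all pairs for AUC, exhaustive
cutoffs for Youden) plus a cross-check against an established ROC
implementation.

## Explainability

Attention rollout mixes each block's head-averaged attention with the
identity ($0.5A + 0.5I$, modelling the residual path), row-normalises,
multiplies across blocks, and upsamples the CLS row over patch tokens
(row-major $14\times14$ grid at full scale) bilinearly to pixel
resolution. RISE generates random coarse binary masks (Bernoulli keep
probability per cell, bilinear upsampling with random sub-cell offsets)
and averages them weighted by the model's score on each masked image,
normalised by the realised per-pixel mask coverage (which makes a
constant scorer yield an exactly flat map). Both are standard
reconstructions — the method names fix the family, not the details, so
the mixing coefficient (0.5), mean head aggregation (max available) and
coverage correction are documented here as the package's choices.

## Numerical choices and degenerate inputs

* Layer-norm uses $\varepsilon = 10^{-6}$; GELU is the exact
  erf form, $x\Phi(x)$.
* Weight init: truncated normal (sd 0.02, resampled beyond 2 sd) for
  projections, zeros for biases, ones for LN scales; optional checkpoint
  loading replaces init entirely.
* Dropout is inverted (scaled at train time) and applies only to the
  adapter input path; evaluation mode is exactly deterministic.
* Empty client shards are skipped with a signal; a round in which every
  client is skipped raises an empty-round error. Non-finite losses or
  gradients raise a divergence error rather than propagating NaNs.
* Dirichlet partitioning resamples (bounded retries) until every shard
  is non-empty; the partition is disjoint and exhaustive by
  construction and this is asserted over many seeds.
* All randomness flows through explicit integer seeds (`withr`-scoped,
  so library calls never disturb the caller's RNG state).

## Known limitations

* No GPU and no compiled kernels: full-size (224-px, 12-block) training
  steps run but are slow; the package's training-scale claims live on
  the reduced benchmark, while full-size claims are restricted to exact
  accounting (which is architecture arithmetic, not training).
* Pretrained DeiT weights can be loaded from a checkpoint but no
  converter for external weight formats ships with the package.
* The synthetic generator's simplicity means saliency checks validate
  localisation mechanics, not radiological plausibility.
* System heterogeneity (stragglers, partial work, dropped clients) is
  out of scope; the client fraction is the only participation control.
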