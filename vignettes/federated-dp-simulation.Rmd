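---
title: "Simulating federated learning with differential privacy on ultrasound phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated learning with differential privacy on ultrasound phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fldpsim)
```

## Scope and model

`fldpsim` is a desk-scale simulation bench for client-side differentially
private federated learning on breast-ultrasound-like image classification.
Everything a full-scale benchmark of this kind exercises — heterogeneous
client partitions, three aggregation rules, per-sample gradient clipping
with calibrated Gaussian noise, closed-form privacy accounting, a
communication-cost model and macro-averaged evaluation — is implemented
and tested here at a scale of ~1,200 synthetic 64×64 images and convex
classifiers, so the complete pipeline runs in minutes on one CPU. The
bench makes no claim about absolute clinical accuracy; its purpose is to
make the *mechanisms* executable, auditable and reproducible.

## The phantom generator

A phantom is built in three multiplicative layers:

1. **Background**: base level 0.5 with a mild vertical gain gradient
   (±0.04) and three broad Gaussian bumps (amplitude ±0.06, width
   0.25–0.45 of the side) — smooth tissue-like variation.
2. **Lesion** (absent for `normal`): a hypoechoic region darkening the
   background by the factor `1 − 0.55·m(x)`, where `m` is a soft
   elliptical membership. Benign lesions use a smooth margin (logistic
   edge width 0.08 in elliptical radius); malignant lesions perturb the
   unit boundary by a weighted sum of random angular harmonics (orders
   4–12, amplitude 0.40) with a sharper edge (0.04), and add a faint
   posterior shadow (strength 0.12) below the lesion footprint. Centers,
   axes (0.10–0.18 of the side per semi-axis) and orientations are drawn
   per image.
3. **Speckle**: each pixel is multiplied by `|1 + 0.35·Z|`, `Z` standard
   normal — folded-normal multiplicative noise, the canonical first-order
   speckle model.

Two design constraints were fixed once, before any federated experiment,
and then frozen: lesion *brightness is identical* for benign and
malignant (so lesion presence is an intensity cue but lesion type is
not), and the benign/malignant difference lives in fine-scale margin
shape that mean-pooling largely destroys. This is what produces the
intended difficulty ordering — screening (normal vs abnormal) is much
easier than diagnosis (benign vs malignant) — which the test suite
verifies as a ≥ 10-accuracy-point gap for an independent L2-regularized
logistic reference classifier (5-fold cross-validation at 200 images per
class).

What the generator does **not** emulate: acoustic physics (no point
spread function, no depth-dependent attenuation beyond the shadow band),
scanner-specific artifacts, annotation noise, or patient identity
(multiple images per patient); real-data conclusions cannot be read off
these phantoms. Passing tests demonstrate that the *machinery* behaves as
specified under controlled conditions, not that any accuracy level
transfers to clinical data.

## Preprocessing

The chain mirrors a transfer-learning ultrasound pipeline: bicubic resize
(separable Catmull–Rom, implemented in-package), CLAHE, 3×3 Gaussian
smoothing, then standardization with the fixed ImageNet channel
statistics. Parameters the emulated protocol leaves open were fixed as:
CLAHE tile grid 8×8 (the standard library default; only the clip limit
2.0 is prescribed), Gaussian σ = 0.8 for the 3×3 kernel (the common
kernel-size rule), and channel handling by replicating the grayscale
image across the three channels (`channels = "replicate"`), with a
single-channel mean-of-means variant behind a flag. Every stage records
mean/sd/min/max into an `audit` attribute, and any non-finite pixel
aborts with the stage name.

## Splitting and partitioning

The 80/10/10 split is image-level; the test set is drawn *first* from the
full cohort so that every configuration sharing a seed evaluates on the
identical held-out set. Rounding is deterministic: `n_test = round(0.1 N)`,
`n_val = round(0.1 N)`, train takes the remainder (at the emulated
cohort size 15,847 this gives 1,585/1,585/12,677).

Label skew draws each client's class proportions from Dirichlet(α·p), p
the global class distribution (α = 0.5 by default). The distributional
recipe leaves integerization open; it is realized by largest-remainder
rounding of per-client quotas against balanced target sizes, filled by
sampling without replacement from per-class pools (a depleted pool
truncates its quota; leftovers go to the clients furthest below target).
Quantity skew then re-targets client sizes by log-normal draws
(`sdlog = 0.3` by default; the emulated protocol prescribes no shape
parameter) rescaled to conserve the total exactly, re-allocating samples
so each client keeps its drawn class mix as closely as integer quotas
allow — label skew first, then size re-targeting. Feature skew assigns
each client one fixed (brightness, contrast, rotation) draw, applied at
image-load time so stored pixels stay canonical; ranges default to
±0.1, ×0.9–1.1, ±10°, a mild scanner-variation surrogate chosen once.

The reference non-IID client table (eight clients, sizes 847–3,247,
total 15,847) ships as a static fixture of integer per-client class
counts, obtained from the published per-client totals and one-decimal
percentages by largest-remainder rounding — which reproduces every
printed percentage exactly. It is one unreported-seed realization and
cannot be regenerated from the recipe; it is therefore packaged, not
re-derived. Its printed global percentage row reflects the underlying
class totals rather than the sum of the rounded per-client rows, so
`summarize_partition()` reports the realized global row instead.

## Models and the per-sample gradient contract

Two families expose exact per-sample gradients through a flat parameter
vector: multinomial logistic regression and a one-hidden-layer tanh
network, over images mean-pooled to a `pool × pool` grid (default 8,
i.e. 64 features). Closed-form backpropagation means per-sample clipping
needs no automatic differentiation, and the finite-difference oracle in
the test suite checks the gradients to 10⁻⁵ relative error. The seven
reference ImageNet architectures appear only as parameter-count metadata
driving the communication-cost model `2·|θ|·4 bytes·K` per round
(1 MB = 10⁶ bytes, 32-bit parameters).

## Aggregation rules and their fixed conventions

Three conventions were genuinely open and are fixed as follows:

- **FedAvg weighting**: the printed aggregation rule is the unweighted
  mean, while the surrounding text says "weighted averaging"; the
  printed form wins as the default, with `weighted_avg = TRUE`
  available.
- **FedOpt pseudo-gradient sign**: `Δ_t = w_t − mean_k(w_k)`, so the
  server's subtraction moves the global model toward the clients.
- **FedOpt bias correction**: the stated recurrence carries no Adam
  bias-correction terms, so none are applied by default
  (`server_bias_correction = TRUE` restores them).

Local training runs `E` epochs over `⌊n_k/B⌋` full batches (partial
batches dropped, consistent with the nominal "25 batches per epoch"
arithmetic at n ≈ 800, B = 32), with the learning rate decayed by 0.1 at
the configured rounds (a round `r` is decayed once per decay round
≤ r). The emulated protocol prescribes Adam as the local optimizer while its
DP algorithm statement uses a plain SGD step; both are implemented
(`local_optimizer`), but the plain step is the default and the only
path under DP. At desk scale the choice is not cosmetic: direction-
normalized Adam updates from label-skewed clients average destructively,
while plain SGD averages to the mixture gradient.

## The differential-privacy mechanism

Per step: per-sample gradients, clipping
`g̃ = g · min(1, C/max(‖g‖₂, 10⁻⁷))` (the floor guards the zero
gradient), batch mean, then Gaussian noise with per-coordinate standard
deviation **η·C applied to the batch average** — exactly as the
emulated mechanism states it, although the common DP-SGD convention
calibrates σC to the *sum* (i.e. ηC/B on the average). The
`convention = "sum_scaled"` flag exposes the alternative for sensitivity
analysis; accounting always describes the default form. The proximal and
weight-decay terms are data-independent and are added outside the
mechanism, so they carry no privacy cost.

Accounting is closed-form: `ε_step = √(2 ln(1.25/δ))/η` with
`δ_step = δ = 10⁻⁵` substituted directly — note this conflates per-step
and total δ, but it is reproduced as stated because the reference
arithmetic does exactly that. Basic composition multiplies by
`T = R·E·batches`; the sublinear estimate multiplies by √T. Reproducing
the printed budget table requires one further convention, kept explicit
in the ledger: the per-step ε is rounded to two decimals *before* linear
composition (2.42 × 12,500 = 30,250), while exact unrounded values are
reported alongside (`eps_basic` vs `eps_basic_printed`). η = 0 yields an
infinite budget as a distinguished value, not an error. The nominal
T = 12,500 uses 25 batches/epoch; because realistic client sizes
(847–3,247 at B = 32) imply 26–101 batches, the accounting module also
reports manifest-derived per-client step counts.

## The desk-scale study profile

`desk_profile()` freezes the conditions under which the qualitative
recovery properties are tested: 400/519/281 phantoms (the emulated
cohort's class mix at 1/13.2 scale), K = 8, α = 0.5, quantity
`sdlog = 0.3`, pooled-logistic model, and a federated protocol of
**400 rounds × 1 local epoch at batch 64, SGD learning rate 2 decayed at
rounds 280/360, weight decay 10⁻³**.

The protocol deviates deliberately from a deep-learning schedule, for
reasons specific to convex desk-scale models:

- **Frequent averaging (one local step per round).** With many local
  steps per round, each strongly-skewed client converges toward its
  *local* optimum within the round, and the average of local optima is a
  measurably worse classifier than the pooled optimum — a client-drift
  bias that more rounds or smaller rates do not remove. With one local
  step per round, FedAvg is synchronized large-batch SGD on the mixture
  objective and the bias vanishes.
- **Weight decay 10⁻³.** The pooled phantom tasks are near-separable for
  the logistic model, so the unregularized maximum-likelihood optimum
  diverges and "accuracy at equal epochs" degenerates into a race of
  step counts. The L2 term makes the objective strongly convex with a
  well-defined optimum that federated and centralized training share.
- **Learning rate 2.** Appropriate for pooled-pixel features of order
  0.5 and a 64-dimensional convex problem; the deep-net rate of 10⁻³
  leaves the desk-scale model at the majority-class solution within any
  reasonable budget.

Under this profile the test suite verifies, over five seeds, that the
best federated accuracy across FedAvg/FedProx/FedOpt is within 3
accuracy points of the centralized baseline at equal total epochs on the
screening task, and that mean accuracy is non-increasing in the noise
multiplier over η ∈ {0.5, 1, 2, 3} (Spearman rank correlation ≤ 0) under
DP with C = 1.5.

## Numerical choices and degenerate inputs

- Seed fan-out uses a stable multiplicative-mix hash
  (`derive_seed(master, component, ...)`) over path components, all
  arithmetic exact in doubles below 2³¹, so adding components never
  perturbs existing streams and every operation is a pure function of
  its inputs plus seed.
- Largest-remainder rounding breaks ties by first index — deterministic
  across platforms.
- Softmax is computed with the row-max subtracted; cross-entropy floors
  probabilities at 10⁻³⁰⁰ before the log.
- Evaluation defines 0/0 as 0 for per-class precision/recall/F1, and the
  class still counts in the macro mean (the conservative convention; the
  emulated protocol does not specify one). Argmax ties resolve to the
  first class index.
- Empty confusion inputs, out-of-range labels, fractions not summing to
  1 (tolerance 10⁻⁹), clients smaller than one batch (unless
  `allow_small_client`), zero-sample task classes, and non-finite pixels
  after any preprocessing stage all raise immediate, named errors.
- Dirichlet draws that leave a client empty are re-drawn (at most 100
  attempts) unless empty clients are explicitly permitted; log-normal
  size targets below one sample likewise.

## Limitations

The bench's verdicts are about mechanism correctness and qualitative
orderings, not clinical performance. The phantoms are statistically far
simpler than ultrasound; the classifiers are convex; the federation is
simulated in-process with full participation and no stragglers,
client sampling, or communication failures; privacy accounting is the
conservative closed-form composition (no Rényi accountant, no
subsampling amplification — deliberately, matching the accounting it
reproduces). The DP utility numbers at desk scale degrade faster with η
than a fine-tuned deep network would, because the model has no excess
capacity to absorb noise; only the *ordering* across η is asserted.
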