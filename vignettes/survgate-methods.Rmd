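---
title: "Gated multimodal discrete-time survival models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated multimodal discrete-time survival models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survgate)
```

## The model

Each patient carries up to three pooled modality vectors — histopathology
patch features $x_{img} \in \mathbb{R}^{2048}$, RNA embeddings
$x_{rna} \in \mathbb{R}^{256}$ and clinical-text embeddings
$x_{txt} \in \mathbb{R}^{768}$ — plus a binary availability mask
$m \in \{0,1\}^3$. Histopathology is the *anchor modality*: it must be
present, and the fusion contract rejects a cohort where it is not.

1. **Projection.** Each modality is mapped to a unified $d = 32$ space:
   $z_m = \mathrm{Dropout}(\mathrm{ReLU}(W_m x_m + b_m))$, dropout 0.25
   (training only). Missing modalities are replaced by the zero vector
   *after* projection (`zero_substitute`), so no imputed value ever
   mixes into a learned statistic.
2. **Availability-masked gated fusion.** Gate logits
   $\ell = W_g [z_{img}; z_{rna}; z_{txt}]$ (no bias) receive an
   additive penalty $-10^9$ wherever $m = 0$; a row-wise softmax then
   yields weights $g$ with $\sum_m g_m = 1$ and — because
   $e^{-10^9}$ underflows to exactly 0 in double precision — a *hard*
   zero on every unavailable modality. The fused embedding is
   $z_{fused} = \sum_m g_m z_m$. An unmasked early-fusion variant
   (concatenate + linear) is included as the robustness foil
   (`model_config(fusion = "early")`).
3. **Shared encoder.** A 2-layer, 4-head pre-norm transformer encoder
   with feed-forward width 64 processes $z_{fused}$ as a length-1 token
   sequence (optionally the three gate-weighted modality embeddings as
   a 3-token sequence via `encoder_tokens = "modality"`). There is *no*
   final layer norm after the blocks: with zero attention/feed-forward
   output weights the encoder is then exactly the identity, a property
   the tests pin down.
4. **Cancer-type-specific hazard heads.** For cancer type $c$, hazards
   are $\hat h = \sigma(W_c H + b_c) \in (0,1)^T$ with $T = 4$ time
   bins cut at per-cancer quantiles of the *uncensored training* event
   times (pooled fallback when a cancer has fewer than $T$ events).

**Loss.** With $S(t) = \prod_{k \le t} (1 - \hat h_k)$ and $S(0) = 1$,
an observed event in bin $\tau$ contributes
$-\log S(\tau - 1) - \log \hat h_\tau$ and a censored observation
contributes $-\log S(\tau)$; the loss is the batch mean. The scalar
risk used for ranking is the negative area under the discrete survival
curve, $r = -\sum_t S(t)$, and ranking quality is measured by the
concordance index over comparable pairs ($t_i < t_j$, patient $i$ an
event; ties in risk count 0.5), verified exactly against a brute-force
pair loop.

All forward and backward passes are hand-written in base R (layer norm,
multi-head attention, the gate softmax through its mask, the NLL
gradient through the sigmoid heads) and checked against central finite
differences:

```{r gradient-check}
cohort <- generate_cohort(sim_config(n = 40, n_cancers = 3), seed = 99)
cohort$mask[2, 2] <- 0L; cohort$mask[3, 3] <- 0L
disc <- fit_discretizer(cohort$meta, n_bins = 4)
batch <- make_batch(cohort, 1:4, disc)
cfg <- model_config(n_cancers = 3)
check_gradients(init_params(cfg, seed = 7), batch, cfg)$max_rel_err
```

## Numerical choices

- **Masked softmax.** The $-10^9$ penalty (configurable, required
  $\le -10^6$) makes unavailable-modality weights *exactly* zero in
  double precision; the row-max is subtracted before exponentiation so
  available logits never overflow.
- **Hazard clamping.** Hazards are clamped to $[10^{-7}, 1 - 10^{-7}]$
  before logs; the gradient w.r.t. the pre-sigmoid logits is formed
  analytically ($h_k$ below the event bin, $h_\tau - 1$ at it), which
  is exact and cancels the sigmoid saturation.
- **Layer norm at zero tokens.** In the 3-token encoder variant a
  zero-substituted modality is an all-zero token whose variance is 0,
  so layer norm operates at a point of very high curvature
  ($1/\sqrt{\epsilon}$, $\epsilon = 10^{-5}$). The analytic gradient is
  still correct — finite differences converge to it as the step
  shrinks — but naive finite differencing at step $10^{-5}$ is
  dominated by truncation error there. The gradient test therefore
  checks that variant on a fully observed batch; the default fused
  (1-token) architecture is checked with missing modalities present.
- **Determinism.** Every stochastic step (cohort generation, splits,
  initialisation, shuffling, modality dropout, K-means) runs under a
  seed saved in the artifacts, and `with_seed` restores the caller's
  RNG state, so whole experiments are bit-reproducible.

## Training: why momentum SGD + L2, not Adam

The obvious default — Adam at learning rate $10^{-3}$ — fails on this
problem class, and the failure is instructive. With ~240 training
patients and a 2048-dimensional image projection, Adam's per-coordinate
step sizes let the first projection layer memorize feature noise within
a few epochs: training NLL collapses toward zero while the rank
correlation between predicted and true risk peaks around epoch 4 and
then degrades. Validation-based checkpoint selection cannot rescue a
trajectory that never approaches the attainable optimum: a ridge
Cox benchmark fitted to the same cohorts reaches within ~0.02 of the
oracle C-index ceiling, while Adam-trained networks stall 0.13–0.23
below it.

The package default is therefore **momentum SGD** (momentum 0.9,
learning rate $3 \times 10^{-3}$) with a **coupled L2 penalty**
$\lambda = 3$ on weight matrices only (never biases or layer-norm
parameters), batch 32, up to 60 epochs with patience-15 early stopping
on the validation mean C-index across cancer types, and structured
modality dropout ($p = 0.3$ per auxiliary modality) so the gate learns
to operate under missing data. $\lambda$ was selected on *validation*
concordance over $\lambda \in \{0.5, 1, 2, 3\}$; the L2-regularized SGD
trajectory tracks the ridge-like solution that generalizes. With this
regime the gap to the per-seed oracle ceiling on planted-signal cohorts
(`signal_strength = 20`, $n = 600$, 3 cancers, ~35% censoring) is
0.03–0.07 across the five canonical seeds (123, 132, 213, 231, 321).
Adam remains available via `train_config(optimizer = "adam")`.

## The synthetic cohort generator

`generate_cohort` plants a known signal so recovery can be measured
against an oracle:

- each patient has one latent standard-normal factor per modality;
- observed features are factor × a fixed loading direction (norm
  `signal_strength`) + an institution-specific mean shift
  (sd `site_sd = 0.5`) + unit Gaussian noise;
- the true log relative hazard is the cancer-type-weighted sum
  $r_i = \sum_m \beta_m^{(c_i)} f_{i,m}$ (default $\beta$ = (0.5, 1.0,
  0.5): RNA dominant);
- survival is exponential with rate $\lambda_0 e^{r_i}$,
  $\lambda_0 = 1/365$; censoring is an independent exponential whose
  rate is tuned by root finding so the *expected* censoring fraction
  equals the target exactly;
- ground truth (factors, risks, rates) is returned in a separate
  `$truth` table that no pipeline stage consumes.

Site shifts move feature means only, never the latent risk, so
institution-grouped splits probe covariate-shift robustness rather than
label shift. The oracle ceiling — the concordance of the *true* risks
on the simulated outcomes — bounds what any fitted model can achieve
and is recomputed per seed:

```{r oracle}
co <- generate_cohort(sim_config(n = 600, n_cancers = 3,
                                 signal_strength = 20), seed = 123)
oracle_cindex_ceiling(co)$overall
censoring_rate(co)
```

**Realism and limits.** The generator reproduces the structural
features that matter for the protocol — multimodal signal with a
dominant modality, site-level covariate shift, heavy censoring,
per-cancer effect heterogeneity — but it is linear-Gaussian with
exponential outcomes; it does not model non-linear interactions,
informative censoring, or modality-missingness correlated with outcome.
Conclusions about *relative* robustness (gated vs early fusion) are the
intended use; absolute C-index values are not comparable to clinical
cohorts. By default the generator emits pooled per-patient vectors;
`level = "raw"` additionally emits patch/gene/token arrays at the true
dimensionalities for exercising the preprocessing path
(entropy-filtered patches, seeded K-means aggregation to $k = 128$
centers, mean pooling with text truncated at 200 tokens), which is
memory-heavy and intended for small $n$.

## Evaluation protocol

```{r protocol, eval = FALSE}
ex_gated <- multi_seed_experiment(sim_config(signal_strength = 20))
ex_early <- multi_seed_experiment(sim_config(signal_strength = 20),
                                  model_config(n_cancers = 3, fusion = "early"))
paired_ttest_bonferroni(ex_gated, ex_early)   # per-cancer, alpha / 7
variance_f_test(ex_gated$overall_per_seed, ex_early$overall_per_seed)
```

- **Splits**: 4:2:4 and 7:1:2 ratios; patient mode stratifies by cancer
  with largest-remainder rounding; institution mode assigns whole
  tissue-source sites greedily to the most under-filled fold, so sites
  never straddle folds.
- **Missing-modality stress**: `missing_modality_protocol` masks an
  exact rounded fraction of test patients (copy-on-mask; labels and the
  anchor are never altered), and `sweep_missing` traces C-index against
  rates 0/20/50/80%.
- **Statistics**: paired t-tests across seeds per cancer with
  Bonferroni $\alpha/7$, and a directional variance F-test
  ($F = s_a^2 / s_b^2$, one-sided critical value
  `qf(0.95, 4, 4)` $\approx 6.39$ for five seeds per arm). The harness
  is calibration-tested under the null in the test suite.

## Problem sizes

The bundled experiments run on one CPU: $n = 600$ patients, 3 cancer
types, 12 institutions, full feature widths (2048/256/768). One
training run takes roughly 7 seconds; the complete test suite,
including two training-based acceptance checks across multiple seeds,
finishes in about 90 seconds. The architecture constants ($d = 32$,
2 layers, 4 heads, $T = 4$, $C \le 10$) keep the hand-written
linear algebra comfortably fast at these sizes.
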