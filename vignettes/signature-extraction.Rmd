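---
title: "De novo mutational-signature extraction with an explainable autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo mutational-signature extraction with an explainable autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigxae)
```

## The model

A tumour's SBS-96 catalogue row $x \in \mathbb{N}^{96}$ counts its somatic
single-base substitutions in 96 trinucleotide-context channels. The model
explains a cohort $C \in \mathbb{N}^{m \times 96}$ as non-negative
combinations of $k$ signature profiles through a hybrid autoencoder:

* a **nonlinear encoder** $z = f(x)$: three dense hidden layers, each
  followed by batch normalization and a softplus activation, ending in a
  latent layer of width $k$ with a non-negative activation — $z$ are the
  sample's *exposures*;
* a **linear non-negative decoder** $\hat{x} = z W^\top$ with
  $W \in \mathbb{R}^{96 \times k}_{\ge 0}$ and no bias — the columns of $W$
  are the *signatures*, directly interpretable because the reconstruction
  is a plain non-negative mixture.

Training minimizes

$$
\mathcal{L}(x,\hat x) \;=\; \sum \bigl(-x \log \hat x + \hat x\bigr)
\;+\; \beta \log\det\!\left(W W^\top + I\right),
\qquad W \ge 0 ,
$$

the unnormalized Poisson negative log-likelihood (natural for counts; the
$\log x!$ term is constant and dropped) plus a **minimum-volume** penalty
that discourages inflated, overly similar signature sets and improves
identifiability. The penalty is evaluated as
$\beta \log\det(W^\top W + I_k)$; by Sylvester's determinant identity the
two forms are equal, so the cheap $k \times k$ computation is exact.
Non-negativity of $W$ is enforced by projection (clipping at zero after
every optimizer step).

## Model selection by consensus (the NMFk idea)

A single training run of a factorization model is not trustworthy: the
solution depends on the initialization, and the right number of signatures
$K^*$ is unknown. The extraction pipeline in `sigxae()` addresses both:

1. **Bootstrap augmentation.** Each genome with burden $N$ and channel
   frequencies $p$ is resampled $t$ times from $\mathrm{Multinomial}(N, p)$,
   enlarging the training set $t$-fold. Augmentation feeds the network
   enough data and, empirically, stabilizes run-to-run selection.
2. **Repeated training.** For every candidate $k$ the model is trained $n$
   times from different random initializations on the augmented catalogue;
   each run's decoder matrix and its reconstruction error
   $E_{rec} = \lVert C - \hat C \rVert_F$ *on the original catalogue* are
   collected.
3. **Matched consensus clustering.** The $n$ decoder matrices are clustered
   into $k$ clusters of exactly $n$ members: each run's columns are matched
   one-to-one to the current centroids by solving a linear assignment
   problem on $1-\cos$ cost (a Jonker–Volgenant solver, exact), then
   centroids are recomputed; iterate to a fixed point. Centroids are the
   consensus signatures $S_k$.
4. **Stability filter.** Cluster quality is summarized by silhouette scores
   under $1-\cos$ distance. Candidates must exceed both an average
   (`th_avg`, default 0.9) and a minimum (`th_min`, default 0.7) silhouette.
5. **Selection.** Among stable candidates, $K^*$ minimizes the mean
   reconstruction error; ties break toward the smaller $k$. If nothing is
   stable the result is flagged and the highest-silhouette $k$ is reported.

Two interpretation choices were open and are fixed here: the error entering
step 5 is the **mean** of the $n$ per-run errors (robust to a single bad
run; per-run values are kept in the result), and the **minimum silhouette**
is the minimum over clusters of the per-cluster mean silhouette. A single
cluster ($k=1$) is trivially consistent and is given silhouette 1.
Centroids are initialized from the lowest-error run, which makes the
clustering deterministic and quality-biased.

## Exposure assignment

Given a fixed signature set (the consensus $S_{K^*}$, or reference
profiles), `refit_exposures()` column-normalizes the signatures, installs
them as frozen decoder weights, and retrains only the encoder under the
Poisson loss — the volume penalty is constant once the decoder is frozen
and is dropped. Two L1 penalties promote sparse attributions and guard
against over-assignment: one on the last encoder layer's weights
(`l1_weights`, default 1e-4) and one on the latent output after its
non-negative activation (`l1_activity`, default 1e-3). The latent values
are the exposures; `rescale = TRUE` optionally scales each sample's
exposures to sum to its observed burden (off by default — the raw latent
output is the model's own estimate).

## Numerical choices

These matter for anyone retraining at other scales; none change the model
class.

* **Latent scale.** The latent activation is $z = c\,\mathrm{softplus}(\cdot)$
  with $c = \bar N / (k \log 2)$, $\bar N$ the mean training burden. At
  initialization exposures then sum to roughly $\bar N$ per sample and every
  trainable parameter sits at order one, so a single Adam learning rate
  works from 100-mutation exomes to 100k-mutation genomes. Softplus (not
  ReLU) keeps the gradient alive near zero.
* **Decoder initialization.** In de novo mode the decoder columns are
  seeded from randomly chosen, sum-normalized catalogue rows (plus a small
  uniform jitter): the signatures start on the data simplex at probability
  scale, which converges far faster than blind uniform initialization while
  preserving run-to-run diversity through the row choice.
* **Component resurrection.** A latent unit whose activation collapses to
  zero, or a signature column that duplicates another (cosine > 0.98),
  receives no useful gradient and would waste one of the $k$ components.
  Every 10 epochs during the first 70% of training such components are
  re-seeded from the currently worst-reconstructed spectra — the residual
  points at whatever process the model fails to explain (the same logic as
  restarting an empty k-means cluster). Each unit is rescued at most twice:
  a component that keeps collapsing is genuinely redundant for the dataset
  and leaving it alone preserves the nesting of reconstruction error in
  $k$.
* **Optimization.** Adam with minibatches, cosine decay of the learning
  rate to a tenth of its initial value, early stopping on a held-out
  fraction of rows (10% by default; the training loss when no split is
  used, as in assignment refits), best-epoch weights restored.
* **Batch-normalization statistics.** Inference-mode statistics are
  recalibrated from actual activation moments (a subsample during training,
  the full training set at the end) instead of relying on lagging running
  averages; without this, evaluation and training behaviour diverge badly
  on low-noise data.
* **Stability of the loss.** The Poisson term uses
  $\log(\hat x + \varepsilon)$ with $\varepsilon = 10^{-7}$; $\hat x \ge 0$
  holds by construction, so the gradient is exact everywhere.
* **Defaults.** Encoder widths default to 128/64/32 in `xae_control()`. The
  `sigxae()` pipeline, which trains hundreds of models, instead sizes a
  narrow funnel to the candidate range (about `3.2u / 1.6u / u` with
  bottleneck `u = max(8, max(k))`, batch 128, learning rate 4e-3 with
  cosine decay, at most 150 epochs): small networks of this shape converge
  more reproducibly across restarts, which is exactly what the consensus
  needs, and keep a full model scan tractable on a single CPU. $\beta$ defaults to 1e-3: with probability-scale decoder columns the
  penalty then acts as a gentle tie-breaker rather than a distortion.

## The synthetic-cohort generator

`scenario_template()` reproduces the structure of five published benchmark
designs (cohort sizes 1000/1000/1000/1000/2700; 11/11/11/3/21 signatures;
two-subcohort mixes for designs 2–4, nine cancer types for design 5).
`simulate_cohort()` draws, per sample: a log-normal total burden (rounded,
minimum 1), Bernoulli activation of each signature by its prevalence (a
sample losing all signatures falls back to the most prevalent one), a
Dirichlet-weighted multinomial split of the burden over active signatures,
and multinomial channel counts from each signature's profile (or Poisson
with the same means). Ground truth is recorded exactly as drawn, so
recovery can be scored without approximation.

Since curated reference profiles cannot be redistributed here,
`random_signatures()` generates sparse Dirichlet profiles with a hard upper
bound on pairwise cosine similarity; real reference files load through
`read_signatures()` wherever a signature matrix is accepted. Defaults
(sparsity 0.5, concentration 0.3, separation bound 0.6) give spiky,
signature-like profiles. What the simulator deliberately does **not**
emulate: sequencing artefacts, strand bias, subclonal structure, and the
specific shapes of curated signatures (flat or near-duplicate profiles can
be approached with the `max_pairwise_cosine` knob, not matched exactly).
Passing recovery tests on these cohorts therefore demonstrates correctness
of the machinery, not performance on any particular real tumour series.

## Problem sizes used by the tests and the acceptance script

The package's own benchmarks run at desk scale, chosen so a full consensus
extraction finishes in minutes on one CPU: a 3-signature two-subcohort
cohort of 400 samples ($t = 10$, $n = 15$, $k \in 1..8$) and an
11-signature cohort of 500 samples ($t = 10$, $n = 10$, $k \in 5..15$),
both with silhouette thresholds 0.9/0.7. Production-scale defaults
(`augment = 100`, `runs = 100`) match the published protocol and are the
recommended settings when hours of compute are available. Unit tests use
smaller cohorts still, with the reduced `xae_control` profiles visible in
the test helpers.

## Known limitations

* Selection can return a flagged "no stable solution" result on hard
  cohorts; downstream code should check `$flagged` rather than trust
  `K*` blindly.
* Training is stochastic gradient descent on a non-convex objective: a
  small fraction of runs may converge to inferior optima even with
  resurrection; the consensus layer absorbs occasional failures but a
  systematically multimodal cohort (near-duplicate true signatures) will
  depress silhouettes at the true $k$.
* The simulator's multinomial/Poisson noise is idealized; real catalogues
  carry correlated noise the model never sees in testing.
* Only SBS-96 channels are supported (no indel/doublet/copy-number
  signatures), and catalogues are assumed precomputed (no VCF/MAF parsing).
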