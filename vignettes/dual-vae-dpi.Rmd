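---
title: "Predicting drug-protein interactions with dual variational autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-protein interactions with dual variational autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dpivae` predicts whether a small molecule interacts with a protein target
from nothing but their linear text representations: the SMILES string of the
drug and the amino-acid sequence of the protein. Each of the two inputs is
treated as a character sequence, tokenized against a per-alphabet dictionary
(case-sensitively — aromatic `c` and aliphatic `C` are different symbols),
and modeled by its own variational autoencoder (VAE):

* **Encoder.** An embedding layer (the padding symbol embeds to the zero
  vector) followed by three gated convolutional blocks,
  `ReLU(conv_A(x) * sigmoid(conv_B(x)))`, with filter counts $(n, 2n, 3n)$
  where $n$ is the base filter count, and a pad-masked global max pool. Two
  affine heads map the pooled feature to the mean $\mu$ and log-variance
  $\log\sigma^2$ of a diagonal Gaussian approximate posterior
  $q(z \mid x)$.
* **Sampling.** The reparameterization trick,
  $z = \mu + \sigma \odot \epsilon$ with $\epsilon \sim N(0, I)$, keeps the
  sample differentiable in the posterior parameters. Evaluation uses
  $\epsilon = 0$ (the posterior mean), so inference is deterministic.
* **Decoder.** An affine expansion of $z$ seeds a full-length sequence,
  refined by three transposed-convolution layers mirroring the encoder's
  filter counts $(3n, 2n, n)$; a position-wise affine map scores each
  position against the vocabulary. With unit stride a transposed
  convolution is mathematically a convolution, and the implementation uses
  that form.
* **Prediction head.** Each branch's latent passes through an affine map to
  a `fc_dim`-wide feature, scaled dot-product self-attention
  ($\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with $Q = K = V$ the feature
  reshaped into rows), then the two branches are concatenated and passed
  through FC + ReLU + dropout twice and a final affine map to class scores.

The training objective combines all parts:

$$\mathcal{L} = \mathrm{CE}(y, \hat y) \;+\; \lambda \lVert \Theta \rVert^2
\;+\; w_{\mathrm{vae}} \cdot \bigl(\mathrm{KL}_d + \mathrm{Recon}_d +
\mathrm{KL}_t + \mathrm{Recon}_t\bigr),$$

the cross-entropy of the interaction label plus an L2 penalty on all
non-bias weights plus the negative dual evidence lower bound
$-L' = -(L_{\mathrm{DrugVAE}} + L_{\mathrm{ProteinVAE}})$. The KL between
the diagonal Gaussian posterior and the standard-normal prior has the
closed form $\tfrac12\sum_j (\sigma_j^2 + \mu_j^2 - 1 - \log\sigma_j^2)$.
Optimization is Adam with per-epoch reshuffling, early stopping on
validation accuracy, and a grid search over $\lambda = 10^k$,
$k \in \{-5, \dots, +5\}$.

## Design choices where the design was genuinely open

Several details of this architecture family admit more than one reading;
the package fixes each with a documented, configurable choice.

* **Attention scaling.** The scores are divided by $\sqrt{d_k}$, the
  standard scaled dot product. `attention_scale = "linear"` divides by
  $d_k$ instead, for the variant in which the raw dimension is used.
* **Gating form.** "Gated convolution" is realized as a gated linear unit —
  one filter bank multiplied by the sigmoid of a second — followed by the
  ReLU, the canonical construction matching the name.
* **What the head consumes.** The head reads the latent variables $z_d$ and
  $z_t$ themselves (consistent with the generative story in which the
  interaction is generated from the latents), not the pooled convolutional
  features.
* **Self-attention over a single feature vector.** Attention over a one-row
  matrix is a no-op, so each branch's `fc_dim` feature is reshaped into
  `attention_heads_rows` rows (default 8) before attending and flattened
  after. This gives the mechanism content while operating per sample.
* **Reconstruction likelihood.** The sequences are discrete characters, so
  the default reconstruction loss is position-wise categorical
  cross-entropy over non-pad positions. `recon_mode = "gaussian_embedding"`
  instead regresses the decoder output onto the input's embedded matrix
  (squared error), honoring a Gaussian-likelihood reading.
* **Combining the ELBO with the supervised loss.** The weight
  `vae_weight` (default 1) multiplies the negative dual ELBO; 0 gives a
  purely supervised ablation in which the decoder pass is skipped
  entirely. See the calibration note below on how this weight behaves at
  small data scales.
* **The λ grid.** A grid over $[-5, +5]$ only makes sense as base-10
  exponents (a negative linear λ would violate the loss's own
  precondition), so candidates are $10^{-5} \dots 10^{5}$, ties broken
  toward the stronger regularizer. The default is $10^{-3}$.
* **Log-variance initialization.** The log-variance head's bias starts at
  −4 ($\sigma \approx 0.14$). A near-deterministic initial posterior keeps
  the sampled latent informative for the prediction head from the first
  epochs — with $\sigma \approx 1$ the early latent is noise-dominated and
  supervised learning stalls — while the KL term pulls $\sigma$ toward the
  prior as training proceeds.
* **Max pooling.** Global over sequence positions, with padded positions
  masked out, so padding length cannot influence the latent state. The
  backward pass routes gradient to the first position attaining the
  maximum.
* **Splits.** Record-level splitting (guarding record leakage): shuffled
  partition in which identical (drug, protein, label) triples never
  straddle two splits.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_filters_base` | 32 | filters in the first gated block; the next two use 2x, 3x |
| `filter_len_drug` / `filter_len_protein` | 5 / 7 | convolution filter lengths (characters) |
| `embed_dim` | 128 | character embedding dimension |
| `latent_dim` | 128 | dimension of each Gaussian latent |
| `fc_dim` | 1024 | first head layer width (second uses half) |
| `dropout_rate` | 0.1 | head dropout fraction |
| `max_len_drug` / `max_len_protein` | 100 / 1000 | tokenized lengths; longer sequences truncate with a flag |
| `epochs` / `batch_size` | 300 / 256 | optimization budget |
| `learning_rate` | 0.001 | Adam step size (0.0001 for continuous-affinity multiclass runs) |
| `lambda_l2` | 1e-3 | L2 coefficient (best grid value) |
| `vae_weight` | 1.0 | weight on the negative dual ELBO |
| `patience` | 20 | early-stop epochs without validation improvement |

The convolution filter counts, filter lengths, epoch budget, batch size and
learning rates follow the reference configuration of this model family; the dimensions that
configuration leaves open (embedding, latent, fully connected, dropout,
maximum lengths, patience) are declared package defaults, chosen once as
conventional values for character-level SMILES/protein models.

## Affinity discretization

Continuous affinity panels (pKd values, KIBA scores) are turned into a
five-class problem from the sample mean $\mu$ and standard deviation
$\sigma$ of the affinity column: with $d = |x - \mu| / \sigma$, class 0 is
$d \le 1$, classes 1-3 the successive annuli $(1,2]$, $(2,3]$, $(3,4]$,
and class 4 everything beyond. The nested printed intervals of the scheme
are resolved to these disjoint annuli — the only reading under which five
categories partition the data — with boundary ties going to the inner
class. On exactly normal data the expected class proportions are the
annulus masses (0.6827, 0.2718, 0.0428, 0.00263, 0.0000634). Kd in nM
converts to pKd as $-\log_{10}(\mathrm{Kd} \cdot 10^{-9})$.

## The synthetic study

Real interaction panels require external downloads, so the package ships a
generator whose defaults define its reference study: 200 drugs (SMILES-like
strings, 20-60 characters) and 200 proteins (amino-acid strings, 80-200
residues), a short motif planted in a random half of each library, 4,000
sampled pairs, and the AND rule — a pair interacts exactly when the drug
carries the drug motif *and* the protein carries the protein motif — with
5% independent label flips. The AND rule is chosen because neither branch
can resolve it alone: the head must combine both latents, mirroring the
structure of the real task. Affinity columns for the discretization module
are drawn from a two-component Gaussian mixture (85% N(5, 0.6²),
15% N(8, 1.2²)), emulating the skewed shape of kinase-panel histograms.

What the generator does *not* emulate: chemical validity of the SMILES,
binding physics, the long-tailed degree distributions of real interaction
networks, or covariate shift between drug families. Passing the synthetic
study therefore demonstrates that the implementation is correct and that
the architecture can learn a pair-level sequence rule — not that it attains
any particular accuracy on BindingDB-scale data.

**Scoring rule recovery under label noise.** With 5% label flips applied at
generation, the held-out *observed* labels are themselves 5% wrong: even a
perfect model would score an expected observed-label accuracy of exactly
0.95 and an observed-label AUC ceiling near 0.92. The learnability check
therefore scores the model against the noise-free rule labels, which the
generator returns alongside the noisy ones (`label_true`); observed-label
metrics are reported for completeness. This is the quantity of interest —
did the architecture recover the generating rule? — and it is not bounded
by the noise floor.

## Calibration at desk scale

Two interactions between the reference hyperparameters and Adam matter a
great deal on small data, and both were mapped with controlled ablations
on the reference synthetic study before fixing the package's verification
configuration:

* **L2-in-loss under Adam.** Adding `lambda * sum(W^2)` to the loss gives
  every weight a gradient component `2 * lambda * W`. Adam normalizes each
  parameter's update by its own gradient magnitude, so wherever the data
  gradient is smaller than this penalty term the update degenerates to a
  constant-rate shrink toward zero, and with `lambda = 1e-3` (the best
  value of the reference grid, selected on datasets of sixty thousand to a
  million pairs) the entire network collapses to zero within a few hundred
  steps on a 4,000-pair study — the training loss freezes at the label
  prior's entropy. Regularization strength must be chosen for the data
  scale; the package's own grid search exists for exactly that purpose,
  and the desk-scale verification runs use no penalty.
* **Generative-discriminative interference.** The reconstruction term
  contributes on the order of 3 nats per sequence position, the
  interaction cross-entropy at most ~0.6 per pair, and both pull on the
  same encoder weights. At the reference scale the supervised signal
  never lifts off while the weighted generative term is active (the KL
  also re-inflates the posterior spread, so the sampled latent that the
  head reads during training grows noisier). The learnability study
  therefore trains the supervised configuration (`vae_weight = 0`,
  `lambda_l2 = 0`, learning rate 0.002, batch 64), which recovers the
  planted rule; the generative pathway is verified separately — by the
  closed-form KL and reconstruction oracles, gradient checks, and a short
  joint-objective run asserting that the ELBO terms themselves improve.
  Because Adam is per-parameter scale-invariant, decoder-only parameters
  train at full pace for any positive `vae_weight`; the interference is a
  property of the shared encoder, not of the decoders.

## Numerical notes

* All gradients are analytic and verified against central finite
  differences in the test suite (at parameter points where ReLU and
  max-pool operate away from their kinks; at a kink the objective has only
  subgradients and the implementation takes the first-maximum convention).
* Softmaxes subtract the row maximum before exponentiation;
  reconstruction and prediction cross-entropies clamp probabilities at
  1e-300 before the log.
* The padding embedding row is pinned to zero by construction (its
  gradient is zeroed), and padded positions are excluded from both the max
  pool and the reconstruction loss, so tokenization length is semantically
  inert.
* Training is exactly reproducible: one seed drives initialization,
  shuffling, epsilon draws and dropout masks, and single-threaded BLAS
  makes the arithmetic deterministic.
* Divergent (non-finite) losses abort with a diagnostic rather than
  continuing.

## Problem sizes used in the checks

The package's own verification runs use desk-scale configurations chosen to
exercise every stage: the learnability study trains the reduced model
(`n_filters_base = 16`, `fc_dim = 128`, `embed_dim = 16`,
`latent_dim = 32`, maximum lengths 60/200 matching the generated ranges) on
the 4,000-pair reference study under the supervised configuration described
in the calibration section; the reproducibility and grid-search checks
use smaller record counts and epoch budgets, since determinism and
candidate enumeration are scale-free properties; Monte-Carlo oracles use
1e5-1e6 draws with three-standard-error bands.

## Known limitations

* Character-level SMILES only: multi-character tokens (`Cl`, `Br`, ring
  indices above 9) are split into single symbols; no canonicalization or
  graph parsing.
* The five-class scheme degenerates when the affinity column is constant
  (σ = 0), and statistics are computed on the full column by default — a
  `stats` argument supports train-only statistics when leakage matters.
* The trainer is single-threaded CPU R; it is sized for desk-scale studies,
  not for BindingDB-scale training.
* Binary decisions use a fixed 0.5 threshold; no calibration is performed.
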