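# dpivae

Drug–protein interaction (DPI) prediction from raw sequence text with a
pair of variational autoencoders. Given a drug's SMILES string and a
protein's amino-acid sequence, each branch tokenizes its input at character
level, encodes it with three gated convolutional blocks into a diagonal
Gaussian latent state, and reconstructs it through a deconvolutional
decoder; the two latents pass through scaled dot-product self-attention and
a fully connected head that scores the interaction. The package is aimed at
computational chemists and method developers who want a fully inspectable,
dependency-light implementation of this model family — every gradient is
analytic R, verified against finite differences.

## The model in brief

Per branch, the encoder produces the approximate posterior
q(z|x) = N(μ, diag(σ²)); sampling uses the reparameterization
z = μ + σ⊙ε. The training loss is

```
CE(y, ŷ) + λ‖Θ‖² + vae_weight · (KL_d + Recon_d + KL_t + Recon_t)
```

— interaction cross-entropy, L2 on non-bias weights, and the negative dual
evidence lower bound L′ = L_DrugVAE + L_ProteinVAE, where each branch's
KL to the standard-normal prior is ½Σ(σ² + μ² − 1 − log σ²) in closed form
and the reconstruction term is position-wise categorical cross-entropy over
non-pad positions. Attention is softmax(QKᵀ/√d_k)V. Optimization is Adam
(batch 256, up to 300 epochs) with early stopping on validation accuracy
and a λ = 10ᵏ grid search over k ∈ [−5, +5].

For continuous affinity panels (pKd, KIBA scores) a five-class scheme bins
each value by how many standard deviations it sits from the column mean:
classes 0–3 are the annuli d ≤ 1, 1 < d ≤ 2, 2 < d ≤ 3, 3 < d ≤ 4, and
class 4 is everything beyond.

## Worked example

Everything runs on the built-in synthetic study (motif-planted sequences;
a pair interacts iff the drug carries one motif AND the protein the other):

```r
library(dpivae)

spec  <- synthetic_spec(n_drugs = 40, n_proteins = 40, n_pairs = 300,
                        protein_len_range = c(50, 100), label_noise = 0,
                        seed = 1)
data   <- generate_dpi_dataset(spec)
splits <- make_splits(data$pairs, c(0.7, 0.15, 0.15), seed = 1)

dvoc <- build_vocabulary(data$sequences$drugs, "drug")
pvoc <- build_vocabulary(data$sequences$proteins, "protein")
mcfg <- model_config(n_filters_base = 8, embed_dim = 16, latent_dim = 16,
                     fc_dim = 64, max_len_drug = 60, max_len_protein = 100,
                     attention_heads_rows = 4)
# desk-scale supervised configuration; the methods vignette's calibration
# section explains why small studies train with vae_weight = 0, lambda = 0
fit  <- train_dpi(dpi_model(dvoc, pvoc, mcfg, seed = 1), splits,
                  train_config(epochs = 25, batch_size = 64, patience = 25,
                               seed = 1, learning_rate = 0.002,
                               lambda_l2 = 0, vae_weight = 0))
fit
evaluate_model(fit, splits$test)
```

```
<dpi_fit: 25 epoch(s), best val_acc 1.0000 at epoch 23>
<dpi_eval_report: n=45 acc=0.9556 auc=0.9764 prec=0.8750 rec=0.8750 f1=0.8750>
```

`acc` is the fraction of held-out pairs classified correctly at threshold
0.5, `auc` the probability that a random interacting pair outscores a
random non-interacting one (ties half), and precision/recall/F1 the usual
confusion-matrix summaries of the positive class. Discretizing a simulated
pKd-like affinity column:

```r
aff <- generate_affinities(10000, seed = 1)
d   <- discretize_dataset(aff)
d$freq
#>    0    1    2    3    4
#> 7950 1313  549  173   15
```

A command-line interface (`inst/cli/dpivae`) wraps the same functions as
`simulate`, `train`, `evaluate`, `predict` and `discretize` subcommands.

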