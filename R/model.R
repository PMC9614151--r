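#' Model configuration
#'
#' Collects every architecture hyperparameter. Defaults follow the reference
#' configuration: 32 encoder/decoder filters with the second and third gated
#' convolutions carrying two and three times the base count, filter lengths 5
#' (drug) and 7 (protein). Dimensions this model family leaves open
#' (embedding, latent, fully connected, dropout) have declared defaults and
#' are all overridable.
#'
#' @param n_filters_base Filters in the first gated convolution (the next two
#'   use 2x and 3x this count).
#' @param filter_len_drug,filter_len_protein Odd convolution filter lengths.
#' @param embed_dim Character embedding dimension.
#' @param latent_dim Dimension of each branch's Gaussian latent state.
#' @param fc_dim Width of the first fully connected head layer (the second
#'   uses `fc_dim / 2`). Must be divisible by `2 * attention_heads_rows`.
#' @param dropout_rate Dropout fraction in `[0, 1)` for the head.
#' @param n_classes 2 for binary interaction, 5 for discretized affinities.
#' @param max_len_drug,max_len_protein Fixed tokenized lengths per branch.
#' @param attention_scale `"sqrt"` divides attention scores by `sqrt(d_k)`
#'   (the standard scaled dot product); `"linear"` divides by `d_k`.
#' @param attention_heads_rows The head's self-attention reshapes each
#'   branch's `fc_dim` feature vector into this many rows before attending.
#' @param recon_mode `"categorical"` scores every position against the
#'   vocabulary (cross-entropy); `"gaussian_embedding"` regresses the
#'   decoder output onto the input's embedded matrix (squared error).
#' @return A validated `dpi_model_config` list.
#' @export
model_config <- function(n_filters_base = 32L,
                         filter_len_drug = 5L,
                         filter_len_protein = 7L,
                         embed_dim = 128L,
                         latent_dim = 128L,
                         fc_dim = 1024L,
                         dropout_rate = 0.1,
                         n_classes = 2L,
                         max_len_drug = 100L,
                         max_len_protein = 1000L,
                         attention_scale = c("sqrt", "linear"),
                         attention_heads_rows = 8L,
                         recon_mode = c("categorical", "gaussian_embedding")) {
  attention_scale <- match.arg(attention_scale)
  recon_mode <- match.arg(recon_mode)
  cfg <- list(
    n_filters_base = as.integer(n_filters_base),
    filter_len_drug = as.integer(filter_len_drug),
    filter_len_protein = as.integer(filter_len_protein),
    embed_dim = as.integer(embed_dim),
    latent_dim = as.integer(latent_dim),
    fc_dim = as.integer(fc_dim),
    dropout_rate = dropout_rate,
    n_classes = as.integer(n_classes),
    max_len_drug = as.integer(max_len_drug),
    max_len_protein = as.integer(max_len_protein),
    attention_scale = attention_scale,
    attention_heads_rows = as.integer(attention_heads_rows),
    recon_mode = recon_mode
  )
  stopifnot(
    cfg$n_filters_base >= 1L,
    cfg$filter_len_drug >= 1L, cfg$filter_len_drug %% 2L == 1L,
    cfg$filter_len_protein >= 1L, cfg$filter_len_protein %% 2L == 1L,
    cfg$embed_dim >= 1L, cfg$latent_dim >= 1L,
    cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
    cfg$n_classes >= 2L,
    cfg$max_len_drug >= 1L, cfg$max_len_protein >= 1L,
    cfg$attention_heads_rows >= 1L,
    cfg$fc_dim %% (2L * cfg$attention_heads_rows) == 0L
  )
  structure(cfg, class = "dpi_model_config")
}

xavier <- function(fan_in, fan_out, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / (fan_in + fan_out))), dim = dims)
}

branch_cfg <- function(config, which) {
  if (which == "drug") {
    list(L = config$max_len_drug, k = config$filter_len_drug, prefix = "d_")
  } else {
    list(L = config$max_len_protein, k = config$filter_len_protein, prefix = "t_")
  }
}

init_branch_params <- function(config, vocab_size, which) {
  n <- config$n_filters_base
  e <- config$embed_dim
  z <- config$latent_dim
  b <- branch_cfg(config, which)
  k <- b$k; L <- b$L
  out_dim <- if (config$recon_mode == "categorical") vocab_size else e
  E <- xavier(vocab_size, e, c(vocab_size, e))
  E[1L, ] <- 0                               # pad embedding fixed at zero
  p <- list(
    emb = E,
    conv1_W = xavier(k * e, k * n, c(k, e, 2L * n)),          conv1_b = numeric(2L * n),
    conv2_W = xavier(k * n, k * 2L * n, c(k, n, 4L * n)),     conv2_b = numeric(4L * n),
    conv3_W = xavier(k * 2L * n, k * 3L * n, c(k, 2L * n, 6L * n)), conv3_b = numeric(6L * n),
    mu_W = xavier(3L * n, z, c(3L * n, z)),                   mu_b = numeric(z),
    # the log-variance head starts at -4 (sigma ~ 0.14): a near-deterministic
    # initial posterior keeps the sampled latent informative for the
    # prediction head from the first epochs; the KL term pulls sigma toward
    # the prior as training proceeds
    lv_W = xavier(3L * n, z, c(3L * n, z)),                   lv_b = rep(-4, z),
    seed_W = xavier(z, L * n, c(z, L * n)),                   seed_b = numeric(L * n),
    dec1_W = xavier(k * n, k * 3L * n, c(k, n, 3L * n)),      dec1_b = numeric(3L * n),
    dec2_W = xavier(k * 3L * n, k * 2L * n, c(k, 3L * n, 2L * n)), dec2_b = numeric(2L * n),
    dec3_W = xavier(k * 2L * n, k * n, c(k, 2L * n, n)),      dec3_b = numeric(n),
    out_W = xavier(n, out_dim, c(n, out_dim)),                out_b = numeric(out_dim),
    headf_W = xavier(z, config$fc_dim, c(z, config$fc_dim)),  headf_b = numeric(config$fc_dim)
  )
  names(p) <- paste0(b$prefix, names(p))
  p
}

#' Construct a dual-VAE interaction model
#'
#' Builds the full parameter set — per-branch embedding, three gated
#' convolutional encoder blocks (base, 2x, 3x filters), Gaussian latent
#' heads, a three-layer deconvolutional decoder with a position-wise output
#' map, per-branch head projections, and the shared three-layer prediction
#' head — initialized with the normalized-variance (Xavier normal) scheme
#' from a seeded generator.
#'
#' @param drug_vocab,protein_vocab `dpi_vocabulary` objects for the two
#'   branches.
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `dpi_model` list with `params`, `config`, `drug_vocab`,
#'   `protein_vocab`.
#' @export
dpi_model <- function(drug_vocab, protein_vocab, config = model_config(),
                      seed = 1L) {
  stopifnot(inherits(drug_vocab, "dpi_vocabulary"),
            inherits(protein_vocab, "dpi_vocabulary"),
            inherits(config, "dpi_model_config"))
  set.seed(seed)
  fc <- config$fc_dim
  params <- c(
    init_branch_params(config, drug_vocab$size, "drug"),
    init_branch_params(config, protein_vocab$size, "protein"),
    list(
      fc1_W = xavier(2L * fc, fc, c(2L * fc, fc)),      fc1_b = numeric(fc),
      fc2_W = xavier(fc, fc %/% 2L, c(fc, fc %/% 2L)),  fc2_b = numeric(fc %/% 2L),
      fc3_W = xavier(fc %/% 2L, config$n_classes, c(fc %/% 2L, config$n_classes)),
      fc3_b = numeric(config$n_classes)
    )
  )
  structure(list(params = params, config = config,
                 drug_vocab = drug_vocab, protein_vocab = protein_vocab,
                 init_seed = as.integer(seed)),
            class = "dpi_model")
}

#' @export
print.dpi_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("<dpi_model: %d parameters; filters %d/%dx/%dx, ",
                     "embed %d, latent %d, fc %d, %d classes>\n"),
              n_par, x$config$n_filters_base, 2L, 3L, x$config$embed_dim,
              x$config$latent_dim, x$config$fc_dim, x$config$n_classes))
  invisible(x)
}

#' Gated convolutional block
#'
#' Applies `ReLU(conv_A(x) * sigmoid(conv_B(x)))` with two independent
#' stride-1, same-padded filter banks, so the output keeps the input length.
#' With no `weights` supplied, Xavier-normal filters are drawn from the
#' current RNG state.
#'
#' @param features A length x channels numeric matrix.
#' @param n_filters Output channels.
#' @param filter_len Odd filter length.
#' @param weights Optional list `(W, b)`: `W` an array of dim
#'   `(filter_len, channels, 2 * n_filters)` holding bank A then bank B along
#'   the last margin, `b` a numeric vector of length `2 * n_filters`.
#' @return A length x n_filters matrix.
#' @export
gated_conv_block <- function(features, n_filters, filter_len, weights = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite input to gated_conv_block")
  stopifnot(filter_len %% 2L == 1L, n_filters >= 1L)
  C <- ncol(features)
  if (is.null(weights)) {
    weights <- list(
      W = xavier(filter_len * C, filter_len * n_filters,
                 c(filter_len, C, 2L * n_filters)),
      b = numeric(2L * n_filters)
    )
  }
  stopifnot(all(dim(weights$W) == c(filter_len, C, 2L * n_filters)))
  gated_conv_forward(features, weights$W, weights$b, 1L, nrow(features))$Y
}

as_token_matrix <- function(tok, max_len) {
  if (inherits(tok, "dpi_tokens")) {
    stopifnot(length(tok$indices) == max_len)
    list(indices = matrix(tok$indices, 1L), lengths = tok$original_length)
  } else if (is.matrix(tok)) {
    stopifnot(ncol(tok) == max_len)
    lens <- apply(tok, 1L, function(r) max(which(r != 0L), 1L))
    list(indices = tok, lengths = as.integer(lens))
  } else {
    stop("tok must be a dpi_tokens object or an integer matrix")
  }
}

# Batched encoder pipeline; returns mu/log_var matrices plus caches when
# keep_cache (training) is set.
encode_batch <- function(model, tokmat, lens, which, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  b <- branch_cfg(cfg, which)
  pf <- b$prefix
  B <- nrow(tokmat); L <- b$L
  idxvec <- as.vector(t(tokmat))
  X0 <- embed_forward(p[[paste0(pf, "emb")]], idxvec)
  g1 <- gated_conv_forward(X0, p[[paste0(pf, "conv1_W")]], p[[paste0(pf, "conv1_b")]], B, L)
  g2 <- gated_conv_forward(g1$Y, p[[paste0(pf, "conv2_W")]], p[[paste0(pf, "conv2_b")]], B, L)
  g3 <- gated_conv_forward(g2$Y, p[[paste0(pf, "conv3_W")]], p[[paste0(pf, "conv3_b")]], B, L)
  pool <- maxpool_forward(g3$Y, B, L, lens)
  mu <- dense_forward(pool$Y, p[[paste0(pf, "mu_W")]], p[[paste0(pf, "mu_b")]])
  lv <- dense_forward(pool$Y, p[[paste0(pf, "lv_W")]], p[[paste0(pf, "lv_b")]])
  out <- list(mu = mu, log_var = lv)
  if (keep_cache) {
    out$cache <- list(idxvec = idxvec, X0 = X0, g1 = g1, g2 = g2, g3 = g3,
                      pool = pool, B = B, L = L)
  }
  out
}

#' Encode a tokenized sequence to its Gaussian latent state
#'
#' Embedding lookup (pad embeds to the zero vector), three gated
#' convolutional blocks with filter counts (n, 2n, 3n), a pad-masked global
#' max pool over positions, and two parallel affine maps giving the
#' approximate posterior's mean and log-variance. Deterministic: no sampling
#' happens here.
#'
#' @param model A `dpi_model`.
#' @param tok A `dpi_tokens` from [tokenize()] with the branch's `max_len`.
#' @param which `"drug"` or `"protein"`.
#' @return A `dpi_latent` list with numeric vectors `mu` and `log_var` of
#'   length `latent_dim`.
#' @export
encode <- function(model, tok, which = c("drug", "protein")) {
  which <- match.arg(which)
  b <- branch_cfg(model$config, which)
  tm <- as_token_matrix(tok, b$L)
  enc <- encode_batch(model, tm$indices, tm$lengths, which)
  structure(list(mu = drop(enc$mu), log_var = drop(enc$log_var)),
            class = "dpi_latent")
}

#' Reparameterized sample from a latent state
#'
#' `z = mu + exp(log_var / 2) * epsilon`, elementwise — the standard
#' reparameterization trick making the sample differentiable in the
#' posterior parameters.
#'
#' @param latent A `dpi_latent` (or list with `mu`, `log_var`).
#' @param epsilon Standard-normal noise vector of length `latent_dim`;
#'   `epsilon = 0` returns the posterior mean.
#' @return Numeric vector `z`.
#' @export
reparameterize <- function(latent, epsilon) {
  mu <- latent$mu; lv <- latent$log_var
  if (length(epsilon) == 1L) epsilon <- rep(epsilon, length(mu))
  if (length(epsilon) != length(mu)) {
    stop("epsilon length must equal latent_dim")
  }
  mu + exp(0.5 * lv) * epsilon
}

decode_batch <- function(model, Z, which, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  b <- branch_cfg(cfg, which)
  pf <- b$prefix
  n <- cfg$n_filters_base
  B <- nrow(Z); L <- b$L
  s_pre <- dense_forward(Z, p[[paste0(pf, "seed_W")]], p[[paste0(pf, "seed_b")]])
  s_act <- relu_forward(s_pre)
  X0 <- seed_to_seq(s_act, B, L, n)
  d1 <- conv1d_forward(X0, p[[paste0(pf, "dec1_W")]], p[[paste0(pf, "dec1_b")]], B, L)
  a1 <- relu_forward(d1$Y)
  d2 <- conv1d_forward(a1, p[[paste0(pf, "dec2_W")]], p[[paste0(pf, "dec2_b")]], B, L)
  a2 <- relu_forward(d2$Y)
  d3 <- conv1d_forward(a2, p[[paste0(pf, "dec3_W")]], p[[paste0(pf, "dec3_b")]], B, L)
  a3 <- relu_forward(d3$Y)
  out <- dense_forward(a3, p[[paste0(pf, "out_W")]], p[[paste0(pf, "out_b")]])
  res <- list(scores = out)
  if (keep_cache) {
    res$cache <- list(s_act = s_act, X0 = X0, d1 = d1, a1 = a1, d2 = d2,
                      a2 = a2, d3 = d3, a3 = a3, B = B, L = L)
  }
  res
}

#' Decode a latent vector to position-wise reconstruction scores
#'
#' An affine expansion of `z` seeds a full-length sequence of base-filter
#' channels; three transposed-convolution layers (filter counts 3n, 2n, n,
#' realized in their stride-1 convolution form) with ReLU refine it, and a
#' position-wise affine map scores each position against the branch
#' vocabulary (or the embedding space under `recon_mode =
#' "gaussian_embedding"`).
#'
#' @param model A `dpi_model`.
#' @param z Numeric latent vector of length `latent_dim`.
#' @param which `"drug"` or `"protein"`.
#' @return A `max_len` x `vocab_size` (or `embed_dim`) numeric matrix.
#' @export
decode <- function(model, z, which = c("drug", "protein")) {
  which <- match.arg(which)
  stopifnot(length(z) == model$config$latent_dim)
  decode_batch(model, matrix(z, 1L), which)$scores
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / scale) V` with row-wise softmax, so each output row is a
#' convex combination of `V`'s rows. The default scale is `sqrt(d_k)`;
#' `scale = "linear"` divides by `d_k` instead.
#'
#' @param Q n x d_k query matrix.
#' @param K m x d_k key matrix.
#' @param V m x d_v value matrix.
#' @param scale `"sqrt"` or `"linear"`.
#' @return n x d_v output matrix, with the n x m softmax weights attached as
#'   attribute `"weights"`.
#' @export
attention <- function(Q, K, V, scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d_k <- ncol(Q)
  if (d_k == 0L) stop("d_k must be positive")
  if (ncol(K) != d_k) stop("Q and K must share their second dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share their first dimension")
  s <- if (scale == "sqrt") sqrt(d_k) else d_k
  P <- row_softmax(Q %*% t(K) / s)
  structure(P %*% V, weights = P)
}

# Head forward over batched latents; loops the tiny per-sample attention.
head_forward <- function(model, Zd, Zt, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  h <- cfg$attention_heads_rows
  d <- cfg$fc_dim %/% h
  B <- nrow(Zd)
  fd <- dense_forward(Zd, p$d_headf_W, p$d_headf_b)
  ft <- dense_forward(Zt, p$t_headf_W, p$t_headf_b)
  ad <- matrix(0, B, cfg$fc_dim); at <- matrix(0, B, cfg$fc_dim)
  attn_d <- vector("list", B); attn_t <- vector("list", B)
  for (i in seq_len(B)) {
    Md <- matrix(fd[i, ], h, d, byrow = TRUE)
    Mt <- matrix(ft[i, ], h, d, byrow = TRUE)
    sa_d <- self_attention_forward(Md, cfg$attention_scale)
    sa_t <- self_attention_forward(Mt, cfg$attention_scale)
    ad[i, ] <- as.vector(t(sa_d$Y))
    at[i, ] <- as.vector(t(sa_t$Y))
    if (keep_cache) { attn_d[[i]] <- sa_d; attn_t[[i]] <- sa_t }
  }
  cc <- cbind(ad, at)
  h1_pre <- dense_forward(cc, p$fc1_W, p$fc1_b)
  h1 <- relu_forward(h1_pre)
  dr1 <- dropout_forward(h1, cfg$dropout_rate, training)
  h2_pre <- dense_forward(dr1$Y, p$fc2_W, p$fc2_b)
  h2 <- relu_forward(h2_pre)
  dr2 <- dropout_forward(h2, cfg$dropout_rate, training)
  logits <- dense_forward(dr2$Y, p$fc3_W, p$fc3_b)
  out <- list(logits = logits)
  if (keep_cache) {
    out$cache <- list(fd = fd, ft = ft, ad = ad, at = at, attn_d = attn_d,
                      attn_t = attn_t, cc = cc, h1 = h1, dr1 = dr1, h2 = h2,
                      dr2 = dr2, h = h, d = d, B = B)
  }
  out
}

#' Score an interaction from the two latent feature vectors
#'
#' Per branch: an affine map to `fc_dim`, scaled dot-product self-attention
#' over the feature reshaped as an `attention_heads_rows`-row matrix, then
#' flattening; the branches are concatenated and passed through
#' FC + ReLU + dropout twice and a final affine map to class scores. Dropout
#' is disabled outside training, so inference is deterministic.
#'
#' @param model A `dpi_model`.
#' @param feat_drug,feat_protein Latent feature vectors (length
#'   `latent_dim`).
#' @param training Enable dropout (draws from the session RNG).
#' @return Numeric vector of `n_classes` scores (logits).
#' @export
predict_head <- function(model, feat_drug, feat_protein, training = FALSE) {
  drop(head_forward(model, matrix(feat_drug, 1L), matrix(feat_protein, 1L),
                    training = training)$logits)
}

#' Full forward pass for one drug-protein pair
#'
#' Composes encode, reparameterized sampling, per-branch decoding, and the
#' prediction head. With both epsilons fixed the pass is fully
#' deterministic; `epsilon = 0` gives the mean pass used at evaluation.
#'
#' @param model A `dpi_model`.
#' @param drug_tok,prot_tok `dpi_tokens` for the two branches.
#' @param epsilon_d,epsilon_t Noise vectors (length `latent_dim`) or the
#'   scalar 0.
#' @return A list: `scores` (class logits), `probabilities` (softmax),
#'   `recon_drug`, `recon_protein`, `latent_drug`, `latent_protein`, `z_drug`,
#'   `z_protein`.
#' @export
dpi_forward <- function(model, drug_tok, prot_tok, epsilon_d = 0,
                        epsilon_t = 0) {
  lat_d <- encode(model, drug_tok, "drug")
  lat_t <- encode(model, prot_tok, "protein")
  z_d <- reparameterize(lat_d, epsilon_d)
  z_t <- reparameterize(lat_t, epsilon_t)
  logits <- predict_head(model, z_d, z_t)
  pr <- drop(row_softmax(matrix(logits, 1L)))
  list(
    scores = logits,
    probabilities = pr,
    recon_drug = decode(model, z_d, "drug"),
    recon_protein = decode(model, z_t, "protein"),
    latent_drug = lat_d,
    latent_protein = lat_t,
    z_drug = z_d,
    z_protein = z_t
  )
}

# Fast batched inference: encode both branches at the mean (epsilon = 0) and
# run the head; decoders skipped. Returns the softmax probability matrix.
predict_batch <- function(model, drug_mat, drug_lens, prot_mat, prot_lens) {
  enc_d <- encode_batch(model, drug_mat, drug_lens, "drug")
  enc_t <- encode_batch(model, prot_mat, prot_lens, "protein")
  logits <- head_forward(model, enc_d$mu, enc_t$mu)$logits
  row_softmax(logits)
}
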