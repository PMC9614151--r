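# One training step: forward pass through both VAE branches and the
# prediction head, loss assembly, and analytic gradients for every
# parameter. Gradients are exact (verified against finite differences in the
# test suite). All stochastic elements (epsilon draws, dropout masks) come
# from the session RNG so a seeded run is fully reproducible.

branch_forward_train <- function(model, tokmat, lens, which, vae_weight) {
  cfg <- model$config
  enc <- encode_batch(model, tokmat, lens, which, keep_cache = TRUE)
  B <- nrow(tokmat)
  zd <- cfg$latent_dim
  eps <- matrix(stats::rnorm(B * zd), B, zd)
  sig <- exp(0.5 * enc$log_var)
  Z <- enc$mu + sig * eps
  kl <- 0.5 * sum(exp(enc$log_var) + enc$mu^2 - 1 - enc$log_var) / B
  if (vae_weight == 0) {
    # ablation mode: the generative pathway carries no gradient, so the
    # decoder pass is skipped entirely and no reconstruction is scored
    return(list(enc = enc, dec = NULL, eps = eps, sig = sig, Z = Z, kl = kl,
                recon = 0, dOut = NULL, dX0_extra = NULL, B = B))
  }
  dec <- decode_batch(model, Z, which, keep_cache = TRUE)

  idxvec <- enc$cache$idxvec
  keep <- idxvec != 0L
  w_row <- (1 / lens[rep(seq_len(B), each = enc$cache$L)])[keep]
  if (cfg$recon_mode == "categorical") {
    P <- row_softmax(dec$scores[keep, , drop = FALSE])
    p_true <- P[cbind(seq_len(sum(keep)), idxvec[keep])]
    recon <- sum(-log(pmax(p_true, 1e-300)) * w_row) / B
    dOut <- matrix(0, nrow(dec$scores), ncol(dec$scores))
    G <- P
    G[cbind(seq_len(sum(keep)), idxvec[keep])] <-
      G[cbind(seq_len(sum(keep)), idxvec[keep])] - 1
    dOut[keep, ] <- G * (w_row * vae_weight / B)
    dX0_extra <- NULL
  } else {
    Tgt <- enc$cache$X0
    diff <- dec$scores - Tgt
    recon <- sum(0.5 * rowSums(diff[keep, , drop = FALSE]^2) * w_row) / B
    dOut <- matrix(0, nrow(dec$scores), ncol(dec$scores))
    dOut[keep, ] <- diff[keep, , drop = FALSE] * (w_row * vae_weight / B)
    dX0_extra <- -dOut                      # gradient through the target
  }
  list(enc = enc, dec = dec, eps = eps, sig = sig, Z = Z, kl = kl,
       recon = recon, dOut = dOut, dX0_extra = dX0_extra, B = B)
}

branch_backward <- function(model, fw, dZ_head, which, vae_weight, grads) {
  cfg <- model$config
  p <- model$params
  pf <- branch_cfg(cfg, which)$prefix
  n <- cfg$n_filters_base
  B <- fw$B
  L <- fw$enc$cache$L
  g <- function(nm) paste0(pf, nm)

  if (is.null(fw$dec)) {
    # ablation mode: decoder grads stay zero
    for (nm in c("out_W", "out_b", "dec3_W", "dec3_b", "dec2_W", "dec2_b",
                 "dec1_W", "dec1_b", "seed_W", "seed_b")) {
      grads[[g(nm)]] <- 0 * p[[g(nm)]]
    }
    dZ <- dZ_head
  } else {
    dZ <- NULL                                  # filled below
  }

  # ---- decoder backward -> dZ_dec ----
  if (!is.null(fw$dec)) {
  dc <- fw$dec$cache
  d_out <- dense_backward(fw$dOut, dc$a3, p[[g("out_W")]])
  grads[[g("out_W")]] <- d_out$dW; grads[[g("out_b")]] <- d_out$db
  dd3 <- relu_backward(d_out$dX, dc$a3)
  b3 <- conv1d_backward(dd3, p[[g("dec3_W")]], dc$d3)
  grads[[g("dec3_W")]] <- b3$dW; grads[[g("dec3_b")]] <- b3$db
  dd2 <- relu_backward(b3$dX, dc$a2)
  b2 <- conv1d_backward(dd2, p[[g("dec2_W")]], dc$d2)
  grads[[g("dec2_W")]] <- b2$dW; grads[[g("dec2_b")]] <- b2$db
  dd1 <- relu_backward(b2$dX, dc$a1)
  b1 <- conv1d_backward(dd1, p[[g("dec1_W")]], dc$d1)
  grads[[g("dec1_W")]] <- b1$dW; grads[[g("dec1_b")]] <- b1$db
  ds_act <- seq_to_seed(b1$dX, B, L, n)
  ds_pre <- relu_backward(ds_act, dc$s_act)
  d_seed <- dense_backward(ds_pre, fw$Z, p[[g("seed_W")]])
  grads[[g("seed_W")]] <- d_seed$dW; grads[[g("seed_b")]] <- d_seed$db
  dZ <- d_seed$dX + dZ_head
  }

  # ---- latent gradients (decoder + head + KL) ----
  dmu <- dZ + vae_weight * fw$enc$mu / B
  dlv <- dZ * fw$eps * 0.5 * fw$sig +
    vae_weight * 0.5 * (exp(fw$enc$log_var) - 1) / B

  # ---- encoder backward ----
  ec <- fw$enc$cache
  d_mu <- dense_backward(dmu, ec$pool$Y, p[[g("mu_W")]])
  d_lv <- dense_backward(dlv, ec$pool$Y, p[[g("lv_W")]])
  grads[[g("mu_W")]] <- d_mu$dW; grads[[g("mu_b")]] <- d_mu$db
  grads[[g("lv_W")]] <- d_lv$dW; grads[[g("lv_b")]] <- d_lv$db
  dg3 <- maxpool_backward(d_mu$dX + d_lv$dX, ec$pool)
  c3 <- gated_conv_backward(dg3, p[[g("conv3_W")]], ec$g3)
  grads[[g("conv3_W")]] <- c3$dW; grads[[g("conv3_b")]] <- c3$db
  c2 <- gated_conv_backward(c3$dX, p[[g("conv2_W")]], ec$g2)
  grads[[g("conv2_W")]] <- c2$dW; grads[[g("conv2_b")]] <- c2$db
  c1 <- gated_conv_backward(c2$dX, p[[g("conv1_W")]], ec$g1)
  grads[[g("conv1_W")]] <- c1$dW; grads[[g("conv1_b")]] <- c1$db
  dX0 <- c1$dX
  if (!is.null(fw$dX0_extra)) dX0 <- dX0 + fw$dX0_extra
  grads[[g("emb")]] <- embed_backward(dX0, ec$idxvec,
                                      nrow(p[[g("emb")]]))
  grads
}

# Full forward + backward on one minibatch. batch: list(drug_mat, drug_lens,
# prot_mat, prot_lens, y) with 0-based labels. Returns loss breakdown and a
# gradient list aligned with model$params.
train_step <- function(model, batch, lambda, vae_weight, training = TRUE) {
  cfg <- model$config
  p <- model$params
  B <- length(batch$y)

  fd <- branch_forward_train(model, batch$drug_mat, batch$drug_lens,
                             "drug", vae_weight)
  ft <- branch_forward_train(model, batch$prot_mat, batch$prot_lens,
                             "protein", vae_weight)
  hd <- head_forward(model, fd$Z, ft$Z, training = training,
                     keep_cache = TRUE)
  hc <- hd$cache

  Pr <- row_softmax(hd$logits)
  iy <- cbind(seq_len(B), batch$y + 1L)
  ce <- -mean(log(pmax(Pr[iy], 1e-300)))
  l2 <- lambda * l2_sum(p)
  kl_sum <- fd$kl + ft$kl
  recon_sum <- fd$recon + ft$recon
  total <- ce + l2 + vae_weight * (kl_sum + recon_sum)
  if (!is.finite(total)) {
    stop(sprintf(
      "non-finite loss (ce=%.4g kl=%.4g recon=%.4g l2=%.4g): training diverged",
      ce, kl_sum, recon_sum, l2))
  }

  # ---- head backward ----
  grads <- vector("list", length(p)); names(grads) <- names(p)
  dlogits <- Pr
  dlogits[iy] <- dlogits[iy] - 1
  dlogits <- dlogits / B
  d3 <- dense_backward(dlogits, hc$dr2$Y, p$fc3_W)
  grads$fc3_W <- d3$dW; grads$fc3_b <- d3$db
  dh2 <- relu_backward(dropout_backward(d3$dX, hc$dr2$mask), hc$h2)
  d2 <- dense_backward(dh2, hc$dr1$Y, p$fc2_W)
  grads$fc2_W <- d2$dW; grads$fc2_b <- d2$db
  dh1 <- relu_backward(dropout_backward(d2$dX, hc$dr1$mask), hc$h1)
  d1 <- dense_backward(dh1, hc$cc, p$fc1_W)
  grads$fc1_W <- d1$dW; grads$fc1_b <- d1$db
  fc <- cfg$fc_dim
  dad <- d1$dX[, seq_len(fc), drop = FALSE]
  dat <- d1$dX[, fc + seq_len(fc), drop = FALSE]
  h <- hc$h; d <- hc$d
  dfd <- matrix(0, B, fc); dft <- matrix(0, B, fc)
  for (i in seq_len(B)) {
    Md <- matrix(hc$fd[i, ], h, d, byrow = TRUE)
    Mt <- matrix(hc$ft[i, ], h, d, byrow = TRUE)
    dMd <- self_attention_backward(matrix(dad[i, ], h, d, byrow = TRUE),
                                   Md, hc$attn_d[[i]])
    dMt <- self_attention_backward(matrix(dat[i, ], h, d, byrow = TRUE),
                                   Mt, hc$attn_t[[i]])
    dfd[i, ] <- as.vector(t(dMd))
    dft[i, ] <- as.vector(t(dMt))
  }
  dhd <- dense_backward(dfd, fd$Z, p$d_headf_W)
  dht <- dense_backward(dft, ft$Z, p$t_headf_W)
  grads$d_headf_W <- dhd$dW; grads$d_headf_b <- dhd$db
  grads$t_headf_W <- dht$dW; grads$t_headf_b <- dht$db

  grads <- branch_backward(model, fd, dhd$dX, "drug", vae_weight, grads)
  grads <- branch_backward(model, ft, dht$dX, "protein", vae_weight, grads)

  if (lambda > 0) {
    for (nm in names(p)) {
      if (!grepl("_b$", nm)) grads[[nm]] <- grads[[nm]] + 2 * lambda * p[[nm]]
    }
  }

  list(
    losses = list(kl_drug = fd$kl, kl_protein = ft$kl,
                  recon_drug = fd$recon, recon_protein = ft$recon,
                  prediction_ce = ce, l2_penalty = l2, total = total),
    grads = grads
  )
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) array(0, dim = dim_or_len(x))),
       v = lapply(params, function(x) array(0, dim = dim_or_len(x))),
       t = 0L)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
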