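# Shared fixtures: tiny vocabularies, a desk-scale model configuration, and
# small synthetic datasets, all built in code at test time.

tiny_vocabs <- function() {
  list(drug = build_vocabulary(c("CNO(=)", "cn1"), "drug"),
       protein = build_vocabulary(c("ACDEFGHIKL"), "protein"))
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_filters_base = 2L, filter_len_drug = 3L, filter_len_protein = 3L,
         embed_dim = 3L, latent_dim = 4L, fc_dim = 8L, dropout_rate = 0,
         n_classes = 2L, max_len_drug = 6L, max_len_protein = 7L,
         attention_heads_rows = 2L),
    list(...))
  do.call(model_config, args)
}

tiny_model <- function(seed = 7L, cfg = tiny_config()) {
  v <- tiny_vocabs()
  dpi_model(v$drug, v$protein, cfg, seed = seed)
}

tiny_batch <- function() {
  b <- list(
    drug_mat = rbind(c(1L, 2L, 3L, 1L, 0L, 0L),
                     c(2L, 2L, 1L, 4L, 5L, 1L),
                     c(3L, 1L, 0L, 0L, 0L, 0L)),
    drug_lens = c(4L, 6L, 2L),
    prot_mat = rbind(c(1L, 2L, 3L, 4L, 5L, 1L, 2L),
                     c(2L, 1L, 2L, 0L, 0L, 0L, 0L),
                     c(5L, 4L, 3L, 2L, 1L, 1L, 0L)),
    prot_lens = c(7L, 3L, 6L),
    y = c(1L, 0L, 1L))
  b
}

# A small, quickly learnable synthetic study (short proteins, no noise).
small_study <- function(n_pairs = 300L, label_noise = 0, seed = 1L) {
  spec <- synthetic_spec(n_drugs = 40L, n_proteins = 40L, n_pairs = n_pairs,
                         protein_len_range = c(50L, 100L),
                         label_noise = label_noise, seed = seed)
  generate_dpi_dataset(spec)
}

small_model_config <- function(max_len_protein = 100L) {
  model_config(n_filters_base = 8L, embed_dim = 16L, latent_dim = 16L,
               fc_dim = 64L, max_len_drug = 60L,
               max_len_protein = max_len_protein, attention_heads_rows = 4L)
}

# Brute-force AUC by pair enumeration (ties count one half).
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force two-loop scaled dot-product attention.
brute_attention <- function(Q, K, V, scale = "sqrt") {
  d_k <- ncol(Q)
  s <- if (scale == "sqrt") sqrt(d_k) else d_k
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    logits <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) logits[j] <- sum(Q[i, ] * K[j, ]) / s
    w <- exp(logits - max(logits)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}
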