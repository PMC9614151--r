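test_that("gated conv block honors its contracts", {
  # zero input with zero biases stays zero: ReLU(0 * sigmoid(0)) = 0
  z <- matrix(0, 10, 3)
  w0 <- list(W = array(rnorm(5 * 3 * 8), c(5, 3, 8)) * 0.1, b = numeric(8))
  expect_true(all(gated_conv_block(z, 4L, 5L, w0) == 0))

  # same-padding keeps length for both standard filter lengths
  set.seed(51)
  x <- matrix(rnorm(24), 12, 2)
  for (k in c(5L, 7L)) {
    expect_equal(dim(gated_conv_block(x, 3L, k)), c(12L, 3L))
  }

  # identity bank A + saturated gate reduces the block to ReLU(features)
  xf <- matrix(rnorm(18), 9, 2)
  W <- array(0, c(1, 2, 4))
  W[1, 1, 1] <- 1; W[1, 2, 2] <- 1            # bank A = identity on 2 channels
  wid <- list(W = W, b = c(0, 0, 50, 50))     # bank B bias -> sigmoid ~ 1
  expect_equal(gated_conv_block(xf, 2L, 1L, wid), xf * (xf > 0),
               tolerance = 1e-12)

  expect_error(gated_conv_block(matrix(c(1, NaN), 2, 1), 2L, 1L), "non-finite")
})

test_that("encode is deterministic with the right shapes", {
  m <- tiny_model()
  v <- tiny_vocabs()
  tk <- tokenize("CNO", v$drug, m$config$max_len_drug)
  l1 <- encode(m, tk, "drug")
  l2 <- encode(m, tk, "drug")
  expect_identical(l1, l2)
  expect_length(l1$mu, m$config$latent_dim)
  expect_length(l1$log_var, m$config$latent_dim)
})

test_that("padding amount does not change the latent state", {
  # the same sequence, embedded at two different max_lens, encodes
  # identically once the extra columns are pure padding
  v <- tiny_vocabs()
  cfg_a <- tiny_config()
  cfg_b <- tiny_config(max_len_drug = 12L)
  m_a <- dpi_model(v$drug, v$protein, cfg_a, seed = 3)
  m_b <- dpi_model(v$drug, v$protein, cfg_b, seed = 3)
  # same branch weights: copy the drug branch from m_a
  for (nm in grep("^d_", names(m_a$params), value = TRUE)) {
    if (nm == "d_seed_W" || nm == "d_seed_b") next   # decoder depends on L
    m_b$params[[nm]] <- m_a$params[[nm]]
  }
  tk_a <- tokenize("CNO", v$drug, cfg_a$max_len_drug)
  tk_b <- tokenize("CNO", v$drug, cfg_b$max_len_drug)
  la <- encode(m_a, tk_a, "drug")
  lb <- encode(m_b, tk_b, "drug")
  expect_equal(la$mu, lb$mu, tolerance = 1e-12)
  expect_equal(la$log_var, lb$log_var, tolerance = 1e-12)
})

test_that("reparameterize recovers the posterior moments", {
  lat <- list(mu = c(1, -1), log_var = 2 * log(c(0.5, 2)))
  expect_identical(reparameterize(lat, 0), c(1, -1))
  expect_identical(reparameterize(list(mu = c(0, 0), log_var = c(0, 0)),
                                  c(0.3, -0.7)), c(0.3, -0.7))
  expect_error(reparameterize(lat, c(1, 2, 3)), "length")

  set.seed(52)
  n <- 1e5
  eps <- matrix(rnorm(2 * n), n, 2)
  z <- t(apply(eps, 1, function(e) reparameterize(lat, e)))
  sig <- c(0.5, 2)
  se_mean <- sig / sqrt(n)
  se_sd <- sig / sqrt(2 * (n - 1))
  expect_true(all(abs(colMeans(z) - lat$mu) <= 3 * se_mean))
  expect_true(all(abs(apply(z, 2, sd) - sig) <= 3 * se_sd))
})

test_that("decode produces branch-shaped deterministic reconstructions", {
  m <- tiny_model()
  z <- rnorm(m$config$latent_dim)
  r1 <- decode(m, z, "drug")
  expect_equal(dim(r1), c(m$config$max_len_drug, m$drug_vocab$size))
  expect_identical(r1, decode(m, z, "drug"))
  r2 <- decode(m, z, "protein")
  expect_equal(dim(r2), c(m$config$max_len_protein, m$protein_vocab$size))
})

test_that("a one-layer decoder analogue matches hand arithmetic", {
  # latent 2 -> seed length 4 x 1 channel -> single 1-tap deconv -> vocab 3:
  # every step collapses to explicit affine maps we can compute by hand
  v <- list(drug = build_vocabulary("C", "drug"),
            protein = build_vocabulary("A", "protein"))
  cfg <- model_config(n_filters_base = 1L, filter_len_drug = 1L,
                      filter_len_protein = 1L, embed_dim = 2L, latent_dim = 2L,
                      fc_dim = 4L, dropout_rate = 0, max_len_drug = 4L,
                      max_len_protein = 4L, attention_heads_rows = 2L)
  m <- dpi_model(v$drug, v$protein, cfg, seed = 5)
  p <- m$params
  z <- c(0.7, -0.3)
  seed_vec <- pmax(drop(z %*% p$d_seed_W) + p$d_seed_b, 0)      # length 4
  h <- matrix(seed_vec, 4, 1)
  for (nm in c("d_dec1", "d_dec2", "d_dec3")) {
    W <- p[[paste0(nm, "_W")]]
    Wmat <- matrix(W[1, , ], nrow = dim(W)[2])   # 1-tap conv = affine map
    hnew <- h %*% Wmat +
      matrix(p[[paste0(nm, "_b")]], 4, dim(W)[3], byrow = TRUE)
    h <- pmax(hnew, 0)
  }
  manual <- h %*% p$d_out_W + matrix(p$d_out_b, 4, 3, byrow = TRUE)
  expect_equal(unname(decode(m, z, "drug")), unname(manual), tolerance = 1e-12)
})

test_that("attention satisfies its exact special cases", {
  # single key: the softmax of a singleton is 1, output = V's row
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(0.4, -1), 1, 2)
  V <- matrix(c(2.5, -3), 1, 2)
  out <- attention(Q, K, V)
  expect_equal(unname(out), matrix(rep(c(2.5, -3), each = 3), 3, 2),
               ignore_attr = TRUE)

  # identical keys: uniform weights, every row = column mean of V
  K2 <- matrix(1, 4, 2)
  V2 <- matrix(rnorm(8), 4, 2)
  out2 <- attention(matrix(rnorm(4), 2, 2), K2, V2)
  expect_equal(out2[1, ], colMeans(V2), ignore_attr = TRUE)
  expect_equal(out2[2, ], colMeans(V2), ignore_attr = TRUE)

  # two-key worked example: weight sigma-like split at 1/sqrt(2)
  out3 <- attention(matrix(c(1, 0), 1, 2), rbind(c(1, 0), c(0, 1)),
                    matrix(c(1, 0), 2, 1))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(out3[1, 1], w1, tolerance = 1e-9)
  expect_equal(w1, 0.6698, tolerance = 1e-4)

  expect_error(attention(matrix(0, 1, 0), matrix(0, 1, 0), matrix(1, 1, 1)),
               "d_k")
})

test_that("attention equals the brute-force oracle with convex rows", {
  set.seed(53)
  for (i in 1:40) {
    n <- sample(1:8, 1); m_ <- sample(1:8, 1)
    dk <- sample(1:8, 1); dv <- sample(1:8, 1)
    Q <- matrix(rnorm(n * dk), n, dk)
    K <- matrix(rnorm(m_ * dk), m_, dk)
    V <- matrix(rnorm(m_ * dv), m_, dv)
    for (sc in c("sqrt", "linear")) {
      out <- attention(Q, K, V, scale = sc)
      expect_equal(unname(unclass(out)), brute_attention(Q, K, V, sc),
                   tolerance = 1e-6, ignore_attr = TRUE)
      W <- attr(out, "weights")
      expect_equal(rowSums(W), rep(1, n), tolerance = 1e-12)
      for (j in seq_len(dv)) {                   # convex-combination bounds
        expect_true(all(out[, j] >= min(V[, j]) - 1e-12))
        expect_true(all(out[, j] <= max(V[, j]) + 1e-12))
      }
    }
  }
})

test_that("prediction head output is class-shaped, normalized and pure at eval", {
  m <- tiny_model()
  zd <- rnorm(m$config$latent_dim); zt <- rnorm(m$config$latent_dim)
  s1 <- predict_head(m, zd, zt)
  expect_length(s1, m$config$n_classes)
  expect_identical(s1, predict_head(m, zd, zt))
  p <- exp(s1 - max(s1)); p <- p / sum(p)
  expect_equal(sum(p), 1)
})

test_that("the full forward pass is deterministic with fixed epsilons", {
  m <- tiny_model()
  v <- tiny_vocabs()
  dt <- tokenize("CNO(", v$drug, m$config$max_len_drug)
  pt <- tokenize("ACDEF", v$protein, m$config$max_len_protein)
  e_d <- rnorm(m$config$latent_dim); e_t <- rnorm(m$config$latent_dim)
  f1 <- dpi_forward(m, dt, pt, e_d, e_t)
  f2 <- dpi_forward(m, dt, pt, e_d, e_t)
  expect_identical(f1, f2)                      # bitwise-stable
  expect_equal(dim(f1$recon_drug), c(m$config$max_len_drug, m$drug_vocab$size))
  expect_equal(dim(f1$recon_protein),
               c(m$config$max_len_protein, m$protein_vocab$size))
  expect_equal(sum(f1$probabilities), 1)

  # epsilon = 0 is the mean pass
  f0 <- dpi_forward(m, dt, pt, 0, 0)
  expect_equal(f0$z_drug, f0$latent_drug$mu)
  expect_equal(f0$scores,
               predict_head(m, f0$latent_drug$mu, f0$latent_protein$mu))
})

test_that("encode/decode shape contracts hold across a configuration grid", {
  for (L in c(5L, 9L)) for (zdim in c(3L, 6L)) {
    v <- list(d = build_vocabulary("CNO", "drug"),
              p = build_vocabulary("ACDEFG", "protein"))
    cfg <- model_config(n_filters_base = 2L, filter_len_drug = 3L,
                        filter_len_protein = 3L, embed_dim = 3L,
                        latent_dim = zdim, fc_dim = 8L, dropout_rate = 0,
                        max_len_drug = L, max_len_protein = L + 2L,
                        attention_heads_rows = 2L)
    m <- dpi_model(v$d, v$p, cfg, seed = 2)
    lat <- encode(m, tokenize("CON", v$d, L), "drug")
    expect_length(lat$mu, zdim)
    expect_equal(dim(decode(m, lat$mu, "drug")), c(L, v$d$size))
    expect_equal(dim(decode(m, rnorm(zdim), "protein")), c(L + 2L, v$p$size))
  }
})

test_that("analytic gradients match finite differences", {
  # biases lifted so ReLU/max-pool operate away from their kinks, where the
  # objective is differentiable and central differences are exact
  m <- tiny_model(seed = 7L)
  for (nm in grep("(conv[0-9]|dec[0-9]|seed)_b$", names(m$params), value = TRUE)) {
    m$params[[nm]] <- m$params[[nm]] + 0.3
  }
  b <- tiny_batch()
  loss_at <- function(mm) {
    set.seed(99)
    train_step(mm, b, lambda = 0.01, vae_weight = 0.7, training = TRUE)$losses$total
  }
  set.seed(99)
  st <- train_step(m, b, lambda = 0.01, vae_weight = 0.7, training = TRUE)
  set.seed(123)
  h <- 1e-5
  for (nm in names(m$params)) {
    n_try <- min(4L, length(m$params[[nm]]))
    idx <- sample(length(m$params[[nm]]), n_try)
    if (grepl("emb$", nm)) {                    # pad row is frozen at zero
      nr <- nrow(m$params[[nm]])
      idx <- idx[((idx - 1L) %% nr) + 1L != 1L]
    }
    for (j in idx) {
      m_p <- m; m_p$params[[nm]][j] <- m_p$params[[nm]][j] + h
      m_m <- m; m_m$params[[nm]][j] <- m_m$params[[nm]][j] - h
      num <- (loss_at(m_p) - loss_at(m_m)) / (2 * h)
      expect_equal(st$grads[[nm]][j], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, j))
    }
  }
})
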