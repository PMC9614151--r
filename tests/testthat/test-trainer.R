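test_that("train_config validates its fields", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$batch_size, 256L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$lambda_l2, 1e-3)
  expect_error(train_config(learning_rate = 0), "not all TRUE|learning_rate")
  expect_error(train_config(split_fractions = c(0.5, 0.5, 0.5)),
               "not all TRUE|fractions")
})

test_that("make_splits partitions deterministically at the requested sizes", {
  recs <- data.frame(drug = paste0("D", 1:10), protein = paste0("P", 1:10),
                     label = rep(0:1, 5), stringsAsFactors = FALSE)
  sp <- make_splits(recs, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(vapply(sp, nrow, 1L), c(train = 8L, val = 1L, test = 1L))

  sp2 <- make_splits(recs, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(sp, sp2)

  # union = input multiset, pairwise intersections empty
  key <- function(d) paste(d$drug, d$protein, d$label)
  all_keys <- sort(unname(unlist(lapply(sp, key))))
  expect_identical(all_keys, sort(key(recs)))
  expect_length(intersect(key(sp$train), key(sp$val)), 0L)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)

  expect_error(make_splits(recs[1:3, ], c(0.8, 0.1, 0.1)), "too few")
})

test_that("duplicate records never straddle two splits", {
  recs <- data.frame(drug = rep(paste0("D", 1:10), each = 2),
                     protein = rep(paste0("P", 1:10), each = 2),
                     label = rep(rep(0:1, 5), each = 2),
                     stringsAsFactors = FALSE)
  sp <- make_splits(recs, c(0.6, 0.2, 0.2), seed = 1)
  key <- function(d) unique(paste(d$drug, d$protein, d$label))
  expect_length(intersect(key(sp$train), key(sp$val)), 0L)
  expect_length(intersect(key(sp$val), key(sp$test)), 0L)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
})

test_that("training is reproducible and tracks its best epoch", {
  data <- small_study(n_pairs = 120L)
  splits <- make_splits(data$pairs, c(0.7, 0.15, 0.15), seed = 1)
  dv <- build_vocabulary(data$sequences$drugs, "drug")
  pv <- build_vocabulary(data$sequences$proteins, "protein")
  cfg <- small_model_config()
  tcfg <- train_config(epochs = 4L, batch_size = 32L, patience = 4L, seed = 3L)

  fit1 <- train_dpi(dpi_model(dv, pv, cfg, seed = 3), splits, tcfg)
  fit2 <- train_dpi(dpi_model(dv, pv, cfg, seed = 3), splits, tcfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  # the retained state's validation accuracy equals the history's maximum
  expect_equal(fit1$best_val_acc, max(fit1$history$val_acc))
  expect_equal(fit1$history$val_acc[fit1$best_epoch], fit1$best_val_acc)
  ds <- dpivae:::prepare_dataset(splits$val, dv, pv, cfg)
  probs <- dpivae:::predict_dataset(fit1$model, ds)
  expect_equal(mean(max.col(probs, ties.method = "first") - 1L == ds$y),
               fit1$best_val_acc)
})

test_that("a 32-record subset is memorized with the supervised loss alone", {
  data <- small_study(n_pairs = 150L, seed = 1L)
  recs <- data$pairs[1:32, ]
  dv <- build_vocabulary(data$sequences$drugs, "drug")
  pv <- build_vocabulary(data$sequences$proteins, "protein")
  splits <- list(train = recs, val = recs)
  tcfg <- train_config(epochs = 150L, batch_size = 32L, patience = 150L,
                       seed = 1L, vae_weight = 0, lambda_l2 = 0,
                       learning_rate = 0.002)
  fit <- train_dpi(dpi_model(dv, pv, small_model_config(), seed = 1), splits,
                   tcfg)
  expect_lt(min(fit$history$prediction_ce), 0.05)
  expect_equal(fit$best_val_acc, 1)
  # scoring the memorized records reproduces their labels exactly
  scored <- predict_interactions(fit, recs)
  expect_identical(scored$pred, recs$label)
})

test_that("early stopping fires on unlearnable labels", {
  data <- small_study(n_pairs = 100L, label_noise = 0.5, seed = 6L)
  splits <- make_splits(data$pairs, c(0.6, 0.2, 0.2), seed = 6)
  dv <- build_vocabulary(data$sequences$drugs, "drug")
  pv <- build_vocabulary(data$sequences$proteins, "protein")
  tcfg <- train_config(epochs = 40L, batch_size = 32L, patience = 2L, seed = 6L)
  fit <- train_dpi(dpi_model(dv, pv, small_model_config(), seed = 6), splits,
                   tcfg)
  expect_true(fit$stopped_early)
  expect_lt(nrow(fit$history), 40L)
})

test_that("the joint objective trains the generative pathway", {
  data <- small_study(n_pairs = 300L)
  splits <- make_splits(data$pairs, c(0.7, 0.15, 0.15), seed = 2)
  dv <- build_vocabulary(data$sequences$drugs, "drug")
  pv <- build_vocabulary(data$sequences$proteins, "protein")
  tcfg <- train_config(epochs = 4L, batch_size = 64L, patience = 4L,
                       seed = 2L, lambda_l2 = 0, vae_weight = 1)
  fit <- train_dpi(dpi_model(dv, pv, small_model_config(), seed = 2), splits,
                   tcfg)
  h <- fit$history
  neg_elbo <- h$kl_drug + h$kl_protein + h$recon_drug + h$recon_protein
  expect_lt(tail(neg_elbo, 1), neg_elbo[1])     # ELBO improves
  recon <- h$recon_drug + h$recon_protein
  expect_lt(tail(recon, 1), recon[1])           # decoders actually learn
  expect_true(all(h$kl_drug >= 0 & h$kl_protein >= 0))
})

test_that("a degenerate lambda grid returns its only candidate", {
  data <- small_study(n_pairs = 80L)
  splits <- make_splits(data$pairs, c(0.6, 0.2, 0.2), seed = 2)
  dv <- build_vocabulary(data$sequences$drugs, "drug")
  pv <- build_vocabulary(data$sequences$proteins, "protein")
  factory <- function() dpi_model(dv, pv, small_model_config(), seed = 2)
  gs <- grid_search_lambda(factory, splits,
                           train_config(epochs = 2L, batch_size = 32L,
                                        patience = 2L, seed = 2L),
                           exponents = -3L)
  expect_equal(gs$best_lambda, 1e-3)
  expect_equal(nrow(gs$results), 1L)
})

test_that("non-finite losses abort with a diagnostic", {
  m <- tiny_model()
  m$params$fc3_W[] <- Inf
  b <- tiny_batch()
  expect_error(train_step(m, b, 0, 1, TRUE), "diverged")
})
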