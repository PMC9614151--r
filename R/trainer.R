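#' Training configuration
#'
#' Optimization hyperparameters. Defaults follow the reference setup for this model family: Adam,
#' 300 epochs, batches of 256, learning rate 0.001 (0.0001 is the reference
#' choice for continuous-affinity multiclass runs), L2 coefficient
#' `10^-3` (the best grid value). Early-stopping patience and the
#' ELBO weight are declared defaults.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param lambda_l2 L2 regularization coefficient.
#' @param vae_weight Weight on the negative dual ELBO in the total loss;
#'   0 trains a plain supervised model.
#' @param patience Consecutive epochs without a validation-accuracy
#'   improvement before stopping.
#' @param seed Seed controlling shuffling, epsilon draws and dropout.
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @return A validated `dpi_train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 256L,
                         learning_rate = 0.001, lambda_l2 = 1e-3,
                         vae_weight = 1.0, patience = 20L, seed = 0L,
                         split_fractions = c(0.8, 0.1, 0.1)) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, lambda_l2 = lambda_l2,
              vae_weight = vae_weight, patience = as.integer(patience),
              seed = as.integer(seed), split_fractions = split_fractions)
  stopifnot(cfg$epochs >= 1L, cfg$batch_size >= 1L, cfg$learning_rate > 0,
            cfg$lambda_l2 >= 0, cfg$vae_weight >= 0, cfg$patience >= 1L,
            length(cfg$split_fractions) == 3L, all(cfg$split_fractions > 0),
            abs(sum(cfg$split_fractions) - 1) < 1e-8)
  structure(cfg, class = "dpi_train_config")
}

#' Split interaction records into train/validation/test sets
#'
#' Shuffles with the given seed and partitions so that no
#' (drug, protein, label) triple lands in two splits: duplicate triples
#' travel together. With all-distinct records the split sizes are exactly
#' `floor(n * fraction)` for train and validation, remainder to test.
#'
#' @param records Data frame with columns `drug`, `protein`, `label`.
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Shuffling seed.
#' @return A list of three disjoint data frames `train`, `val`, `test`.
#' @export
make_splits <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(is.data.frame(records),
            all(c("drug", "protein", "label") %in% names(records)),
            length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(records)
  n_train <- floor(n * fractions[1L])
  n_val <- floor(n * fractions[2L])
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    stop("too few records for the requested split fractions")
  }
  key <- paste(records$drug, records$protein, records$label, sep = "\r")
  set.seed(seed)
  uk <- sample(unique(key))
  counts <- table(key)[uk]
  cum <- cumsum(as.integer(counts))
  grp <- ifelse(cum <= n_train, 1L, ifelse(cum <= n_train + n_val, 2L, 3L))
  assign <- grp[match(key, uk)]
  list(train = records[assign == 1L, , drop = FALSE],
       val = records[assign == 2L, , drop = FALSE],
       test = records[assign == 3L, , drop = FALSE])
}

# Tokenize a record set once, up front.
prepare_dataset <- function(records, drug_vocab, prot_vocab, cfg) {
  dm <- tokenize_matrix(records$drug, drug_vocab, cfg$max_len_drug, warn = FALSE)
  pm <- tokenize_matrix(records$protein, prot_vocab, cfg$max_len_protein,
                        warn = FALSE)
  list(drug_mat = dm$indices, drug_lens = dm$lengths,
       prot_mat = pm$indices, prot_lens = pm$lengths,
       y = as.integer(records$label), n = nrow(records))
}

slice_batch <- function(ds, rows) {
  list(drug_mat = ds$drug_mat[rows, , drop = FALSE],
       drug_lens = ds$drug_lens[rows],
       prot_mat = ds$prot_mat[rows, , drop = FALSE],
       prot_lens = ds$prot_lens[rows],
       y = ds$y[rows])
}

predict_dataset <- function(model, ds, batch_size = 256L) {
  out <- matrix(0, ds$n, model$config$n_classes)
  starts <- seq(1L, ds$n, by = batch_size)
  for (s in starts) {
    rows <- s:min(s + batch_size - 1L, ds$n)
    b <- slice_batch(ds, rows)
    out[rows, ] <- predict_batch(model, b$drug_mat, b$drug_lens,
                                 b$prot_mat, b$prot_lens)
  }
  out
}

#' Train a dual-VAE interaction model
#'
#' Adam minimization of the total objective (cross-entropy + L2 +
#' `vae_weight` times the negative dual ELBO) with per-epoch seeded
#' reshuffling of the training records. After every epoch the validation
#' accuracy is computed at the posterior mean (epsilon = 0, dropout off);
#' the best-accuracy parameter state is retained, and training stops early
#' once accuracy has not improved for `patience` consecutive epochs.
#'
#' @param model A freshly constructed [dpi_model()].
#' @param splits A list with `train` and `val` (and optionally `test`)
#'   record data frames, e.g. from [make_splits()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `dpi_fit` list: `model` (best state), `history` (per-epoch loss
#'   breakdown + validation accuracy data frame), `best_epoch`,
#'   `best_val_acc`, `stopped_early`, `config`.
#' @export
train_dpi <- function(model, splits, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "dpi_model"), inherits(config, "dpi_train_config"),
            nrow(splits$train) >= 1L, nrow(splits$val) >= 1L)
  mcfg <- model$config
  tr <- prepare_dataset(splits$train, model$drug_vocab, model$protein_vocab, mcfg)
  va <- prepare_dataset(splits$val, model$drug_vocab, model$protein_vocab, mcfg)
  stopifnot(all(tr$y >= 0L), all(tr$y < mcfg$n_classes))

  set.seed(config$seed)
  state <- adam_init(model$params)
  history <- vector("list", config$epochs)
  best_acc <- -Inf; best_params <- model$params; best_epoch <- 0L
  stall <- 0L; stopped_early <- FALSE

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(tr$n)
    starts <- seq(1L, tr$n, by = config$batch_size)
    acc_losses <- NULL
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, tr$n)]
      step <- train_step(model, slice_batch(tr, rows), config$lambda_l2,
                         config$vae_weight, training = TRUE)
      upd <- adam_update(model$params, step$grads, state,
                         config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      w <- length(rows)
      l <- unlist(step$losses) * w
      acc_losses <- if (is.null(acc_losses)) l else acc_losses + l
    }
    mean_losses <- acc_losses / tr$n
    probs <- predict_dataset(model, va, config$batch_size)
    val_acc <- mean(max.col(probs, ties.method = "first") - 1L == va$y)
    history[[epoch]] <- c(epoch = epoch, mean_losses, val_acc = val_acc)
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  ce %.4f  val_acc %.4f",
                      epoch, mean_losses[["total"]],
                      mean_losses[["prediction_ce"]], val_acc))
    }
    if (val_acc > best_acc) {
      best_acc <- val_acc; best_params <- model$params
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) { stopped_early <- TRUE; break }
    }
  }

  model$params <- best_params
  hist_df <- as.data.frame(do.call(rbind, history[!vapply(history, is.null, TRUE)]))
  structure(list(model = model, history = hist_df, best_epoch = best_epoch,
                 best_val_acc = best_acc, stopped_early = stopped_early,
                 config = config),
            class = "dpi_fit")
}

#' @export
print.dpi_fit <- function(x, ...) {
  cat(sprintf("<dpi_fit: %d epoch(s), best val_acc %.4f at epoch %d%s>\n",
              nrow(x$history), x$best_val_acc, x$best_epoch,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' Grid search over the L2 coefficient
#'
#' Trains one model per `lambda = 10^k` for each integer exponent in
#' `exponents` (the standard search range is -5..+5) and selects the
#' lambda maximizing best validation accuracy; ties break toward the larger
#' lambda (stronger regularization).
#'
#' @param model_factory Zero-argument function returning a fresh
#'   [dpi_model()] (identical initialization each call).
#' @param splits Record splits as for [train_dpi()].
#' @param config Base [train_config()]; its `lambda_l2` is overridden.
#' @param exponents Integer vector of base-10 exponents.
#' @return A list: `best_lambda`, `best_exponent`, `results` (data frame of
#'   exponent, lambda, val_acc, best_epoch).
#' @export
grid_search_lambda <- function(model_factory, splits, config = train_config(),
                               exponents = -5:5) {
  stopifnot(length(exponents) >= 1L)
  exponents <- as.integer(exponents)
  res <- data.frame(exponent = exponents, lambda = 10^exponents,
                    val_acc = NA_real_, best_epoch = NA_integer_)
  fits <- vector("list", length(exponents))
  for (i in seq_along(exponents)) {
    cfg_i <- config
    cfg_i$lambda_l2 <- 10^exponents[i]
    fit <- train_dpi(model_factory(), splits, cfg_i)
    res$val_acc[i] <- fit$best_val_acc
    res$best_epoch[i] <- fit$best_epoch
    fits[[i]] <- fit
  }
  # argmax validation accuracy; ties -> larger lambda
  best <- which(res$val_acc == max(res$val_acc))
  best <- best[which.max(res$lambda[best])]
  list(best_lambda = res$lambda[best], best_exponent = res$exponent[best],
       results = res, best_fit = fits[[best]])
}
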