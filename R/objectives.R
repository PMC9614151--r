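#' Closed-form KL divergence to the standard-normal prior
#'
#' For a diagonal Gaussian posterior with mean `mu` and log-variance
#' `log_var`, the KL divergence to N(0, I) is
#' `0.5 * sum(exp(log_var) + mu^2 - 1 - log_var)`; it is zero exactly when
#' the posterior equals the prior.
#'
#' @param latent A `dpi_latent` (or list with `mu`, `log_var`).
#' @return Non-negative scalar.
#' @export
kl_standard_normal <- function(latent) {
  mu <- latent$mu; lv <- latent$log_var
  if (!all(is.finite(mu)) || !all(is.finite(lv))) {
    stop("non-finite latent parameters")
  }
  0.5 * sum(exp(lv) + mu^2 - 1 - lv)
}

#' Reconstruction loss of decoder scores against a token sequence
#'
#' Position-wise categorical cross-entropy between the row-softmaxed scores
#' and the true token indices, averaged over non-pad positions only, so a
#' padding-extended copy of a sequence scores identically.
#'
#' @param recon_scores `max_len` x `vocab_size` score (logit) matrix.
#' @param tok A `dpi_tokens` (indices use 0 for pad; real tokens are
#'   1-based and index score columns directly... column `i` of
#'   `recon_scores` scores token index `i`).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(recon_scores, tok) {
  idx <- if (inherits(tok, "dpi_tokens")) tok$indices else as.integer(tok)
  stopifnot(nrow(recon_scores) == length(idx))
  keep <- idx != 0L
  if (!any(keep)) stop("all-pad sequence: no positions to score")
  P <- row_softmax(recon_scores[keep, , drop = FALSE])
  if (any(idx[keep] > ncol(recon_scores))) {
    stop("token index exceeds score matrix width")
  }
  -mean(log(P[cbind(seq_len(sum(keep)), idx[keep])]))
}

#' Dual evidence lower bound
#'
#' `L' = (-kl_drug - recon_drug) + (-kl_protein - recon_protein)` under the
#' convention that the reconstruction losses are negated log-likelihoods, so
#' `L' <= 0` with supremum 0 and training maximizes it by minimizing `-L'`.
#'
#' @param kl_drug,kl_protein Non-negative KL terms.
#' @param recon_drug,recon_protein Non-negative reconstruction losses.
#' @return Scalar `L'`.
#' @export
elbo_dual <- function(kl_drug, recon_drug, kl_protein, recon_protein) {
  (-kl_drug - recon_drug) + (-kl_protein - recon_protein)
}

#' Supervised prediction loss with L2 penalty
#'
#' Mean cross-entropy between true labels and predicted probabilities —
#' binary cross-entropy on the positive-class probability for two classes,
#' categorical cross-entropy otherwise — plus `lambda` times the sum of
#' squared non-bias weight entries.
#'
#' @param y Integer labels in `0 .. n_classes - 1`.
#' @param scores For binary, a numeric vector of positive-class
#'   probabilities (or an n x 2 probability matrix); for multiclass, an
#'   n x K probability matrix with rows summing to 1.
#' @param lambda Non-negative L2 coefficient.
#' @param weights Optional list of parameter arrays to penalize; entries
#'   whose names end in `"_b"` (biases) are excluded.
#' @return Scalar loss.
#' @export
prediction_loss <- function(y, scores, lambda = 0, weights = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  eps <- 1e-12
  if (is.matrix(scores) && ncol(scores) > 1L) {
    stopifnot(all(y >= 0), all(y < ncol(scores)))
    p_true <- scores[cbind(seq_along(y), y + 1L)]
    ce <- -mean(log(pmax(p_true, eps)))
  } else {
    p <- as.numeric(scores)
    stopifnot(all(y %in% c(0L, 1L)))
    ce <- -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  }
  ce + lambda * l2_sum(weights)
}

l2_sum <- function(weights) {
  if (is.null(weights) || length(weights) == 0L) return(0)
  nm <- names(weights)
  keep <- !grepl("_b$", nm)
  sum(vapply(weights[keep], function(w) sum(w^2), 0))
}

#' Assemble the total training objective
#'
#' `total = pred_loss + vae_weight * (-elbo)`: the supervised cross-entropy
#' (with its L2 penalty already folded in) plus the weighted negative dual
#' ELBO. `vae_weight = 0` reduces to a plain supervised model.
#'
#' @param pred_loss Supervised loss (see [prediction_loss()]).
#' @param elbo Dual ELBO `L'` (see [elbo_dual()]).
#' @param vae_weight Non-negative weight on the generative term.
#' @return Scalar total loss.
#' @export
total_loss <- function(pred_loss, elbo, vae_weight = 1) {
  if (vae_weight < 0) stop("vae_weight must be non-negative")
  pred_loss + vae_weight * (-elbo)
}
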