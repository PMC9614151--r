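# Low-level neural-network primitives.
#
# Sequence activations for a batch are stored as a (B*L) x C matrix whose row
# r = (b-1)*L + t holds the channels of position t in sample b. All
# convolutions are stride-1 with odd filter length and zero same-padding, so
# output length equals input length; a stride-1 transposed convolution is
# mathematically a convolution, and the decoder layers use that form.
# Every *_forward returns the output plus the cache its *_backward needs.

# The convolution is evaluated as one im2col GEMM: the k zero-padded shifts
# of the input are laid side by side as a (B*L) x (C*k) matrix (compiled
# kernel) and multiplied against the filter bank flattened to (C*k) x F.
# One large GEMM is far cheaper than k thin ones; col2im is the adjoint
# scatter used by the backward pass.
conv1d_forward <- function(X, W, bias, B, L) {
  k <- dim(W)[1L]; C <- dim(W)[2L]; F_ <- dim(W)[3L]
  Wflat <- matrix(aperm(W, c(2L, 1L, 3L)), C * k, F_)
  Xcol <- cpp_im2col(X, B, L, C, k)
  Y <- Xcol %*% Wflat
  Y <- Y + rep(bias, each = B * L)
  list(Y = Y, Xcol = Xcol, B = B, L = L, k = k, C = C, F_ = F_,
       Wflat = Wflat)
}

conv1d_backward <- function(dY, W, cache) {
  k <- cache$k; C <- cache$C; F_ <- cache$F_
  dWflat <- crossprod(cache$Xcol, dY)
  dW <- aperm(array(dWflat, c(C, k, F_)), c(2L, 1L, 3L))
  dX <- cpp_col2im(dY %*% t(cache$Wflat), cache$B, cache$L, C, k)
  list(dX = dX, dW = dW, db = colSums(dY))
}

# Gated convolution block: ReLU( conv_A(X) * sigmoid(conv_B(X)) ).
# The two filter banks are stored fused as one weight array with 2*F output
# channels (A first) so each shift costs a single GEMM.
gated_conv_forward <- function(X, W, bias, B, L) {
  cv <- conv1d_forward(X, W, bias, B, L)
  F_ <- cv$F_ %/% 2L
  A <- cv$Y[, seq_len(F_), drop = FALSE]
  S <- 1 / (1 + exp(-cv$Y[, F_ + seq_len(F_), drop = FALSE]))
  H <- A * S
  Y <- H * (H > 0)
  list(Y = Y, A = A, S = S, H = H, conv = cv)
}

gated_conv_backward <- function(dY, W, cache) {
  dH <- dY * (cache$H > 0)
  dA <- dH * cache$S
  dG <- dH * cache$A * cache$S * (1 - cache$S)
  conv1d_backward(cbind(dA, dG), W, cache$conv)
}

dense_forward <- function(X, W, bias) {
  sweep_add(X %*% W, bias)
}

sweep_add <- function(M, bias) {
  M + rep(bias, each = nrow(M))
}

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu_forward <- function(X) pmax(X, 0)
relu_backward <- function(dY, Y) dY * (Y > 0)

# Inverted dropout; mask drawn from the session RNG so seeded runs are
# reproducible. rate = 0 is the identity.
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# Numerically stable row-wise softmax (max.col is much faster than apply).
row_softmax <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M - mx)
  E / rowSums(E)
}

# Masked global max pool over sequence positions: X is (B*L) x F, lens gives
# each sample's real length; padded positions never win the max.
maxpool_forward <- function(X, B, L, lens) {
  F_ <- ncol(X)
  Xm <- X
  pad <- rep(seq_len(L), B) > rep(lens, each = L)
  if (any(pad)) Xm[pad, ] <- -Inf
  tM <- t(matrix(Xm, L))                         # (B*F) x L, row j = (b, f)
  am <- max.col(tM, ties.method = "first")
  vals <- tM[cbind(seq_len(nrow(tM)), am)]
  list(Y = matrix(vals, B, F_), argmax = am, B = B, L = L, F_ = F_)
}

maxpool_backward <- function(dY, cache) {
  B <- cache$B; L <- cache$L; F_ <- cache$F_
  b_of <- rep(seq_len(B), times = F_)
  f_of <- rep(seq_len(F_), each = B)
  dX <- matrix(0, B * L, F_)
  dX[cbind((b_of - 1L) * L + cache$argmax, f_of)] <- as.vector(dY)
  dX
}

embed_forward <- function(E, idxvec) {
  E[idxvec + 1L, , drop = FALSE]
}

embed_backward <- function(dX, idxvec, n_rows) {
  g <- rowsum(dX, group = idxvec)
  dE <- matrix(0, n_rows, ncol(dX))
  dE[as.integer(rownames(g)) + 1L, ] <- g
  dE[1L, ] <- 0                                   # pad embedding is fixed at 0
  dE
}

# Reshape between the dense seed (B x (L*C), column (c-1)*L + t) and the
# stacked sequence layout ((B*L) x C).
seed_to_seq <- function(S, B, L, C) {
  matrix(aperm(array(S, dim = c(B, L, C)), c(2L, 1L, 3L)), B * L, C)
}

seq_to_seed <- function(X, B, L, C) {
  matrix(aperm(array(X, dim = c(L, B, C)), c(2L, 1L, 3L)), B, L * C)
}

# Self-attention over one h x d matrix (Q = K = V = M) with cached weights.
self_attention_forward <- function(M, scale_mode) {
  d_k <- ncol(M)
  s <- if (scale_mode == "sqrt") sqrt(d_k) else d_k
  P <- row_softmax(M %*% t(M) / s)
  list(Y = P %*% M, P = P, s = s)
}

self_attention_backward <- function(dY, M, cache) {
  P <- cache$P
  dP <- dY %*% t(M)
  dM <- crossprod(P, dY)
  dS <- (dP - rowSums(dP * P)) * P
  dM + (dS + t(dS)) %*% M / cache$s
}
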