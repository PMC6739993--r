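# Minimal 1-D neural-network primitives on BLAS matrix operations.
#
# Activations are stored channel-major: a layer output is a matrix of
# dim (channels, len * batch) whose column j = (b - 1) * len + t holds
# the channel vector at time t of batch item b.  Convolutions are
# im2col + GEMM; all kernels are length 3, stride 1, zero-padded so the
# output length equals the input length ("same").

conv1d_fwd <- function(A, C, len, batch, W, b) {
  if (is.null(dim(A)) || dim(A)[1] != C) dim(A) <- c(C, len * batch)
  conv1d_fwd_cpp(A, C, len, batch, W, b)
}

# A_in is the layer input activation (im2col is rebuilt in C++)
conv1d_bwd <- function(dY, A_in, W, C, len, batch) {
  if (is.null(dim(A_in)) || dim(A_in)[1] != C)
    dim(A_in) <- c(C, len * batch)
  out <- conv1d_bwd_cpp(dY, A_in, W, C, len, batch)
  out$db <- as.numeric(out$db)
  out
}

relu_fwd <- function(A) (A > 0) * A
relu_bwd <- function(dY, A) dY * (A > 0)

# max pooling, window 2, stride 2; odd trailing sample dropped.
# Ties take the earlier sample (deterministic).
pool2_fwd <- function(A, C, len, batch) {
  L2 <- len %/% 2L
  dim(A) <- c(C, len, batch)
  A1 <- A[, seq.int(1L, 2L * L2, 2L), , drop = FALSE]
  A2 <- A[, seq.int(2L, 2L * L2, 2L), , drop = FALSE]
  m <- A1 >= A2
  out <- A2
  out[m] <- A1[m]
  dim(out) <- c(C, L2 * batch)
  list(out = out, mask = m)
}

pool2_bwd <- function(dY, mask, C, len, batch) {
  L2 <- len %/% 2L
  dim(dY) <- c(C, L2, batch)
  d1 <- array(0, c(C, L2, batch)); d1[mask] <- dY[mask]
  d2 <- dY; d2[mask] <- 0
  dA <- array(0, c(C, len, batch))
  dA[, seq.int(1L, 2L * L2, 2L), ] <- d1
  dA[, seq.int(2L, 2L * L2, 2L), ] <- d2
  dim(dA) <- c(C, len * batch)
  dA
}

# nearest-neighbour upsampling by 2 (each sample repeated)
up2_fwd <- function(A, C, len, batch) {
  dim(A) <- c(C, len, batch)
  out <- array(0, c(C, 2L * len, batch))
  out[, seq.int(1L, 2L * len, 2L), ] <- A
  out[, seq.int(2L, 2L * len, 2L), ] <- A
  dim(out) <- c(C, 2L * len * batch)
  out
}

up2_bwd <- function(dY, C, len, batch) {
  dim(dY) <- c(C, 2L * len, batch)
  dA <- dY[, seq.int(1L, 2L * len, 2L), , drop = FALSE] +
    dY[, seq.int(2L, 2L * len, 2L), , drop = FALSE]
  dim(dA) <- c(C, len * batch)
  dA
}

# deterministic zero-pad of one trailing sample (aligns the 7 -> 14
# upsampled length with the 15-sample encoder feature for fusion)
pad_end_fwd <- function(A, C, len, batch) {
  dim(A) <- c(C, len, batch)
  out <- array(0, c(C, len + 1L, batch))
  out[, 1:len, ] <- A
  dim(out) <- c(C, (len + 1L) * batch)
  out
}

pad_end_bwd <- function(dY, C, len_padded, batch) {
  dim(dY) <- c(C, len_padded, batch)
  dA <- dY[, 1:(len_padded - 1L), , drop = FALSE]
  dim(dA) <- c(C, (len_padded - 1L) * batch)
  dA
}

# inverted dropout: scaling at train time, identity at eval
dropout_mask <- function(n, rate) {
  (stats::runif(n) >= rate) / (1 - rate)
}

dense_fwd <- function(F, W, b) W %*% F + b

# softmax + cross-entropy head; y is 0/1 integer labels
softmax_probs <- function(Z) {
  Zs <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Zs)
  sweep(E, 2, colSums(E), "/")
}

ce_loss <- function(P, y) {
  -mean(log(pmax(P[cbind(y + 1L, seq_along(y))], 1e-300)))
}

ce_grad <- function(P, y) {
  G <- P
  G[cbind(y + 1L, seq_along(y))] <- G[cbind(y + 1L, seq_along(y))] - 1
  G / length(y)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}
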