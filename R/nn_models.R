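# Architectures for microbubble-vs-tissue RF segment classification:
# a 1-D U-net and the CNN / RNN baselines it is compared against.  All
# three map a length-60 RF segment to a 2-class softmax and share one
# train / predict interface.

#' U-net architecture configuration
#'
#' The encoder applies three blocks of (conv, conv, dropout, maxpool)
#' with feature maps growing 32/64/128; a two-conv bottleneck and a
#' fourth dropout follow; the decoder mirrors with three blocks of
#' (upsample, fusion concatenation with the matching encoder feature,
#' conv, conv); a single dense layer with softmax closes the network.
#' That is 14 convolutions, 3 downsampling, 3 upsampling, 3 fusion and
#' 4 dropout layers.  The layer inventory pins the encoder widths but
#' not the bottleneck/decoder widths; the defaults (197, then 150/93/32)
#' are the plan whose total trainable parameter count is exactly
#' 607,112.
#'
#' @param input_length segment length in samples.
#' @param base_filters encoder feature-map counts per depth.
#' @param bottleneck_filters bottleneck width.
#' @param decoder_filters decoder feature-map counts per depth
#'   (shallowest last).
#' @param dropout_rate dropout probability.
#' @param n_classes output classes.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(input_length = 60L, base_filters = c(32L, 64L, 128L),
                        bottleneck_filters = 197L,
                        decoder_filters = c(150L, 93L, 32L),
                        dropout_rate = 0.5, n_classes = 2L) {
  if (length(base_filters) != 3L || length(decoder_filters) != 3L)
    stop("unet_config: exactly three encoder and three decoder depths ",
         "(3 down / 3 up / 3 fusion layers)")
  if (input_length %% 4L != 0L)
    stop("unet_config: input_length must survive two exact poolings")
  stopifnot(dropout_rate >= 0, dropout_rate < 1, n_classes >= 2)
  structure(list(input_length = as.integer(input_length),
                 base_filters = as.integer(base_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 decoder_filters = as.integer(decoder_filters),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 kernel = 3L, n_conv = 14L, n_dropout = 4L),
            class = "unet_config")
}

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}

conv_par <- function(c_in, c_out) {
  list(W = he_init(c_out, 3L * c_in), b = numeric(c_out))
}

#' Build the 1-D U-net segment classifier
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed fixing the weight initialization.
#' @return an untrained model object of class `ucpwi_model`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 0L) {
  stopifnot(inherits(cfg, "unet_config"))
  f <- cfg$base_filters; bt <- cfg$bottleneck_filters; d <- cfg$decoder_filters
  params <- with_seed(seed, list(
    enc1a = conv_par(1L, f[1]),   enc1b = conv_par(f[1], f[1]),
    enc2a = conv_par(f[1], f[2]), enc2b = conv_par(f[2], f[2]),
    enc3a = conv_par(f[2], f[3]), enc3b = conv_par(f[3], f[3]),
    bot1  = conv_par(f[3], bt),   bot2  = conv_par(bt, bt),
    dec1a = conv_par(bt + f[3], d[1]), dec1b = conv_par(d[1], d[1]),
    dec2a = conv_par(d[1] + f[2], d[2]), dec2b = conv_par(d[2], d[2]),
    dec3a = conv_par(d[2] + f[1], d[3]), dec3b = conv_par(d[3], d[3]),
    dense = list(W = he_init(cfg$n_classes, cfg$input_length * d[3]),
                 b = numeric(cfg$n_classes))))
  structure(list(arch = "unet", cfg = cfg, params = params,
                 trained = FALSE, seed = seed),
            class = "ucpwi_model")
}

#' Count trainable parameters of a model
#'
#' @param model a `ucpwi_model`.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ucpwi_model"))
  n <- 0L
  rec <- function(x) for (e in x)
    if (is.list(e)) rec(e) else n <<- n + length(e)
  rec(model$params)
  n
}

#' @export
print.ucpwi_model <- function(x, ...) {
  cat(sprintf("%s segment classifier: %s parameters, %s\n",
              toupper(x$arch),
              format(count_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Forward pass of the U-net.
# X: batch x input_length matrix of (normalized) segments.
# Returns list(probs, cache) in train mode, list(probs) otherwise.
unet_forward <- function(model, X, train = FALSE) {
  p <- model$params; cfg <- model$cfg
  f <- cfg$base_filters; bt <- cfg$bottleneck_filters; d <- cfg$decoder_filters
  B <- nrow(X); L0 <- cfg$input_length
  L1 <- L0 %/% 2L; L2 <- L1 %/% 2L; L3 <- L2 %/% 2L  # 60/30/15/7
  dr <- cfg$dropout_rate
  A0 <- matrix(as.vector(t(X)), nrow = 1L)
  cv <- function(A, C, len, par) conv1d_fwd(A, C, len, B, par$W, par$b)
  drop_ <- function(A) {
    if (!train || dr == 0) return(list(out = A, mask = NULL))
    m <- dropout_mask(length(A), dr); dim(m) <- dim(A)
    list(out = A * m, mask = m)
  }
  o1a <- cv(A0, 1L, L0, p$enc1a);  e1a <- relu_fwd(o1a)
  o1b <- cv(e1a, f[1], L0, p$enc1b); e1b <- relu_fwd(o1b)
  k1 <- drop_(e1b); pl1 <- pool2_fwd(k1$out, f[1], L0, B)
  o2a <- cv(pl1$out, f[1], L1, p$enc2a); e2a <- relu_fwd(o2a)
  o2b <- cv(e2a, f[2], L1, p$enc2b); e2b <- relu_fwd(o2b)
  k2 <- drop_(e2b); pl2 <- pool2_fwd(k2$out, f[2], L1, B)
  o3a <- cv(pl2$out, f[2], L2, p$enc3a); e3a <- relu_fwd(o3a)
  o3b <- cv(e3a, f[3], L2, p$enc3b); e3b <- relu_fwd(o3b)
  k3 <- drop_(e3b); pl3 <- pool2_fwd(k3$out, f[3], L2, B)
  ob1 <- cv(pl3$out, f[3], L3, p$bot1); b1 <- relu_fwd(ob1)
  ob2 <- cv(b1, bt, L3, p$bot2); b2 <- relu_fwd(ob2)
  k4 <- drop_(b2)
  u1 <- pad_end_fwd(up2_fwd(k4$out, bt, L3, B), bt, 2L * L3, B)  # -> 15
  f1 <- rbind(e3b, u1)
  od1a <- cv(f1, f[3] + bt, L2, p$dec1a); g1a <- relu_fwd(od1a)
  od1b <- cv(g1a, d[1], L2, p$dec1b); g1b <- relu_fwd(od1b)
  u2 <- up2_fwd(g1b, d[1], L2, B)                                # -> 30
  f2 <- rbind(e2b, u2)
  od2a <- cv(f2, f[2] + d[1], L1, p$dec2a); g2a <- relu_fwd(od2a)
  od2b <- cv(g2a, d[2], L1, p$dec2b); g2b <- relu_fwd(od2b)
  u3 <- up2_fwd(g2b, d[2], L1, B)                                # -> 60
  f3 <- rbind(e1b, u3)
  od3a <- cv(f3, f[1] + d[2], L0, p$dec3a); g3a <- relu_fwd(od3a)
  od3b <- cv(g3a, d[3], L0, p$dec3b); g3b <- relu_fwd(od3b)
  Fl <- g3b; dim(Fl) <- c(d[3] * L0, B)
  Z <- dense_fwd(Fl, p$dense$W, p$dense$b)
  probs <- softmax_probs(Z)
  if (!train) return(list(probs = probs))
  list(probs = probs, cache = list(
    A0 = A0, o1a = o1a, e1a = e1a, o1b = o1b, e1b = e1b, k1 = k1, pl1 = pl1,
    o2a = o2a, e2a = e2a, o2b = o2b, e2b = e2b, k2 = k2, pl2 = pl2,
    o3a = o3a, e3a = e3a, o3b = o3b, e3b = e3b, k3 = k3, pl3 = pl3,
    ob1 = ob1, b1 = b1, ob2 = ob2, b2 = b2, k4 = k4,
    f1 = f1, od1a = od1a, g1a = g1a, od1b = od1b, g1b = g1b,
    f2 = f2, od2a = od2a, g2a = g2a, od2b = od2b, g2b = g2b,
    f3 = f3, od3a = od3a, g3a = g3a, od3b = od3b, g3b = g3b,
    Fl = Fl, B = B))
}

# Backward pass; dZ is the loss gradient at the logits.
unet_backward <- function(model, cache, dZ) {
  p <- model$params; cfg <- model$cfg
  f <- cfg$base_filters; bt <- cfg$bottleneck_filters; d <- cfg$decoder_filters
  B <- cache$B; L0 <- cfg$input_length
  L1 <- L0 %/% 2L; L2 <- L1 %/% 2L; L3 <- L2 %/% 2L
  g <- list()
  g$dense <- list(W = tcrossprod(dZ, cache$Fl), b = rowSums(dZ))
  dFl <- crossprod(p$dense$W, dZ)
  dim(dFl) <- c(d[3], L0 * B)
  dg3b <- relu_bwd(dFl, cache$od3b)
  bk <- conv1d_bwd(dg3b, cache$g3a, p$dec3b$W, d[3], L0, B)
  g$dec3b <- list(W = bk$dW, b = bk$db)
  dg3a <- relu_bwd(bk$dA, cache$od3a)
  bk <- conv1d_bwd(dg3a, cache$f3, p$dec3a$W, f[1] + d[2], L0, B)
  g$dec3a <- list(W = bk$dW, b = bk$db)
  de1b_skip <- bk$dA[1:f[1], , drop = FALSE]
  du3 <- bk$dA[(f[1] + 1L):(f[1] + d[2]), , drop = FALSE]
  dg2b <- relu_bwd(up2_bwd(du3, d[2], L1, B), cache$od2b)
  bk <- conv1d_bwd(dg2b, cache$g2a, p$dec2b$W, d[2], L1, B)
  g$dec2b <- list(W = bk$dW, b = bk$db)
  dg2a <- relu_bwd(bk$dA, cache$od2a)
  bk <- conv1d_bwd(dg2a, cache$f2, p$dec2a$W, f[2] + d[1], L1, B)
  g$dec2a <- list(W = bk$dW, b = bk$db)
  de2b_skip <- bk$dA[1:f[2], , drop = FALSE]
  du2 <- bk$dA[(f[2] + 1L):(f[2] + d[1]), , drop = FALSE]
  dg1b <- relu_bwd(up2_bwd(du2, d[1], L2, B), cache$od1b)
  bk <- conv1d_bwd(dg1b, cache$g1a, p$dec1b$W, d[1], L2, B)
  g$dec1b <- list(W = bk$dW, b = bk$db)
  dg1a <- relu_bwd(bk$dA, cache$od1a)
  bk <- conv1d_bwd(dg1a, cache$f1, p$dec1a$W, f[3] + bt, L2, B)
  g$dec1a <- list(W = bk$dW, b = bk$db)
  de3b_skip <- bk$dA[1:f[3], , drop = FALSE]
  du1 <- bk$dA[(f[3] + 1L):(f[3] + bt), , drop = FALSE]
  dk4 <- up2_bwd(pad_end_bwd(du1, bt, L2, B), bt, L3, B)
  if (!is.null(cache$k4$mask)) dk4 <- dk4 * cache$k4$mask
  db2 <- relu_bwd(dk4, cache$ob2)
  bk <- conv1d_bwd(db2, cache$b1, p$bot2$W, bt, L3, B)
  g$bot2 <- list(W = bk$dW, b = bk$db)
  db1 <- relu_bwd(bk$dA, cache$ob1)
  bk <- conv1d_bwd(db1, cache$pl3$out, p$bot1$W, f[3], L3, B)
  g$bot1 <- list(W = bk$dW, b = bk$db)
  dk3 <- pool2_bwd(bk$dA, cache$pl3$mask, f[3], L2, B)
  if (!is.null(cache$k3$mask)) dk3 <- dk3 * cache$k3$mask
  de3b <- dk3 + de3b_skip
  dc3b <- relu_bwd(de3b, cache$o3b)
  bk <- conv1d_bwd(dc3b, cache$e3a, p$enc3b$W, f[3], L2, B)
  g$enc3b <- list(W = bk$dW, b = bk$db)
  dc3a <- relu_bwd(bk$dA, cache$o3a)
  bk <- conv1d_bwd(dc3a, cache$pl2$out, p$enc3a$W, f[2], L2, B)
  g$enc3a <- list(W = bk$dW, b = bk$db)
  dk2 <- pool2_bwd(bk$dA, cache$pl2$mask, f[2], L1, B)
  if (!is.null(cache$k2$mask)) dk2 <- dk2 * cache$k2$mask
  de2b <- dk2 + de2b_skip
  dc2b <- relu_bwd(de2b, cache$o2b)
  bk <- conv1d_bwd(dc2b, cache$e2a, p$enc2b$W, f[2], L1, B)
  g$enc2b <- list(W = bk$dW, b = bk$db)
  dc2a <- relu_bwd(bk$dA, cache$o2a)
  bk <- conv1d_bwd(dc2a, cache$pl1$out, p$enc2a$W, f[1], L1, B)
  g$enc2a <- list(W = bk$dW, b = bk$db)
  dk1 <- pool2_bwd(bk$dA, cache$pl1$mask, f[1], L0, B)
  if (!is.null(cache$k1$mask)) dk1 <- dk1 * cache$k1$mask
  de1b <- dk1 + de1b_skip
  dc1b <- relu_bwd(de1b, cache$o1b)
  bk <- conv1d_bwd(dc1b, cache$e1a, p$enc1b$W, f[1], L0, B)
  g$enc1b <- list(W = bk$dW, b = bk$db)
  dc1a <- relu_bwd(bk$dA, cache$o1a)
  bk <- conv1d_bwd(dc1a, cache$A0, p$enc1a$W, 1L, L0, B)
  g$enc1a <- list(W = bk$dW, b = bk$db)
  g[names(model$params)]
}

#' Build the CNN baseline classifier
#'
#' Two 128-filter convolutions, max pooling, two 64-filter convolutions,
#' max pooling, dropout, then two fully connected layers with a softmax
#' head; ReLU activations throughout.
#'
#' @param input_length segment length.
#' @param dropout_rate dropout probability.
#' @param seed integer seed fixing the initialization.
#' @return an untrained `ucpwi_model`.
#' @export
build_cnn <- function(input_length = 60L, dropout_rate = 0.5, seed = 0L) {
  L2 <- input_length %/% 4L
  params <- with_seed(seed, list(
    conv1 = conv_par(1L, 128L), conv2 = conv_par(128L, 128L),
    conv3 = conv_par(128L, 64L), conv4 = conv_par(64L, 64L),
    fc1 = list(W = he_init(64L, 64L * L2), b = numeric(64L)),
    fc2 = list(W = he_init(2L, 64L), b = numeric(2L))))
  structure(list(arch = "cnn",
                 cfg = list(input_length = as.integer(input_length),
                            dropout_rate = dropout_rate),
                 params = params, trained = FALSE, seed = seed),
            class = "ucpwi_model")
}

cnn_forward <- function(model, X, train = FALSE) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(X); L0 <- cfg$input_length
  L1 <- L0 %/% 2L; L2 <- L1 %/% 2L
  A0 <- matrix(as.vector(t(X)), nrow = 1L)
  o1 <- conv1d_fwd(A0, 1L, L0, B, p$conv1$W, p$conv1$b); a1 <- relu_fwd(o1)
  o2 <- conv1d_fwd(a1, 128L, L0, B, p$conv2$W, p$conv2$b); a2 <- relu_fwd(o2)
  pl1 <- pool2_fwd(a2, 128L, L0, B)
  o3 <- conv1d_fwd(pl1$out, 128L, L1, B, p$conv3$W, p$conv3$b); a3 <- relu_fwd(o3)
  o4 <- conv1d_fwd(a3, 64L, L1, B, p$conv4$W, p$conv4$b); a4 <- relu_fwd(o4)
  pl2 <- pool2_fwd(a4, 64L, L1, B)
  kp <- if (train && cfg$dropout_rate > 0) {
    m <- dropout_mask(length(pl2$out), cfg$dropout_rate)
    dim(m) <- dim(pl2$out)
    list(out = pl2$out * m, mask = m)
  } else list(out = pl2$out, mask = NULL)
  Fl <- kp$out; dim(Fl) <- c(64L * L2, B)
  z1 <- dense_fwd(Fl, p$fc1$W, p$fc1$b); h1 <- relu_fwd(z1)
  Z <- dense_fwd(h1, p$fc2$W, p$fc2$b)
  probs <- softmax_probs(Z)
  if (!train) return(list(probs = probs))
  list(probs = probs,
       cache = list(A0 = A0, o1 = o1, a1 = a1, o2 = o2, a2 = a2, pl1 = pl1,
                    o3 = o3, a3 = a3, o4 = o4, a4 = a4, pl2 = pl2,
                    kp = kp, Fl = Fl, z1 = z1, h1 = h1, B = B))
}

cnn_backward <- function(model, cache, dZ) {
  p <- model$params; cfg <- model$cfg
  B <- cache$B; L0 <- cfg$input_length
  L1 <- L0 %/% 2L; L2 <- L1 %/% 2L
  g <- list()
  g$fc2 <- list(W = tcrossprod(dZ, cache$h1), b = rowSums(dZ))
  dh1 <- relu_bwd(crossprod(p$fc2$W, dZ), cache$z1)
  g$fc1 <- list(W = tcrossprod(dh1, cache$Fl), b = rowSums(dh1))
  dFl <- crossprod(p$fc1$W, dh1)
  dim(dFl) <- c(64L, L2 * B)
  if (!is.null(cache$kp$mask)) dFl <- dFl * cache$kp$mask
  da4 <- relu_bwd(pool2_bwd(dFl, cache$pl2$mask, 64L, L1, B), cache$o4)
  bk <- conv1d_bwd(da4, cache$a3, p$conv4$W, 64L, L1, B)
  g$conv4 <- list(W = bk$dW, b = bk$db)
  da3 <- relu_bwd(bk$dA, cache$o3)
  bk <- conv1d_bwd(da3, cache$pl1$out, p$conv3$W, 128L, L1, B)
  g$conv3 <- list(W = bk$dW, b = bk$db)
  da2 <- relu_bwd(pool2_bwd(bk$dA, cache$pl1$mask, 128L, L0, B), cache$o2)
  bk <- conv1d_bwd(da2, cache$a1, p$conv2$W, 128L, L0, B)
  g$conv2 <- list(W = bk$dW, b = bk$db)
  da1 <- relu_bwd(bk$dA, cache$o1)
  bk <- conv1d_bwd(da1, cache$A0, p$conv1$W, 1L, L0, B)
  g$conv1 <- list(W = bk$dW, b = bk$db)
  g[names(model$params)]
}

#' Build the RNN baseline classifier
#'
#' Four stacked simple (tanh) recurrent layers of 100 units reading the
#' segment sample by sample, dropout on the final hidden state, then
#' three fully connected layers (ReLU, ReLU, softmax).
#'
#' @param input_length segment length.
#' @param units recurrent state size.
#' @param dropout_rate dropout probability.
#' @param seed integer seed fixing the initialization.
#' @return an untrained `ucpwi_model`.
#' @export
build_rnn <- function(input_length = 60L, units = 100L,
                      dropout_rate = 0.5, seed = 0L) {
  rnn_par <- function(n_in) list(
    Wx = he_init(units, n_in),
    Wh = he_init(units, units) / sqrt(2),  # ~orthogonal scale
    b = numeric(units))
  params <- with_seed(seed, list(
    rnn1 = rnn_par(1L), rnn2 = rnn_par(units),
    rnn3 = rnn_par(units), rnn4 = rnn_par(units),
    fc1 = list(W = he_init(64L, units), b = numeric(64L)),
    fc2 = list(W = he_init(32L, 64L), b = numeric(32L)),
    fc3 = list(W = he_init(2L, 32L), b = numeric(2L))))
  structure(list(arch = "rnn",
                 cfg = list(input_length = as.integer(input_length),
                            units = as.integer(units),
                            dropout_rate = dropout_rate),
                 params = params, trained = FALSE, seed = seed),
            class = "ucpwi_model")
}

# one recurrent layer forward: X (n_in, T, batch) -> H (units, T, batch)
rnn_layer_fwd <- function(X, par, units, B) {
  T_ <- dim(X)[2]
  H <- array(0, c(units, T_, B))
  h <- matrix(0, units, B)
  n_in <- dim(X)[1]
  for (t in seq_len(T_)) {
    xt <- matrix(X[, t, ], n_in, B)
    h <- tanh(par$Wx %*% xt + par$Wh %*% h + par$b)
    H[, t, ] <- h
  }
  H
}

# BPTT through one layer; dH is the gradient on H.  Returns grads and dX.
rnn_layer_bwd <- function(X, H, par, dH, units, B) {
  T_ <- dim(X)[2]
  dWx <- array(0, dim(par$Wx)); dWh <- array(0, dim(par$Wh))
  db <- numeric(units)
  dX <- array(0, dim(X))
  dh_carry <- matrix(0, units, B)
  for (t in rev(seq_len(T_))) {
    dh <- matrix(dH[, t, ], units, B) + dh_carry
    da <- dh * (1 - matrix(H[, t, ], units, B)^2)
    xt <- matrix(X[, t, ], dim(X)[1], B)
    hprev <- if (t > 1L) matrix(H[, t - 1L, ], units, B) else
      matrix(0, units, B)
    dWx <- dWx + tcrossprod(da, xt)
    dWh <- dWh + tcrossprod(da, hprev)
    db <- db + rowSums(da)
    dh_carry <- crossprod(par$Wh, da)
    dX[, t, ] <- crossprod(par$Wx, da)
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

rnn_forward <- function(model, X, train = FALSE) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(X); T_ <- cfg$input_length; u <- cfg$units
  X0 <- array(0, c(1L, T_, B))
  X0[1L, , ] <- t(X)
  H1 <- rnn_layer_fwd(X0, p$rnn1, u, B)
  H2 <- rnn_layer_fwd(H1, p$rnn2, u, B)
  H3 <- rnn_layer_fwd(H2, p$rnn3, u, B)
  H4 <- rnn_layer_fwd(H3, p$rnn4, u, B)
  hT <- matrix(H4[, T_, ], u, B)
  kp <- if (train && cfg$dropout_rate > 0) {
    m <- dropout_mask(length(hT), cfg$dropout_rate); dim(m) <- dim(hT)
    list(out = hT * m, mask = m)
  } else list(out = hT, mask = NULL)
  z1 <- dense_fwd(kp$out, p$fc1$W, p$fc1$b); h1 <- relu_fwd(z1)
  z2 <- dense_fwd(h1, p$fc2$W, p$fc2$b); h2 <- relu_fwd(z2)
  Z <- dense_fwd(h2, p$fc3$W, p$fc3$b)
  probs <- softmax_probs(Z)
  if (!train) return(list(probs = probs))
  list(probs = probs,
       cache = list(X0 = X0, H1 = H1, H2 = H2, H3 = H3, H4 = H4,
                    hT = hT, kp = kp, z1 = z1, h1 = h1, z2 = z2, h2 = h2,
                    B = B))
}

rnn_backward <- function(model, cache, dZ) {
  p <- model$params; cfg <- model$cfg
  B <- cache$B; T_ <- cfg$input_length; u <- cfg$units
  g <- list()
  g$fc3 <- list(W = tcrossprod(dZ, cache$h2), b = rowSums(dZ))
  dh2 <- relu_bwd(crossprod(p$fc3$W, dZ), cache$z2)
  g$fc2 <- list(W = tcrossprod(dh2, cache$h1), b = rowSums(dh2))
  dh1 <- relu_bwd(crossprod(p$fc2$W, dh2), cache$z1)
  g$fc1 <- list(W = tcrossprod(dh1, cache$kp$out), b = rowSums(dh1))
  dhT <- crossprod(p$fc1$W, dh1)
  if (!is.null(cache$kp$mask)) dhT <- dhT * cache$kp$mask
  dH4 <- array(0, c(u, T_, B)); dH4[, T_, ] <- dhT
  b4 <- rnn_layer_bwd(cache$H3, cache$H4, p$rnn4, dH4, u, B)
  g$rnn4 <- b4[c("Wx", "Wh", "b")]
  b3 <- rnn_layer_bwd(cache$H2, cache$H3, p$rnn3, b4$dX, u, B)
  g$rnn3 <- b3[c("Wx", "Wh", "b")]
  b2 <- rnn_layer_bwd(cache$H1, cache$H2, p$rnn2, b3$dX, u, B)
  g$rnn2 <- b2[c("Wx", "Wh", "b")]
  b1 <- rnn_layer_bwd(cache$X0, cache$H1, p$rnn1, b2$dX, u, B)
  g$rnn1 <- b1[c("Wx", "Wh", "b")]
  g[names(model$params)]
}

model_forward <- function(model, X, train = FALSE) {
  switch(model$arch,
         unet = unet_forward(model, X, train),
         cnn = cnn_forward(model, X, train),
         rnn = rnn_forward(model, X, train),
         stop("unknown architecture: ", model$arch))
}

model_backward <- function(model, cache, dZ) {
  switch(model$arch,
         unet = unet_backward(model, cache, dZ),
         cnn = cnn_backward(model, cache, dZ),
         rnn = rnn_backward(model, cache, dZ))
}
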