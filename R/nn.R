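# Internal neural-network primitives: dense layers, layer normalization,
# ReLU, multi-head self-attention, pre-LN transformer encoder layers, and
# Adam. Parameters are nested lists with numeric-array leaves; every forward
# returns the caches its backward needs. Batches of B equal-length sequences
# of T tokens are stored as (B*T) x d matrices, rows ordered token-major
# within sample (b1t1, b1t2, ..., b2t1, ...).

add_bias <- function(x, b) x + rep(b, each = nrow(x))

nn_linear <- function(d_in, d_out, sd = 0.02) {
  list(W = matrix(rnorm(d_in * d_out, 0, sd), d_in, d_out),
       b = rep(0, d_out))
}

lin_fwd <- function(x, p) add_bias(x %*% p$W, p$b)
lin_bwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W), W = crossprod(x, dy), b = colSums(dy))
}

ln_init <- function(d) list(g = rep(1, d), b = rep(0, d))

ln_fwd <- function(x, p, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- add_bias(xhat * rep(p$g, each = nrow(x)), p$b)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, p) {
  n <- nrow(dy)
  dxhat <- dy * rep(p$g, each = n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx,
       g = colSums(dy * cache$xhat),
       b = colSums(dy))
}

relu <- function(x) (x > 0) * x
relu_grad <- function(x) (x > 0) * 1

attn_init <- function(d, sd = 0.02) {
  list(Wq = matrix(rnorm(d * d, 0, sd), d, d), bq = rep(0, d),
       Wk = matrix(rnorm(d * d, 0, sd), d, d), bk = rep(0, d),
       Wv = matrix(rnorm(d * d, 0, sd), d, d), bv = rep(0, d),
       Wo = matrix(rnorm(d * d, 0, sd), d, d), bo = rep(0, d))
}

# Multi-head self-attention over B sequences of T tokens, vectorised across
# the batch AND the heads: per token index j, the all-head score vector is a
# row-block dot product (Q * K_j) %*% indicator, and the value contraction
# expands the per-head attention weights to the full width. Only the (small)
# token index is looped over.
attn_fwd <- function(x, p, B, T, heads) {
  d <- ncol(x)
  dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  n <- nrow(x)
  Q <- add_bias(x %*% p$Wq, p$bq)
  K <- add_bias(x %*% p$Wk, p$bk)
  V <- add_bias(x %*% p$Wv, p$bv)
  boff <- T * (0:(B - 1))
  exp_j <- lapply(seq_len(T), function(j) rep(j + boff, each = T))
  bm <- head_indicator(d, heads)      # d x heads 0/1 block indicator
  hrep <- rep(seq_len(heads), each = dk)

  S3 <- array(0, c(n, T, heads))
  for (j in seq_len(T))
    S3[, j, ] <- (Q * K[exp_j[[j]], , drop = FALSE]) %*% bm
  S3 <- S3 * scale
  P3 <- array(0, c(n, T, heads))
  for (h in seq_len(heads)) {
    S <- S3[, , h]
    mx <- S[, 1]
    if (T > 1) for (j in 2:T) mx <- pmax(mx, S[, j])
    E <- exp(S - mx)
    P3[, , h] <- E / rowSums(E)
  }
  O <- matrix(0, n, d)
  for (j in seq_len(T)) {
    Pj <- P3[, j, ]
    O <- O + V[exp_j[[j]], , drop = FALSE] * Pj[, hrep]
  }
  list(y = add_bias(O %*% p$Wo, p$bo), Q = Q, K = K, V = V, O = O,
       P = P3, x = x)
}

attn_bwd <- function(dy, cache, p, B, T, heads) {
  d <- ncol(dy)
  dk <- d %/% heads
  scale <- 1 / sqrt(dk)
  n <- nrow(dy)
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  Q <- cache$Q; K <- cache$K; V <- cache$V; P3 <- cache$P
  boff <- T * (0:(B - 1))
  exp_j <- lapply(seq_len(T), function(j) rep(j + boff, each = T))
  bm <- head_indicator(d, heads)
  hrep <- rep(seq_len(heads), each = dk)
  # group-sum over the T consecutive rows of each sample: fold the matrix
  # into a (T, B, d) array in place (no copy) and sum out the first margin
  gsum <- function(M) { dim(M) <- c(T, B, d); colSums(M, dims = 1) }

  dP3 <- array(0, c(n, T, heads))
  dV <- matrix(0, n, d)
  for (j in seq_len(T)) {
    Vj <- V[exp_j[[j]], , drop = FALSE]
    dP3[, j, ] <- (dO * Vj) %*% bm
    Pj <- P3[, j, ]
    dV[j + boff, ] <- dV[j + boff, ] + gsum(Pj[, hrep] * dO)
  }
  dS3 <- array(0, c(n, T, heads))
  for (h in seq_len(heads)) {
    P <- P3[, , h]
    dP <- dP3[, , h]
    dS3[, , h] <- P * (dP - rowSums(dP * P)) * scale
  }
  dQ <- matrix(0, n, d)
  dK <- matrix(0, n, d)
  for (j in seq_len(T)) {
    dSj <- dS3[, j, ]
    dSj <- dSj[, hrep]
    dQ <- dQ + K[exp_j[[j]], , drop = FALSE] * dSj
    dK[j + boff, ] <- dK[j + boff, ] + gsum(dSj * Q)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  x <- cache$x
  list(dx = dx,
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

# 0/1 indicator mapping feature columns to their head, memoised per (d, heads)
head_indicator <- local({
  cache <- list()
  function(d, heads) {
    key <- paste0(d, "_", heads)
    if (is.null(cache[[key]])) {
      dk <- d %/% heads
      m <- matrix(0, d, heads)
      for (h in seq_len(heads)) m[((h - 1) * dk + 1):(h * dk), h] <- 1
      cache[[key]] <<- m
    }
    cache[[key]]
  }
})

tlayer_init <- function(d, ffn_dim, sd = 0.02) {
  list(ln1 = ln_init(d),
       attn = attn_init(d, sd),
       ln2 = ln_init(d),
       ffn = list(W1 = matrix(rnorm(d * ffn_dim, 0, sd), d, ffn_dim),
                  b1 = rep(0, ffn_dim),
                  W2 = matrix(rnorm(ffn_dim * d, 0, sd), ffn_dim, d),
                  b2 = rep(0, d)))
}

# pre-LN residual transformer encoder layer:
#   x -> x + attn(LN1(x)) -> (+) + ffn(LN2(.))
tlayer_fwd <- function(x, p, B, T, heads) {
  ln1 <- ln_fwd(x, p$ln1)
  att <- attn_fwd(ln1$y, p$attn, B, T, heads)
  x2 <- x + att$y
  ln2 <- ln_fwd(x2, p$ln2)
  a1 <- add_bias(ln2$y %*% p$ffn$W1, p$ffn$b1)
  g1 <- relu(a1)
  y <- x2 + add_bias(g1 %*% p$ffn$W2, p$ffn$b2)
  list(y = y, ln1 = ln1, att = att, x2 = x2, ln2 = ln2, a1 = a1, g1 = g1)
}

tlayer_bwd <- function(dy, cache, p, B, T, heads) {
  dW2 <- crossprod(cache$g1, dy)
  db2 <- colSums(dy)
  dg1 <- dy %*% t(p$ffn$W2)
  da1 <- dg1 * relu_grad(cache$a1)
  dW1 <- crossprod(cache$ln2$y, da1)
  db1 <- colSums(da1)
  dln2y <- da1 %*% t(p$ffn$W1)
  ln2b <- ln_bwd(dln2y, cache$ln2, p$ln2)
  dx2 <- dy + ln2b$dx
  attb <- attn_bwd(dx2, cache$att, p$attn, B, T, heads)
  ln1b <- ln_bwd(attb$dx, cache$ln1, p$ln1)
  dx <- dx2 + ln1b$dx
  list(dx = dx,
       grads = list(ln1 = list(g = ln1b$g, b = ln1b$b),
                    attn = attb$grads,
                    ln2 = list(g = ln2b$g, b = ln2b$b),
                    ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

tstack_init <- function(n_layers, d, ffn_dim, sd = 0.02) {
  lapply(seq_len(n_layers), function(i) tlayer_init(d, ffn_dim, sd))
}

tstack_fwd <- function(x, layers, B, T, heads) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    caches[[l]] <- tlayer_fwd(x, layers[[l]], B, T, heads)
    x <- caches[[l]]$y
  }
  list(y = x, caches = caches)
}

tstack_bwd <- function(dy, caches, layers, B, T, heads) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    b <- tlayer_bwd(dy, caches[[l]], layers[[l]], B, T, heads)
    grads[[l]] <- b$grads
    dy <- b$dx
  }
  list(dx = dy, grads = grads)
}

# ---- Adam over nested parameter lists -------------------------------------

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like) else p * 0
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- step(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      p <- p - opt$lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- step(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(params = r$p, opt = opt)
}

# sum of all parameter entries' squares; used for freeze-contract checks
nn_param_checksum <- function(p) {
  if (is.list(p)) sum(vapply(p, nn_param_checksum, numeric(1)))
  else sum(as.numeric(p)^2)
}
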