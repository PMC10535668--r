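#' Architecture and training hyperparameters of the heart-rate network
#'
#' The network has three transformer parts: a masked-autoencoder (MAE)
#' encoder pretrained by reconstructing randomly masked token patches of
#' unlabeled phase windows, a lightweight MAE decoder used only during
#' pretraining, and a ViT regression stage that consumes the frozen encoder's
#' output and maps the class-token state to a heart rate.
#'
#' Defaults are the full-size architecture: 8 encoder layers at width 128,
#' 5 decoder layers at width 64, 5 ViT layers at width 64, 16 attention heads,
#' feed-forward width 2048, 40% masking, Adam at learning rate 5e-5. See
#' [mvn_desk_config()] for a reduced profile sized for single-CPU runs.
#'
#' @param enc_layers,enc_dim MAE encoder depth and width.
#' @param dec_layers,dec_dim MAE decoder depth and width.
#' @param vit_layers,vit_dim ViT regression stage depth and width.
#' @param heads Attention heads (must divide every width).
#' @param ffn_dim Feed-forward hidden width inside each transformer layer.
#' @param mask_ratio Fraction of data tokens masked during pretraining,
#'   in (0, 1); the class token is never masked.
#' @param patch_len Frames per token patch; must divide the window length.
#' @param learning_rate Adam learning rate (both stages).
#' @param pretrain_epochs,finetune_epochs Training epochs per stage; the
#'   retained model is the best-validation checkpoint, not the last epoch.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for initialization, masking and batch order.
#' @param label_scale BPM divisor mapping regression targets into (0, 1).
#' @param loss_on `"masked"` (reconstruction loss on masked tokens only,
#'   the MAE convention) or `"all"`.
#' @return An object of class `mvn_config`.
#' @export
mvn_config <- function(enc_layers = 8, enc_dim = 128,
                       dec_layers = 5, dec_dim = 64,
                       vit_layers = 5, vit_dim = 64,
                       heads = 16, ffn_dim = 2048,
                       mask_ratio = 0.40, patch_len = 8,
                       learning_rate = 5e-5,
                       pretrain_epochs = 300, finetune_epochs = 300,
                       batch_size = 64, seed = 1, label_scale = 200,
                       loss_on = c("masked", "all")) {
  loss_on <- match.arg(loss_on)
  stopifnot(enc_layers >= 1, dec_layers >= 1, vit_layers >= 1,
            mask_ratio > 0, mask_ratio < 1,
            patch_len >= 1, learning_rate > 0, batch_size >= 1,
            pretrain_epochs >= 1, finetune_epochs >= 1, label_scale > 0)
  if (enc_dim %% heads || dec_dim %% heads || vit_dim %% heads)
    stop("heads must divide enc_dim, dec_dim and vit_dim")
  structure(list(
    enc_layers = enc_layers, enc_dim = enc_dim,
    dec_layers = dec_layers, dec_dim = dec_dim,
    vit_layers = vit_layers, vit_dim = vit_dim,
    heads = heads, ffn_dim = ffn_dim,
    mask_ratio = mask_ratio, patch_len = patch_len,
    learning_rate = learning_rate,
    pretrain_epochs = pretrain_epochs, finetune_epochs = finetune_epochs,
    batch_size = batch_size, seed = as.integer(seed),
    label_scale = label_scale, loss_on = loss_on
  ), class = "mvn_config")
}

#' Reduced architecture profile for single-CPU experiments
#'
#' A 4-layer/width-64 encoder profile (2-layer decoder and ViT, 8 heads,
#' feed-forward 256, Adam at 1e-3) that trains in minutes on one CPU while
#' preserving the full architecture's structure: asymmetric encoder/decoder,
#' 40% masking, frozen-encoder transfer, class-token regression.
#'
#' @param ... Overrides passed on to [mvn_config()].
#' @return An `mvn_config` object.
#' @export
mvn_desk_config <- function(...) {
  defaults <- list(enc_layers = 4, enc_dim = 64, dec_layers = 2,
                   dec_dim = 32, vit_layers = 2, vit_dim = 32,
                   heads = 8, ffn_dim = 128, learning_rate = 2e-3,
                   pretrain_epochs = 200, finetune_epochs = 300,
                   batch_size = 64)
  do.call(mvn_config, modifyList(defaults, list(...)))
}

#' @export
print.mvn_config <- function(x, ...) {
  cat(sprintf(
    "MVN config: enc %dx%d | dec %dx%d | vit %dx%d | %d heads, ffn %d\n",
    x$enc_layers, x$enc_dim, x$dec_layers, x$dec_dim, x$vit_layers,
    x$vit_dim, x$heads, x$ffn_dim))
  cat(sprintf("  mask %.0f%%, patch %d frames, lr %g, batch %d, epochs %d/%d\n",
              100 * x$mask_ratio, x$patch_len, x$learning_rate,
              x$batch_size, x$pretrain_epochs, x$finetune_epochs))
  invisible(x)
}

#' Cut a phase window into non-overlapping time-patch tokens
#'
#' Splits a W-frame, `n_bins`-column phase window into `W / patch_len`
#' tokens, each the flattened `patch_len x n_bins` block (column-major),
#' ordered by time.
#'
#' @param window A `phase_window` or its W x n_bins matrix.
#' @param patch_len Frames per token; must divide W.
#' @return Matrix of `W / patch_len` token rows, each of length
#'   `patch_len * n_bins`.
#' @export
patchify <- function(window, patch_len = 8) {
  m <- if (inherits(window, "phase_window")) window$matrix else window
  stopifnot(is.matrix(m))
  W <- nrow(m)
  if (W %% patch_len != 0)
    stop("patch_len must divide the window length")
  n_tok <- W %/% patch_len
  out <- matrix(0, n_tok, patch_len * ncol(m))
  for (t in seq_len(n_tok)) {
    out[t, ] <- as.vector(m[((t - 1) * patch_len + 1):(t * patch_len), ,
                            drop = FALSE])
  }
  out
}

#' @rdname patchify
#' @param tokens Token matrix produced by `patchify`.
#' @param n_bins Number of range-bin columns of the original window.
#' @export
unpatchify <- function(tokens, patch_len = 8, n_bins = 5) {
  stopifnot(is.matrix(tokens), ncol(tokens) == patch_len * n_bins)
  out <- matrix(0, nrow(tokens) * patch_len, n_bins)
  for (t in seq_len(nrow(tokens))) {
    out[((t - 1) * patch_len + 1):(t * patch_len), ] <-
      matrix(tokens[t, ], patch_len, n_bins)
  }
  out
}

#' Draw a random token mask
#'
#' Masks exactly `round(ratio * n_tokens)` data tokens, uniformly without
#' replacement, from the current RNG state. The class token is not part of
#' the data-token index set and is therefore never masked.
#'
#' @param n_tokens Number of data tokens.
#' @param ratio Masking ratio in (0, 1); must leave at least one masked and
#'   one visible token.
#' @return List with sorted integer vectors `visible` and `masked`
#'   partitioning `1:n_tokens`.
#' @export
random_mask <- function(n_tokens, ratio = 0.40) {
  stopifnot(ratio > 0, ratio < 1, n_tokens >= 2)
  m <- round(ratio * n_tokens)
  if (m < 1 || m >= n_tokens)
    stop("mask ratio leaves no masked or no visible tokens")
  masked <- sort(sample.int(n_tokens, m))
  list(visible = setdiff(seq_len(n_tokens), masked), masked = masked)
}

# ---- internal model builders and passes -----------------------------------

mae_init_params <- function(cfg, patch_dim, n_tokens) {
  list(
    enc = list(
      emb = nn_linear(patch_dim, cfg$enc_dim),
      cls = rnorm(cfg$enc_dim, 0, 0.02),
      pos = matrix(rnorm((n_tokens + 1) * cfg$enc_dim, 0, 0.02),
                   n_tokens + 1, cfg$enc_dim),
      layers = tstack_init(cfg$enc_layers, cfg$enc_dim, cfg$ffn_dim),
      lnf = ln_init(cfg$enc_dim)),
    dec = list(
      proj = nn_linear(cfg$enc_dim, cfg$dec_dim),
      mask_tok = rnorm(cfg$dec_dim, 0, 0.02),
      pos = matrix(rnorm(n_tokens * cfg$dec_dim, 0, 0.02),
                   n_tokens, cfg$dec_dim),
      layers = tstack_init(cfg$dec_layers, cfg$dec_dim, cfg$ffn_dim),
      lnf = ln_init(cfg$dec_dim),
      head = nn_linear(cfg$dec_dim, patch_dim))
  )
}

vit_init_params <- function(cfg, n_tokens) {
  list(
    proj = nn_linear(cfg$enc_dim, cfg$vit_dim),
    pos = matrix(rnorm((n_tokens + 1) * cfg$vit_dim, 0, 0.02),
                 n_tokens + 1, cfg$vit_dim),
    layers = tstack_init(cfg$vit_layers, cfg$vit_dim, cfg$ffn_dim),
    lnf = ln_init(cfg$vit_dim),
    head = list(W1 = matrix(rnorm(cfg$vit_dim^2, 0, 0.02),
                            cfg$vit_dim, cfg$vit_dim),
                b1 = rep(0, cfg$vit_dim),
                W2 = matrix(rnorm(cfg$vit_dim, 0, 0.02), cfg$vit_dim, 1),
                b2 = 0))
}

# Encoder forward over a batch. tokmat: (B*Td) x patch_dim rows ordered
# token-major within sample; posids: original 1-based token positions per
# row. Prepends the class token (positional slot 1; data token t sits in
# slot t+1). Returns (B*(Td+1)) x d output plus caches.
enc_fwd <- function(enc, tokmat, posids, B, Td, heads) {
  d <- length(enc$cls)
  E <- add_bias(tokmat %*% enc$emb$W, enc$emb$b)
  E <- E + enc$pos[posids + 1L, , drop = FALSE]
  Tseq <- Td + 1L
  cls_rows <- (0:(B - 1)) * Tseq + 1L
  data_rows <- rep((0:(B - 1)) * Tseq + 1L, each = Td) + rep(seq_len(Td), B)
  X <- matrix(0, B * Tseq, d)
  X[cls_rows, ] <- matrix(enc$cls + enc$pos[1L, ], B, d, byrow = TRUE)
  X[data_rows, ] <- E
  st <- tstack_fwd(X, enc$layers, B, Tseq, heads)
  lnf <- ln_fwd(st$y, enc$lnf)
  list(y = lnf$y, lnf = lnf, stack = st, cls_rows = cls_rows,
       data_rows = data_rows, posids = posids, tokmat = tokmat,
       Tseq = Tseq)
}

enc_bwd <- function(dY, fw, enc, B, heads) {
  Tseq <- fw$Tseq
  lnfb <- ln_bwd(dY, fw$lnf, enc$lnf)
  stb <- tstack_bwd(lnfb$dx, fw$stack$caches, enc$layers, B, Tseq, heads)
  dX <- stb$dx
  dE <- dX[fw$data_rows, , drop = FALSE]
  dcls_tot <- colSums(dX[fw$cls_rows, , drop = FALSE])
  dpos <- matrix(0, nrow(enc$pos), ncol(enc$pos))
  dpos[1L, ] <- dcls_tot
  agg <- rowsum(dE, fw$posids)
  dpos[as.integer(rownames(agg)) + 1L, ] <-
    dpos[as.integer(rownames(agg)) + 1L, ] + agg
  list(grads = list(
    emb = list(W = crossprod(fw$tokmat, dE), b = colSums(dE)),
    cls = dcls_tot,
    pos = dpos,
    layers = stb$grads,
    lnf = list(g = lnfb$g, b = lnfb$b)))
}

# Decoder forward: project visible-token latents, scatter them into the full
# token grid with the learnable mask token at masked slots, add decoder
# positional embeddings, run the stack, and linearly map back to patch space.
dec_fwd <- function(dec, encY, enc_fwd_cache, Vis, B, T_full, heads) {
  dd <- length(dec$mask_tok)
  lat <- encY[enc_fwd_cache$data_rows, , drop = FALSE]
  Z <- add_bias(lat %*% dec$proj$W, dec$proj$b)
  nv <- ncol(Vis)
  vis_rows <- rep((0:(B - 1)) * T_full, each = nv) + as.vector(t(Vis))
  G <- matrix(dec$mask_tok, B * T_full, dd, byrow = TRUE)
  G[vis_rows, ] <- Z
  posids_full <- rep(seq_len(T_full), B)
  G <- G + dec$pos[posids_full, , drop = FALSE]
  st <- tstack_fwd(G, dec$layers, B, T_full, heads)
  lnf <- ln_fwd(st$y, dec$lnf)
  R <- add_bias(lnf$y %*% dec$head$W, dec$head$b)
  list(R = R, lnf = lnf, stack = st, vis_rows = vis_rows, lat = lat,
       posids_full = posids_full)
}

dec_bwd <- function(dR, fw, dec, B, T_full, heads) {
  dhead <- lin_bwd(dR, fw$lnf$y, dec$head)
  lnfb <- ln_bwd(dhead$dx, fw$lnf, dec$lnf)
  stb <- tstack_bwd(lnfb$dx, fw$stack$caches, dec$layers, B, T_full, heads)
  dG <- stb$dx
  dpos <- rowsum(dG, fw$posids_full)
  dZ <- dG[fw$vis_rows, , drop = FALSE]
  dmask_tok <- colSums(dG[-fw$vis_rows, , drop = FALSE])
  dproj <- lin_bwd(dZ, fw$lat, dec$proj)
  list(dlat = dproj$dx,
       grads = list(
         proj = list(W = dproj$W, b = dproj$b),
         mask_tok = dmask_tok,
         pos = dpos,
         layers = stb$grads,
         lnf = list(g = lnfb$g, b = lnfb$b),
         head = list(W = dhead$W, b = dhead$b)))
}

# ViT forward over cached encoder features: per-token projection ("embedding
# encoding"), fresh positional embeddings, transformer stack, final LN, and
# an MLP head on the class-token state only. feats: (B*Tseq) x enc_dim.
vit_fwd <- function(vit, feats, B, Tseq, heads) {
  Z <- add_bias(feats %*% vit$proj$W, vit$proj$b)
  posids <- rep(seq_len(Tseq), B)
  Z <- Z + vit$pos[posids, , drop = FALSE]
  st <- tstack_fwd(Z, vit$layers, B, Tseq, heads)
  lnf <- ln_fwd(st$y, vit$lnf)
  cls_rows <- (0:(B - 1)) * Tseq + 1L
  cls <- lnf$y[cls_rows, , drop = FALSE]
  a1 <- add_bias(cls %*% vit$head$W1, vit$head$b1)
  h1 <- relu(a1)
  pred <- as.vector(h1 %*% vit$head$W2 + vit$head$b2)
  list(pred = pred, lnf = lnf, stack = st, cls = cls, a1 = a1, h1 = h1,
       cls_rows = cls_rows, posids = posids, feats = feats)
}

vit_bwd <- function(dpred, fw, vit, B, Tseq, heads) {
  dpred <- matrix(dpred, ncol = 1)
  dW2 <- crossprod(fw$h1, dpred)
  db2 <- sum(dpred)
  dh1 <- dpred %*% t(vit$head$W2)
  da1 <- dh1 * relu_grad(fw$a1)
  dW1 <- crossprod(fw$cls, da1)
  db1 <- colSums(da1)
  dcls <- da1 %*% t(vit$head$W1)
  dY <- matrix(0, nrow(fw$lnf$y), ncol(fw$lnf$y))
  dY[fw$cls_rows, ] <- dcls
  lnfb <- ln_bwd(dY, fw$lnf, vit$lnf)
  stb <- tstack_bwd(lnfb$dx, fw$stack$caches, vit$layers, B, Tseq, heads)
  dZ <- stb$dx
  dpos <- rowsum(dZ, fw$posids)
  dproj <- lin_bwd(dZ, fw$feats, vit$proj)
  list(grads = list(
    proj = list(W = dproj$W, b = dproj$b),
    pos = dpos,
    layers = stb$grads,
    lnf = list(g = lnfb$g, b = lnfb$b),
    head = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

# one pretraining step on a batch of windows; returns loss and grads
mae_batch_pass <- function(params, toks_list, ids, cfg, masks = NULL,
                           grads = TRUE) {
  B <- length(ids)
  T_full <- nrow(toks_list[[ids[1]]])
  pd <- ncol(toks_list[[ids[1]]])
  heads <- cfg$heads
  if (is.null(masks))
    masks <- lapply(seq_len(B), function(i) random_mask(T_full, cfg$mask_ratio))
  nv <- length(masks[[1]]$visible)
  Vis <- t(vapply(masks, function(m) m$visible, integer(nv)))
  nm <- T_full - nv
  Mask <- t(vapply(masks, function(m) m$masked, integer(nm)))
  if (nv == 1L) Vis <- matrix(Vis, B, 1L)
  if (nm == 1L) Mask <- matrix(Mask, B, 1L)

  toks_full <- do.call(rbind, toks_list[ids])
  vis_tok_rows <- rep((0:(B - 1)) * T_full, each = nv) + as.vector(t(Vis))
  tok_vis <- toks_full[vis_tok_rows, , drop = FALSE]
  posids <- as.vector(t(Vis))

  ef <- enc_fwd(params$enc, tok_vis, posids, B, nv, heads)
  df <- dec_fwd(params$dec, ef$y, ef, Vis, B, T_full, heads)

  if (cfg$loss_on == "masked") {
    loss_rows <- rep((0:(B - 1)) * T_full, each = nm) + as.vector(t(Mask))
  } else {
    loss_rows <- seq_len(B * T_full)
  }
  err <- df$R[loss_rows, , drop = FALSE] -
    toks_full[loss_rows, , drop = FALSE]
  loss <- mean(err * err)
  if (!grads)
    return(list(loss = loss))

  dR <- matrix(0, nrow(df$R), pd)
  dR[loss_rows, ] <- 2 * err / length(err)
  db <- dec_bwd(dR, df, params$dec, B, T_full, heads)
  dencY <- matrix(0, nrow(ef$y), ncol(ef$y))
  dencY[ef$data_rows, ] <- db$dlat
  eb <- enc_bwd(dencY, ef, params$enc, B, heads)
  list(loss = loss, grads = list(enc = eb$grads, dec = db$grads))
}

#' Self-supervised pretraining of the masked-autoencoder encoder
#'
#' Trains the asymmetric MAE on unlabeled phase windows: each window is cut
#' into time-patch tokens, a random 40% (by default) of tokens is masked, the
#' encoder sees only the visible tokens (plus its class token), and the
#' decoder reconstructs the full token grid from the encoded latents and a
#' learnable mask token. Adam minimizes the reconstruction MSE on the masked
#' tokens; the retained parameters are the checkpoint with the lowest
#' held-out reconstruction MSE (fixed validation split and masks).
#'
#' @param x List of `phase_window` objects or plain W x bins matrices
#'   (labels, if any, are ignored).
#' @param config An [mvn_config()].
#' @param val_fraction Fraction of windows held out for checkpoint selection.
#' @param epochs Override of `config$pretrain_epochs`.
#' @param verbose Print per-epoch losses.
#' @return An object of class `mvn_encoder`: trained parameters (`params`,
#'   with `$enc` and `$dec`), `history` (per-epoch train/validation loss),
#'   `best_epoch`, and the token geometry.
#' @export
mvn_pretrain <- function(x, config = mvn_config(), val_fraction = 0.1,
                         epochs = config$pretrain_epochs, verbose = FALSE) {
  stopifnot(length(x) >= 1)
  mats <- lapply(x, function(w) if (inherits(w, "phase_window")) w$matrix else w)
  W <- nrow(mats[[1]])
  n_bins <- ncol(mats[[1]])
  if (W %% config$patch_len != 0)
    stop("patch_len must divide the window length")
  toks <- lapply(mats, patchify, patch_len = config$patch_len)
  T_full <- W %/% config$patch_len
  pd <- config$patch_len * n_bins

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  params <- mae_init_params(config, pd, T_full)
  n <- length(toks)
  n_val <- if (n >= 5) max(1L, round(val_fraction * n)) else 0L
  val_ids <- if (n_val > 0) sample.int(n, n_val) else integer()
  train_ids <- setdiff(seq_len(n), val_ids)
  val_masks <- lapply(val_ids, function(i) random_mask(T_full, config$mask_ratio))

  opt <- adam_new(params, lr = config$learning_rate)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  bs <- config$batch_size
  for (ep in seq_len(epochs)) {
    ord <- sample(train_ids)
    ep_loss <- 0; nb <- 0
    for (s in seq(1, length(ord), by = bs)) {
      ids <- ord[s:min(s + bs - 1, length(ord))]
      r <- mae_batch_pass(params, toks, ids, config)
      st <- adam_step(opt, params, r$grads)
      params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + r$loss; nb <- nb + 1
    }
    val_loss <- if (n_val > 0) {
      mae_batch_pass(params, toks, val_ids, config, masks = val_masks,
                     grads = FALSE)$loss
    } else ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      ep_loss / nb, val_loss))
  }
  structure(list(params = best$params, config = config, history = hist,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 n_tokens = T_full, patch_dim = pd, n_bins = n_bins,
                 window_frames = W, pretrained = TRUE),
            class = "mvn_encoder")
}

#' Randomly initialized (untrained) encoder
#'
#' The from-scratch control used in the pretraining ablation: identical
#' architecture and initialization distribution, no self-supervised training.
#'
#' @param config An [mvn_config()].
#' @param window_frames Window length W in frames.
#' @param n_bins Number of range-bin columns.
#' @return An `mvn_encoder` with `pretrained = FALSE`.
#' @export
mvn_encoder_random <- function(config = mvn_config(), window_frames = 128,
                               n_bins = 5) {
  if (window_frames %% config$patch_len != 0)
    stop("patch_len must divide the window length")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  T_full <- window_frames %/% config$patch_len
  pd <- config$patch_len * n_bins
  structure(list(params = mae_init_params(config, pd, T_full),
                 config = config, history = NULL, best_epoch = 0L,
                 best_val_loss = NA_real_, n_tokens = T_full,
                 patch_dim = pd, n_bins = n_bins,
                 window_frames = window_frames, pretrained = FALSE),
            class = "mvn_encoder")
}

#' @export
print.mvn_encoder <- function(x, ...) {
  cat(sprintf("MAE encoder (%s): %d layers x %d dim, %d tokens of %d frames\n",
              if (x$pretrained) "pretrained" else "random init",
              x$config$enc_layers, x$config$enc_dim, x$n_tokens,
              x$config$patch_len))
  if (x$pretrained)
    cat(sprintf("  best held-out reconstruction MSE %.5f at epoch %d/%d\n",
                x$best_val_loss, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
plot.mvn_encoder <- function(x, ...) {
  if (is.null(x$history)) stop("no training history (random encoder)")
  plot(x$history$epoch, x$history$train_loss, type = "l",
       xlab = "epoch", ylab = "reconstruction MSE",
       main = "MAE pretraining", ...)
  lines(x$history$epoch, x$history$val_loss, lty = 2)
  abline(v = x$best_epoch, col = "grey")
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Encode tokens with the MAE encoder
#'
#' Forward pass of the encoder on one window's visible tokens (all tokens by
#' default, as in the transfer stage). Returns the latent vectors with the
#' class-token state as the first row.
#'
#' @param encoder An `mvn_encoder`.
#' @param window A `phase_window`, W x bins matrix, or token matrix.
#' @param visible Optional sorted integer vector of visible token positions.
#' @return Matrix of `(length(visible) + 1)` latent rows of width `enc_dim`.
#' @export
mae_encode <- function(encoder, window, visible = NULL) {
  toks <- if (is.matrix(window) && ncol(window) == encoder$patch_dim) {
    window
  } else {
    patchify(if (inherits(window, "phase_window")) window$matrix else window,
             encoder$config$patch_len)
  }
  if (nrow(toks) != encoder$n_tokens)
    stop("token count mismatch")
  if (is.null(visible)) visible <- seq_len(encoder$n_tokens)
  ef <- enc_fwd(encoder$params$enc, toks[visible, , drop = FALSE],
                visible, 1L, length(visible), encoder$config$heads)
  ef$y
}

#' Reconstruct a full token grid with the MAE decoder
#'
#' @param encoder An `mvn_encoder` (carries the decoder parameters).
#' @param latents Output of [mae_encode()] on the visible tokens.
#' @param masked Sorted masked token positions (complement of the visible
#'   set); may be empty.
#' @return Reconstructed token matrix (`n_tokens` x `patch_dim`).
#' @export
mae_decode <- function(encoder, latents, masked) {
  T_full <- encoder$n_tokens
  visible <- setdiff(seq_len(T_full), masked)
  if (nrow(latents) != length(visible) + 1L)
    stop("masked index set inconsistent with the latents")
  ef <- list(data_rows = 1L + seq_along(visible))
  Vis <- matrix(visible, 1L, length(visible))
  df <- dec_fwd(encoder$params$dec, latents, ef, Vis, 1L, T_full,
                encoder$config$heads)
  df$R
}

# encode a list of windows (full tokens, no masking) into the feature matrix
# consumed by the transfer stage; (n * (n_tokens+1)) x enc_dim
encode_features <- function(encoder, x, batch_size = 64) {
  mats <- lapply(x, function(w) if (inherits(w, "phase_window")) w$matrix else w)
  toks <- lapply(mats, patchify, patch_len = encoder$config$patch_len)
  T_full <- encoder$n_tokens
  Tseq <- T_full + 1L
  n <- length(toks)
  feats <- matrix(0, n * Tseq, encoder$config$enc_dim)
  posids_unit <- seq_len(T_full)
  for (s in seq(1, n, by = batch_size)) {
    ids <- s:min(s + batch_size - 1, n)
    B <- length(ids)
    tokmat <- do.call(rbind, toks[ids])
    ef <- enc_fwd(encoder$params$enc, tokmat, rep(posids_unit, B), B,
                  T_full, encoder$config$heads)
    rows <- rep((ids - 1L) * Tseq, each = Tseq) + rep(seq_len(Tseq), B)
    feats[rows, ] <- ef$y
  }
  list(feats = feats, Tseq = Tseq)
}

feat_rows <- function(ids, Tseq) {
  rep((ids - 1L) * Tseq, each = Tseq) + rep(seq_len(Tseq), length(ids))
}

#' Fit the heart-rate regression stage on a frozen encoder
#'
#' The transfer-learning fit: every labeled window is passed (unmasked)
#' through the frozen MAE encoder once, and a ViT regression stage — per-token
#' projection, positional embeddings, transformer layers, final layer
#' normalization, and an MLP head applied to the class-token state — is
#' trained with Adam on the MSE between predicted and reference heart rate
#' scaled by `label_scale`. Encoder parameters are never updated. The
#' retained stage is the best-validation-MSE checkpoint.
#'
#' @param x List of labeled `phase_window` objects, or of W x bins matrices
#'   (then supply `labels`).
#' @param labels Optional numeric vector of reference heart rates in BPM.
#' @param encoder A pretrained (or deliberately random) [mvn_pretrain()]
#'   encoder.
#' @param config Defaults to the encoder's config.
#' @param head `"vit"` for the full transformer regression stage, or
#'   `"linear"` for a single linear layer on the encoder's class-token state
#'   (the transfer-learning ablation control).
#' @param val_fraction Fraction of labeled windows held out for checkpoint
#'   selection.
#' @param epochs Override of `config$finetune_epochs`.
#' @param verbose Print per-epoch losses.
#' @return An object of class `mvn` with `print`, `summary`, `predict`,
#'   `plot`, `fitted` and `residuals` methods.
#' @export
mvn <- function(x, labels = NULL, encoder, config = encoder$config,
                head = c("vit", "linear"), val_fraction = 0.2,
                epochs = config$finetune_epochs, verbose = FALSE) {
  head <- match.arg(head)
  stopifnot(inherits(encoder, "mvn_encoder"), length(x) >= 1)
  if (is.null(labels)) {
    labels <- vapply(x, function(w) {
      if (!inherits(w, "phase_window")) stop("labels required for plain matrices")
      w$label
    }, numeric(1))
  }
  if (anyNA(labels) || any(labels <= 0))
    stop("all labels must be positive heart rates in BPM")
  if (length(unique(labels)) == 1L)
    warning("all labels identical: degenerate regression target")

  y <- labels / config$label_scale
  fe <- encode_features(encoder, x, config$batch_size)
  Tseq <- fe$Tseq
  n <- length(labels)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed + 1L)

  enc_checksum <- nn_param_checksum(encoder$params$enc)
  # validation holdout at recording level where possible: windows of one
  # recording are highly correlated, and a window-level holdout would favor
  # checkpoints that memorize recordings over ones that generalize
  rec_of <- vapply(x, function(w) {
    if (inherits(w, "phase_window")) w$recording_id else NA_character_
  }, character(1))
  val_ids <- integer()
  if (n >= 5) {
    recs <- unique(rec_of)
    if (!anyNA(rec_of) && length(recs) >= 3) {
      val_recs <- sample(recs, max(1L, round(val_fraction * length(recs))))
      val_ids <- which(rec_of %in% val_recs)
    } else {
      val_ids <- sample.int(n, max(1L, round(val_fraction * n)))
    }
  }
  n_val <- length(val_ids)
  train_ids <- setdiff(seq_len(n), val_ids)

  if (head == "vit") {
    params <- vit_init_params(config, encoder$n_tokens)
  } else {
    params <- nn_linear(config$enc_dim, 1)
  }
  opt <- adam_new(params, lr = config$learning_rate)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  bs <- config$batch_size

  fwd_ids <- function(params, ids) {
    B <- length(ids)
    f <- fe$feats[feat_rows(ids, Tseq), , drop = FALSE]
    if (head == "vit") {
      vit_fwd(params, f, B, Tseq, config$heads)
    } else {
      cls <- f[(0:(B - 1)) * Tseq + 1L, , drop = FALSE]
      list(pred = as.vector(cls %*% params$W + params$b), cls = cls)
    }
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(train_ids)
    ep_loss <- 0; nb <- 0
    for (s in seq(1, length(ord), by = bs)) {
      ids <- ord[s:min(s + bs - 1, length(ord))]
      B <- length(ids)
      fw <- fwd_ids(params, ids)
      err <- fw$pred - y[ids]
      loss <- mean(err * err)
      dpred <- 2 * err / B
      if (head == "vit") {
        g <- vit_bwd(dpred, fw, params, B, Tseq, config$heads)$grads
      } else {
        g <- list(W = crossprod(fw$cls, matrix(dpred, ncol = 1)),
                  b = sum(dpred))
      }
      st <- adam_step(opt, params, g)
      params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    val_loss <- if (n_val > 0) {
      fwv <- fwd_ids(params, val_ids)
      mean((fwv$pred - y[val_ids])^2)
    } else ep_loss / nb
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      ep_loss / nb, val_loss))
  }
  stopifnot(nn_param_checksum(encoder$params$enc) == enc_checksum)

  obj <- structure(list(encoder = encoder, head_type = head,
                        params = best$params, config = config,
                        history = hist, best_epoch = best$epoch,
                        best_val_loss = best$loss, labels = labels,
                        train_ids = train_ids, val_ids = val_ids,
                        call = match.call()),
                   class = "mvn")
  obj$fitted.values <- predict_features(obj, fe)
  obj$residuals <- labels - obj$fitted.values
  obj
}

# predict from already-encoded features
predict_features <- function(object, fe) {
  Tseq <- fe$Tseq
  n <- nrow(fe$feats) / Tseq
  bs <- object$config$batch_size
  out <- numeric(n)
  for (s in seq(1, n, by = bs)) {
    ids <- s:min(s + bs - 1, n)
    B <- length(ids)
    f <- fe$feats[feat_rows(ids, Tseq), , drop = FALSE]
    out[ids] <- if (object$head_type == "vit") {
      vit_fwd(object$params, f, B, Tseq, object$config$heads)$pred
    } else {
      cls <- f[(0:(B - 1)) * Tseq + 1L, , drop = FALSE]
      as.vector(cls %*% object$params$W + object$params$b)
    }
  }
  out * object$config$label_scale
}

#' Predict heart rates for new phase windows
#'
#' Deterministic forward pass (no masking) through the frozen encoder and the
#' fitted regression stage.
#'
#' @param object A fitted [mvn()] model.
#' @param newdata A list of `phase_window` objects / matrices, or a single
#'   window.
#' @param ... Unused.
#' @return Numeric vector of heart-rate estimates in BPM.
#' @export
predict.mvn <- function(object, newdata, ...) {
  if (inherits(newdata, "phase_window") ||
      (is.matrix(newdata) && !is.list(newdata)))
    newdata <- list(newdata)
  fe <- encode_features(object$encoder, newdata, object$config$batch_size)
  predict_features(object, fe)
}

#' @export
print.mvn <- function(x, ...) {
  cat(sprintf("MVN heart-rate model (%s head, %s encoder)\n",
              x$head_type,
              if (x$encoder$pretrained) "pretrained" else "random"))
  cat(sprintf("  %d labeled windows; best val MSE %.5f (scaled) at epoch %d/%d\n",
              length(x$labels), x$best_val_loss, x$best_epoch,
              nrow(x$history)))
  cat(sprintf("  training AAEP %.2f%%\n",
              aaep(x$fitted.values, x$labels)))
  invisible(x)
}

#' @export
summary.mvn <- function(object, ...) {
  res <- list(
    head_type = object$head_type,
    pretrained = object$encoder$pretrained,
    n_labeled = length(object$labels),
    best_epoch = object$best_epoch,
    best_val_mse_scaled = object$best_val_loss,
    train_aaep = aaep(object$fitted.values, object$labels),
    train_mse_bpm = mse(object$labels, object$fitted.values),
    residual_summary = summary(object$residuals))
  class(res) <- "summary.mvn"
  res
}

#' @export
print.summary.mvn <- function(x, ...) {
  cat(sprintf("MVN model: %s head, %s encoder, %d labeled windows\n",
              x$head_type, if (x$pretrained) "pretrained" else "random",
              x$n_labeled))
  cat(sprintf("  best checkpoint: epoch %d, validation MSE (scaled) %.5f\n",
              x$best_epoch, x$best_val_mse_scaled))
  cat(sprintf("  training AAEP %.2f%%, MSE %.2f BPM^2\n",
              x$train_aaep, x$train_mse_bpm))
  cat("  residuals (BPM):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
plot.mvn <- function(x, ...) {
  plot(x$history$epoch, x$history$train_loss, type = "l",
       xlab = "epoch", ylab = "MSE (scaled heart rate)",
       main = "transfer-learning fit", ...)
  lines(x$history$epoch, x$history$val_loss, lty = 2)
  abline(v = x$best_epoch, col = "grey")
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
residuals.mvn <- function(object, ...) object$residuals

#' @export
fitted.mvn <- function(object, ...) object$fitted.values
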