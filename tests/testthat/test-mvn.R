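# tiny architecture + sinusoidal toy windows keep these tests fast; the
# geometry (tokens, masking, class token, freezing) is identical to the
# full-size model
tiny_cfg <- mvn_config(enc_layers = 2, enc_dim = 16, dec_layers = 2,
                       dec_dim = 8, vit_layers = 2, vit_dim = 8,
                       heads = 4, ffn_dim = 32, patch_len = 8,
                       learning_rate = 2e-3, pretrain_epochs = 150,
                       finetune_epochs = 80, batch_size = 16, seed = 5)

toy_windows <- local({
  set.seed(99)
  f <- runif(48, 1.0, 1.7)
  lapply(f, function(fi) {
    t <- (1:64) / 50
    m <- matrix(sin(2 * pi * fi * t), 64, 5) +
      matrix(rnorm(64 * 5, 0, 0.2), 64, 5)
    structure(list(matrix = (m - mean(m)) / sd(m), label = 60 * fi,
                   recording_id = sprintf("r%02d", seq_along(f)[which(f == fi)]),
                   start_frame = 1L), class = "phase_window")
  })
})

test_that("mvn_config validates the architecture invariants", {
  expect_error(mvn_config(heads = 5), "divide")
  expect_error(mvn_config(mask_ratio = 0))
  expect_error(mvn_config(mask_ratio = 1))
  cfg <- mvn_config()
  expect_equal(cfg$enc_layers, 8)
  expect_equal(cfg$enc_dim, 128)
  expect_equal(cfg$dec_layers, 5)
  expect_equal(cfg$dec_dim, 64)
  expect_equal(cfg$vit_layers, 5)
  expect_equal(cfg$heads, 16)
  expect_equal(cfg$ffn_dim, 2048)
  expect_equal(cfg$mask_ratio, 0.40)
  expect_equal(cfg$learning_rate, 5e-5)
})

test_that("patchify produces time patches and round-trips losslessly", {
  m <- matrix(rnorm(128 * 5), 128, 5)
  tok <- patchify(m, 8)
  expect_equal(dim(tok), c(16L, 40L))
  expect_identical(unpatchify(tok, 8, 5), m)
  tok2 <- patchify(matrix(rnorm(256 * 5), 256, 5), 8)
  expect_equal(nrow(tok2), 32L)
  expect_error(patchify(m, 7), "divide")
})

test_that("random_mask flags the exact count and samples uniformly", {
  set.seed(1)
  mk <- random_mask(100, 0.40)
  expect_length(mk$masked, 40L)
  expect_length(mk$visible, 60L)
  expect_identical(sort(c(mk$visible, mk$masked)), 1:100)

  set.seed(2)
  m1 <- random_mask(20, 0.4)
  set.seed(2)
  m2 <- random_mask(20, 0.4)
  expect_identical(m1, m2)

  # binomial check: each of 10 tokens masked with frequency ~0.4
  set.seed(3)
  counts <- integer(10)
  n_draw <- 10000
  for (i in seq_len(n_draw)) {
    mk_i <- random_mask(10, 0.4)$masked
    counts[mk_i] <- counts[mk_i] + 1L
  }
  freq <- counts / n_draw
  se <- sqrt(0.4 * 0.6 / n_draw)
  expect_true(all(abs(freq - 0.4) < 3 * se))
  expect_error(random_mask(2, 0.1), "no masked")
})

test_that("mae_encode yields visible+1 latents; masking changes them", {
  enc <- mvn_encoder_random(tiny_cfg, window_frames = 64, n_bins = 5)
  w <- toy_windows[[1]]
  full <- mae_encode(enc, w)
  expect_equal(dim(full), c(9L, 16L))     # 8 tokens + class
  vis <- c(1, 2, 4, 7, 8)
  part <- mae_encode(enc, w, visible = vis)
  expect_equal(nrow(part), length(vis) + 1L)
  # same tokens, different visibility -> different latents for shared tokens
  expect_false(isTRUE(all.equal(part[2, ], full[2, ])))
})

test_that("mae_decode reconstructs the full token grid for any mask", {
  enc <- mvn_encoder_random(tiny_cfg, window_frames = 64, n_bins = 5)
  w <- toy_windows[[2]]
  masked <- c(3, 5, 6)
  lat <- mae_encode(enc, w, visible = setdiff(1:8, masked))
  R <- mae_decode(enc, lat, masked)
  expect_equal(dim(R), c(8L, 40L))
  expect_true(all(is.finite(R)))
  # degenerate: nothing masked still reconstructs every position
  R0 <- mae_decode(enc, mae_encode(enc, w), integer())
  expect_equal(dim(R0), c(8L, 40L))
  expect_error(mae_decode(enc, lat, c(2, 5)), "inconsistent")
})

test_that("pretraining reduces held-out reconstruction error and is seed-deterministic", {
  enc <- mvn_pretrain(toy_windows, tiny_cfg)
  expect_equal(nrow(enc$history), tiny_cfg$pretrain_epochs)
  expect_lt(enc$best_val_loss, enc$history$val_loss[1])
  # >= 10x better than the untrained model on masked reconstruction
  expect_gt(enc$history$val_loss[1] / enc$best_val_loss, 10)

  enc2 <- mvn_pretrain(toy_windows, tiny_cfg)
  expect_equal(enc$history$train_loss[tiny_cfg$pretrain_epochs],
               enc2$history$train_loss[tiny_cfg$pretrain_epochs],
               tolerance = 1e-9)
})

test_that("finetuning freezes the encoder bit-exactly and fits the toy set", {
  enc <- mvn_pretrain(toy_windows, tiny_cfg)
  enc_before <- enc$params$enc
  fit <- mvn(toy_windows[1:36], encoder = enc)
  expect_identical(enc$params$enc, enc_before)
  expect_identical(fit$encoder$params$enc, enc_before)

  # optimization made progress
  expect_lt(fit$best_val_loss, fit$history$val_loss[1])
  expect_lt(fit$history$train_loss[fit$best_epoch],
            fit$history$train_loss[1])

  # converged training-window predictions are close on the easy toy set
  expect_lt(max(abs(fit$fitted.values[fit$train_ids] -
                      fit$labels[fit$train_ids])), 10)

  # residuals/fitted accessors agree
  expect_equal(fitted(fit) + residuals(fit), fit$labels)
})

test_that("prediction is deterministic and batch-consistent", {
  enc <- mvn_encoder_random(tiny_cfg, 64, 5)
  fit <- mvn(toy_windows[1:20], encoder = enc, epochs = 3)
  p1 <- predict(fit, toy_windows[21:24])
  p2 <- predict(fit, toy_windows[21:24])
  expect_identical(p1, p2)
  single <- vapply(toy_windows[21:24], function(w) predict(fit, w),
                   numeric(1))
  expect_equal(p1, single, tolerance = 1e-10)
  expect_true(all(is.finite(p1)))

  # zero-input window still yields a finite scalar
  z <- matrix(0, 64, 5)
  expect_true(is.finite(predict(fit, z)))
})

test_that("linear-head variant trains only its own two parameters", {
  enc <- mvn_encoder_random(tiny_cfg, 64, 5)
  fit <- mvn(toy_windows[1:20], encoder = enc, head = "linear", epochs = 10)
  expect_equal(length(fit$params), 2L)   # W and b only
  expect_identical(fit$encoder$params$enc, enc$params$enc)
  expect_true(all(is.finite(predict(fit, toy_windows[21:22]))))
})

test_that("degenerate labels warn but do not fail", {
  enc <- mvn_encoder_random(tiny_cfg, 64, 5)
  ws <- toy_windows[1:8]
  expect_warning(mvn(ws, labels = rep(72, 8), encoder = enc, epochs = 2),
                 "identical")
})
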