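# STFT spectrogram contracts, encoder determinism, projector geometry,
# checkpoint round trip, and finite-difference verification of the
# backward passes.

test_that("spectrogram shape and frequency mapping are correct", {
  spec <- encoder_spec(C = 1, N = 300, fs = 100, stft_window = 100,
                       stft_hop = 25, conv_channels = c(2, 2, 2, 2),
                       log_compress = FALSE)
  x <- sine_epoch(freq = 10, fs = 100, N = 300)
  s <- stft_spectrogram(x, spec)
  Tf <- (300L - 100L) %/% 25L + 1L
  expect_identical(dim(s), c(1L, 51L, Tf))
  # bin index for 10 Hz: 10 * window / fs = 10 (1-based: 11)
  for (t in seq_len(Tf)) expect_identical(which.max(s[1, , t]), 11L)

  dc <- signal_epoch(matrix(1, 1, 300), fs = 100)
  sdc <- stft_spectrogram(dc, spec)
  for (t in seq_len(Tf)) {
    expect_identical(which.max(sdc[1, , t]), 1L)
    expect_gt(sdc[1, 1, t] / sum(sdc[1, , t]), 0.5)
  }

  expect_error(encoder_spec(C = 1, N = 50, fs = 100, stft_window = 100,
                            stft_hop = 50),
               "exceeds")
})

test_that("a rectangular window puts all DC energy in bin zero", {
  spec <- encoder_spec(C = 1, N = 800, fs = 100, stft_window = 100,
                       stft_hop = 100, stft_window_fn = "rect",
                       conv_channels = c(2, 2, 2, 2), log_compress = FALSE)
  sdc <- stft_spectrogram(signal_epoch(matrix(2, 1, 800), fs = 100), spec)
  expect_equal(sum(sdc[1, -1, ]), 0, tolerance = 1e-9)
})

test_that("encoding is deterministic with the contracted dimension", {
  spec <- tiny_spec()
  params <- init_encoder(spec, seed = 21)
  x <- random_epoch(C = 2, N = 400, fs = 50, seed = 1)
  h1 <- encode(x, params)
  h2 <- encode(x, params)
  expect_identical(h1, h2)
  expect_length(h1, spec$repr_dim)
  expect_true(all(is.finite(h1)))

  expect_error(encode(random_epoch(C = 3, N = 400, fs = 50), params),
               "expects")
})

test_that("representations separate spectrally distinct classes", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 10)
  params <- init_encoder(tiny_spec(), seed = 4)
  H <- encode_batch(ds, params)
  h0 <- colMeans(H[ds$labels == 0, ])
  h1 <- colMeans(H[ds$labels == 1, ])
  expect_gt(sqrt(sum((h0 - h1)^2)), 1e-6)
})

test_that("encode_batch agrees with per-epoch encode", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 5)
  params <- init_encoder(tiny_spec(), seed = 5)
  H <- encode_batch(ds, params, chunk = 4)
  for (i in c(1, 5, 10)) {
    expect_equal(H[i, ], encode(get_epoch(ds, i), params), tolerance = 1e-12)
  }
})

test_that("projection lands on the unit sphere and is scale-invariant there", {
  spec <- tiny_spec()
  params <- init_encoder(spec, seed = 6)
  set.seed(7)
  H <- matrix(rnorm(10 * spec$repr_dim), 10)
  Z <- project(H, params)
  expect_equal(rowSums(Z^2), rep(1, 10), tolerance = 1e-6)
  z1 <- project(H[1, ], params)
  expect_length(z1, spec$proj_dim)

  # L2 normalization maps proportional vectors to the same point
  u <- c(3, 4, 0)
  expect_equal(u / sqrt(sum(u^2)), c(0.6, 0.8, 0))
  expect_equal(contrawr:::mlp_forward(
    matrix(2 * u, 1), list(W1 = diag(3), b1 = numeric(3),
                           W2 = diag(3), b2 = numeric(3)))$Z[1, ],
    c(0.6, 0.8, 0))
})

test_that("parameter initialization is seed-reproducible", {
  spec <- tiny_spec()
  expect_identical(init_encoder(spec, 1), init_encoder(spec, 1))
  expect_false(identical(init_encoder(spec, 1)$conv_w[[1]],
                         init_encoder(spec, 2)$conv_w[[1]]))
})

test_that("checkpoints round-trip and guard the architecture", {
  spec <- tiny_spec()
  params <- init_encoder(spec, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(params, path)
  back <- load_checkpoint(path, expected_spec = spec)
  expect_equal(unclass(back), unclass(params), ignore_attr = TRUE)

  other <- encoder_spec(C = 3, N = 400, fs = 50, stft_window = 50,
                        stft_hop = 50, conv_channels = c(2, 3, 4, 5))
  expect_error(load_checkpoint(path, expected_spec = other), "match")
  unlink(path)
})

test_that("conv-stack gradients match finite differences", {
  spec <- tiny_spec()
  theta <- init_encoder(spec, 1)
  phi <- init_encoder(spec, 2)
  M <- 3
  set.seed(31)
  sig <- array(rnorm(M * 2 * 400), c(M, 2, 400))
  sp_on <- contrawr:::spect_input(sig, spec)
  sp_tg <- contrawr:::spect_input(array(rnorm(M * 2 * 400), c(M, 2, 400)),
                                  spec)
  cfg <- contrastive_config(batch_size = M, mode = "contrawr")
  positives <- contrawr:::target_projections(sp_tg, phi)
  loss_of <- function(p) {
    fw <- contrawr:::cnn_forward_cpp(sp_on, p$conv_w, p$conv_b, FALSE)
    Z <- contrawr:::mlp_forward(fw$h, p$proj, normalize = TRUE)$Z
    contrawr:::batch_loss_grad(Z, positives, cfg)$loss
  }
  st <- contrawr:::online_step(sp_on, positives, theta, cfg)
  eps <- 1e-5
  for (leaf in list(c("conv_w", 1L), c("conv_w", 3L), c("conv_b", 2L),
                    c("conv_w", 4L), c("conv_b", 4L))) {
    nm <- leaf[1L]; l <- as.integer(leaf[2L])
    g <- st$grads[[nm]][[l]]
    for (j in sample(length(g), min(4, length(g)))) {
      tp <- theta; tp[[nm]][[l]][j] <- tp[[nm]][[l]][j] + eps
      tm <- theta; tm[[nm]][[l]][j] <- tm[[nm]][[l]][j] - eps
      num <- (loss_of(tp) - loss_of(tm)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-3)
    }
  }
  for (nm in c("W1", "b2")) {
    g <- st$grads$proj[[nm]]
    for (j in sample(length(g), 3)) {
      tp <- theta; tp$proj[[nm]][j] <- tp$proj[[nm]][j] + eps
      tm <- theta; tm$proj[[nm]][j] <- tm$proj[[nm]][j] - eps
      num <- (loss_of(tp) - loss_of(tm)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-3)
    }
  }
})

test_that("supervised head gradients match finite differences", {
  spec <- tiny_spec()
  set.seed(41)
  M <- 4
  sp <- contrawr:::spect_input(array(rnorm(M * 2 * 400), c(M, 2, 400)), spec)
  y <- c(0L, 1L, 0L, 1L)
  enc <- init_encoder(spec, 3)
  head <- list(W1 = contrawr:::init_linear(spec$repr_dim, spec$head_hidden),
               b1 = numeric(spec$head_hidden),
               W2 = contrawr:::init_linear(spec$head_hidden, 2L),
               b2 = numeric(2L))
  params <- list(conv_w = enc$conv_w, conv_b = enc$conv_b, head = head)
  loss_of <- function(p) {
    fw <- contrawr:::cnn_forward_cpp(sp, p$conv_w, p$conv_b, FALSE)
    logits <- contrawr:::mlp_forward(fw$h, p$head, normalize = FALSE)$Z
    contrawr:::softmax_ce(logits, y)$loss
  }
  fw <- contrawr:::cnn_forward_cpp(sp, params$conv_w, params$conv_b, TRUE)
  hf <- contrawr:::mlp_forward(fw$h, params$head, normalize = FALSE)
  ce <- contrawr:::softmax_ce(hf$Z, y)
  hb <- contrawr:::mlp_backward(hf$cache, params$head, ce$grad)
  cg <- contrawr:::cnn_backward_cpp(fw$cache, params$conv_w, params$conv_b,
                                    hb$dH)
  eps <- 1e-5
  checks <- list(list(cg$dw[[2]], function(p, j, v) { p$conv_w[[2]][j] <- v; p },
                      function(p, j) p$conv_w[[2]][j]),
                 list(hb$grads$W2, function(p, j, v) { p$head$W2[j] <- v; p },
                      function(p, j) p$head$W2[j]))
  for (ck in checks) {
    g <- ck[[1]]
    for (j in sample(length(g), 4)) {
      v0 <- ck[[3]](params, j)
      num <- (loss_of(ck[[2]](params, j, v0 + eps)) -
                loss_of(ck[[2]](params, j, v0 - eps))) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-3)
    }
  }
})
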