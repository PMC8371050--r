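test_that("preprocessing suppresses mains, nulls silence, decimates by 100", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  # pure 60 Hz mains: notch (Q = 50) must crush it
  mains <- matrix(sin(2 * pi * 60 * t), ncol = 1)
  inband <- matrix(sin(2 * pi * 80 * t), ncol = 1)
  f_mains <- hdmodem:::emg_filter_chain(mains, fs)
  f_inband <- hdmodem:::emg_filter_chain(inband, fs)
  # steady-state attenuation of the 60 Hz envelope >= 20 dB vs in-band tone
  steady <- 50:100
  expect_lt(mean(f_mains[steady, 1]), mean(f_inband[steady, 1]) / 10)

  zero <- matrix(0, nrow = 3000, ncol = 2)
  expect_true(all(hdmodem:::emg_filter_chain(zero, fs) == 0))
  expect_equal(nrow(hdmodem:::emg_filter_chain(zero, fs)), 30)

  expect_error(preprocess_emg(zero, NULL), "quantile")
  out <- preprocess_emg(zero, quantiles = c(1, 1))
  expect_equal(dim(out), c(30, 2))
})

test_that("feature quantizer covers edges and uniform bins", {
  expect_equal(quantize_features(0, 128), 1L)
  expect_equal(quantize_features(1, 128), 128L)
  expect_equal(quantize_features(0.5 - 1e-9, 128), 64L)
  expect_equal(quantize_features(0.5, 128), 65L)
  expect_equal(quantize_features(-0.3, 128), 1L)
  expect_equal(quantize_features(1.7, 128), 128L)
  m <- quantize_features(matrix(c(0, 0.25, 0.5, 1), 2, 2), 4)
  expect_equal(dim(m), c(2, 2))
  expect_equal(as.vector(m), c(1L, 2L, 3L, 4L))
})

test_that("spatial encoding is a rotated level superposition", {
  D <- 1024
  cm <- continuous_item_memory(128, D, seed = 1)
  levels <- rep(77L, 64)
  x <- spatial_encode(levels, cm)
  expect_true(all(x %% 2 == 0)) # 64 bipolar addends: even parity
  expect_true(all(abs(x) <= 64))
  # correlates with every rotated level vector it contains
  for (ch in c(1, 17, 64)) {
    expect_gt(cosine_sim(x, hv_rotate(cm$levels[, 77], ch - 1)), 0.08)
  }
  # batched encoder agrees with the single-frame encoder
  lv <- matrix(sample(1:128, 64 * 5, replace = TRUE), nrow = 64)
  X <- hdmodem:::spatial_encode_stream(lv, cm)
  for (j in 1:5) expect_equal(X[, j], spatial_encode(lv[, j], cm))
})

test_that("nearby levels stay closer after spatial encoding", {
  D <- 8192
  cm <- continuous_item_memory(128, D, seed = 2)
  set.seed(3)
  base <- sample(20:100, 64, replace = TRUE)
  near <- base; near[5] <- near[5] + 1L
  far <- base; far[5] <- 128L - far[5] # large level jump on one channel
  x0 <- spatial_encode(base, cm)
  expect_gt(cosine_sim(x0, spatial_encode(near, cm)),
            cosine_sim(x0, spatial_encode(far, cm)))
})

test_that("temporal n-grams are bipolar, order-sensitive, reproducible", {
  D <- 10000
  model <- ncc_model(D, seed = 4)
  cm <- model$cim
  set.seed(5)
  frames <- lapply(1:5, function(i) {
    spatial_encode(sample(1:128, 64, replace = TRUE), cm)
  })
  g1 <- temporal_encode(frames, model)
  expect_true(all(g1 %in% c(-1, 1)))
  expect_identical(g1, temporal_encode(frames, model))
  g2 <- temporal_encode(rev(frames), model)
  expect_lt(abs(cosine_sim(g1, g2)), 0.05)
  expect_error(temporal_encode(frames[1:3], model), "frames")
})

test_that("prototype training accumulates and bipolarizes per class", {
  D <- 256
  tb <- random_bipolar(D, seed = 6)
  enc <- cbind(random_bipolar(D, seed = 7), random_bipolar(D, seed = 8),
               random_bipolar(D, seed = 9))
  p1 <- train_prototypes(enc, c("a", "b", "c"), tb)
  expect_identical(unname(p1$prototypes), unname(enc))
  # duplicating the sample set leaves prototypes unchanged (sign invariance)
  p2 <- train_prototypes(cbind(enc, enc), rep(c("a", "b", "c"), 2), tb)
  expect_identical(p1$prototypes, p2$prototypes)
  expect_error(train_prototypes(enc, c("a", "b"), tb), "label")
})

test_that("classification picks the nearest prototype with tie rules", {
  D <- 512
  tb <- random_bipolar(D, seed = 10)
  protos <- train_prototypes(cbind(random_bipolar(D, seed = 11),
                                   random_bipolar(D, seed = 12)),
                             c("a", "b"), tb)
  expect_equal(ncc_classify(protos$prototypes[, 1], protos), "a")
  # negated prototype of one of two classes lands on the other
  expect_equal(ncc_classify(-protos$prototypes[, 2], protos), "a")
  # bipolarized query equals plain query for bipolar input
  q <- protos$prototypes[, 2]
  expect_equal(ncc_classify(q, protos, bipolarize_query = TRUE), "b")
})

test_that("full-precision queries beat bipolarized queries at low SNR", {
  cfg <- synthetic_config(seed = 20, trials_per_class = 10,
                          separability = 1, noise_sd = 0.02)
  gen <- generate_features(cfg)
  tr <- gen$trials %% 2 == 1
  model <- ncc_model(2048, seed = 21)
  model <- ncc_train(gen$features[tr, ], gen$labels[tr], model,
                     gen$trials[tr])
  acc <- function(bip) {
    p <- ncc_predict(model, gen$features[!tr, ], gen$trials[!tr],
                     snr_db = -5, bipolarize_query = bip, seed = 22)
    mean(p$predicted == gen$labels[!tr][p$frame])
  }
  expect_gte(acc(FALSE) + 0.01, acc(TRUE))
})

test_that("noise-free reconstruction is exact to quantizer resolution", {
  D <- 8192
  L <- 128
  cm <- continuous_item_memory(L, D, seed = 13)
  set.seed(14)
  f <- matrix(runif(40 * 64), 40, 64)
  lev <- t(quantize_features(f, L))
  X <- hdmodem:::spatial_encode_stream(lev, cm)
  rec <- reconstruct_features(X, cm, decoder_config("unit"), 64)
  expect_lte(max(abs(rec - f)), 1 / L)
  # levels map back to bin centers exactly
  expect_equal(rec, t((lev - 0.5) / L))
  # all channels at level 1 reconstruct to the first bin center once the
  # feedback iterations have cancelled the cross-channel interference
  x1 <- hdmodem:::spatial_encode_stream(matrix(1L, 64, 1), cm)
  r1 <- reconstruct_features(x1, cm, decoder_config("unit"), 64)
  expect_true(all(r1 == 0.5 / L))
})

test_that("soft-feedback reconstruction beats no feedback in noise", {
  D <- 1024
  L <- 128
  cm <- continuous_item_memory(L, D, seed = 15)
  set.seed(16)
  f <- matrix(runif(30 * 64), 30, 64)
  X <- hdmodem:::spatial_encode_stream(t(quantize_features(f, L)), cm)
  Y <- X + matrix(rnorm(length(X), sd = sqrt(64 / 10^(5 / 10))), nrow = D)
  m_none <- mse_db(reconstruct_features(Y, cm, decoder_config("none"), 64), f)
  m_soft <- mse_db(reconstruct_features(Y, cm, decoder_config("soft"), 64), f)
  expect_lt(m_soft, m_none)
})

test_that("EMG throughput and MSE helpers evaluate their closed forms", {
  expect_equal(emg_throughput(512), 4.375)
  expect_equal(round(emg_throughput(2048), 3), 1.094)
  expect_equal(emg_throughput(2240), 1)
  expect_error(emg_throughput(0), "positive")

  a <- matrix(0.5, 4, 4)
  expect_equal(mse_db(a + 0.1, a), -20)
  expect_equal(mse_db(a, a), -Inf)
  expect_error(mse_db(a, matrix(0, 2, 2)), "shape")
  expect_error(mse_db(matrix(0, 0, 0), matrix(0, 0, 0)), "empty")
})

test_that("classification and transmission share one spatial encoder", {
  model <- ncc_model(4096, seed = 30)
  # the same CiM object drives both modes: reconstruction of what the
  # classifier's spatial stage encoded recovers the quantized features
  set.seed(31)
  f <- matrix(runif(6 * 64), 6, 64)
  lev <- t(quantize_features(f, model$n_levels))
  X <- hdmodem:::spatial_encode_stream(lev, model$cim)
  rec <- reconstruct_features(X, model$cim, decoder_config("unit"),
                              model$n_channels)
  expect_gt(mean(t(quantize_features(rec, model$n_levels)) == lev), 0.9)
  # and the model's CiM is literally one object shared by both code paths
  expect_identical(model$cim$levels,
                   continuous_item_memory(model$n_levels, model$dim,
                                          seed = derive_seed(model$seed,
                                                             "cim"))$levels)
})
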