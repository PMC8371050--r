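cfg64 <- code_config(64, 8, 1, seed = 1)

test_that("bit-to-index mapping reproduces the worked example and inverts", {
  idx <- bits_to_indexes("0100100010", cfg64)
  expect_equal(idx$q, 2)
  expect_equal(idx$r, 17)
  expect_equal(idx$s, -1)
  expect_equal(bits_to_indexes(rep(0L, 10), cfg64),
               list(q = 0L, r = 0L, s = -1L))
  expect_identical(bits_to_string(indexes_to_bits(idx, cfg64)), "0100100010")
  expect_identical(bits_to_string(indexes_to_bits(list(q = 0L, r = 0L,
                                                       s = 1L), cfg64)),
                   "0000000001")
  set.seed(42)
  for (i in 1:200) {
    u <- random_bits(10)
    expect_identical(indexes_to_bits(bits_to_indexes(u, cfg64), cfg64), u)
  }
  expect_error(bits_to_indexes("010", cfg64), "bits")
  expect_error(indexes_to_bits(list(q = 8L, r = 0L, s = 1L), cfg64), "range")
  expect_error(code_config(100, 8, 1), "power of two")
})

test_that("encoding matches the sign-rotate-lookup construction", {
  im <- item_memory(8, 64, seed = 1)
  x <- hdm_encode("0100100010", im, NULL, cfg64)
  expect_equal(x, -hv_rotate(im$entries[, 3], 17))

  # superposition parity: V bipolar addends with distinct permutations
  cfg2 <- code_config(64, 8, 2, seed = 2)
  cb2 <- hdm_codebook(cfg2)
  set.seed(7)
  x2 <- hdm_encode(random_bits(cfg2$total_bits), cb2$im, cb2$perms, cfg2)
  expect_true(all(x2 %in% c(-2, 0, 2)))
  expect_error(hdm_encode("01", im, NULL, cfg64), "bits")
})

test_that("throughput closed form matches the printed configurations", {
  expect_equal(hdm_throughput(code_config(512, 512, 7)), 133 / 512)
  expect_equal(round(hdm_throughput(code_config(512, 512, 7)), 4), 0.2598)
  expect_equal(round(hdm_throughput(code_config(512, 2048, 9)), 2), 0.37)
  expect_equal(hdm_throughput(code_config(512, 64, 1)), 16 / 512)
})

test_that("am_search matches the brute-force scan and exact queries", {
  im <- item_memory(8, 64, seed = 3)
  # exact match with and without sign
  y1 <- hv_rotate(im$entries[, 4], 5)
  r1 <- am_search(y1, im)
  expect_equal(r1[c("q", "r", "s")], list(q = 3L, r = 5L, s = 1L))
  expect_equal(r1$confidence, 1)
  r2 <- am_search(-y1, im)
  expect_equal(r2[c("q", "r", "s")], list(q = 3L, r = 5L, s = -1L))

  # fft path == direct path == independent double-loop oracle, noisy queries
  set.seed(11)
  for (i in 1:60) {
    y <- hv_rotate(im$entries[, sample(8, 1)], sample(0:63, 1)) *
      sample(c(-1, 1), 1) + rnorm(64, sd = 0.8)
    a <- am_search(y, im, method = "fft")
    b <- am_search(y, im, method = "direct")
    o <- brute_force_am(y, im$entries)
    expect_identical(a[c("q", "r", "s")], b[c("q", "r", "s")])
    expect_equal(a$q, o$q)
    expect_equal(a$r, o$r)
    expect_equal(a$s, o$s)
    expect_equal(a$confidence, o$confidence, tolerance = 1e-10)
  }
})

test_that("noise-free decoding is an exact roundtrip across configurations", {
  grid <- list(c(512, 64, 1), c(512, 512, 3), c(512, 512, 7),
               c(512, 2048, 9), c(256, 16, 2))
  for (g in grid) {
    cfg <- code_config(g[1], g[2], g[3], seed = sum(g))
    cb <- hdm_codebook(cfg)
    cache <- hdmodem:::am_cache(cb$im)
    set.seed(g[3])
    for (i in 1:20) {
      u <- random_bits(cfg$total_bits)
      x <- hdm_encode(u, cb$im, cb$perms, cfg)
      dec <- hdm_decode(x, cb$im, cb$perms, cfg, decoder_config("unit"),
                        cache = cache)
      expect_identical(dec$bits, u)
    }
  }
})

test_that("single-block decoding terminates after one iteration", {
  cfg <- code_config(256, 64, 1, seed = 5)
  cb <- hdm_codebook(cfg)
  set.seed(3)
  u <- random_bits(cfg$total_bits)
  x <- hdm_encode(u, cb$im, cb$perms, cfg)
  y <- awgn(x, 5, signal_power = 1, seed = 8)
  dec <- hdm_decode(y, cb$im, cb$perms, cfg, decoder_config("unit"))
  expect_equal(dec$iterations, 1)
  expect_true(dec$converged)
})

test_that("soft feedback is at least as accurate as unit feedback at 0 dB", {
  cfg <- code_config(512, 512, 7, seed = 17)
  cb <- hdm_codebook(cfg)
  cache <- hdmodem:::am_cache(cb$im)
  n <- 120
  correct <- c(unit = 0, soft = 0)
  set.seed(29)
  for (i in seq_len(n)) {
    u <- random_bits(cfg$total_bits)
    x <- hdm_encode(u, cb$im, cb$perms, cfg)
    y <- awgn(x, 0, signal_power = 7)
    for (fb in c("unit", "soft")) {
      dec <- hdm_decode(y, cb$im, cb$perms, cfg, decoder_config(fb),
                        cache = cache)
      # block-retrieval accuracy: count correctly recovered blocks
      correct[fb] <- correct[fb] +
        sum(colSums(matrix(dec$bits == u, nrow = cfg$block_bits)) ==
              cfg$block_bits)
    }
  }
  expect_gte(correct[["soft"]], correct[["unit"]])
})

test_that("readout quantization maps to the nearest grid value", {
  expect_equal(quantize_readout(0.4, 5), 1)
  expect_equal(quantize_readout(8.2, 5), 5)
  expect_equal(quantize_readout(-8.2, 5), -5)
  expect_equal(quantize_readout(c(-0.4, 2.3), 3), c(-1, 3))
  # a noise-free superposition is already on the grid
  cfg <- code_config(128, 16, 5, seed = 6)
  cb <- hdm_codebook(cfg)
  set.seed(2)
  x <- hdm_encode(random_bits(cfg$total_bits), cb$im, cb$perms, cfg)
  expect_equal(quantize_readout(x, 5), x)
  # halfway ties resolve toward the smaller magnitude
  expect_equal(quantize_readout(2, 5), 1)
  expect_equal(quantize_readout(-2, 5), -1)
})

test_that("fixed-point quantization rounds and clips as specified", {
  expect_equal(quantize_fixed_point(0.73, 4, 1), 0.5)
  expect_equal(quantize_fixed_point(31.7, 4, 1), 15.5)
  expect_equal(quantize_fixed_point(-31.7, 4, 1), -15.5)
  # ties away from zero
  expect_equal(quantize_fixed_point(0.25, 4, 1), 0.5)
  expect_equal(quantize_fixed_point(-0.25, 4, 1), -0.5)
  # soft-feedback scales at q = 1 live on {0, 0.5, 1}
  scales <- quantize_fixed_point(seq(0, 1, by = 0.05), 4, 1)
  expect_true(all(scales %in% c(0, 0.5, 1)))
})

test_that("quantized decoders still decode cleanly at high SNR", {
  cfg <- code_config(512, 512, 7, seed = 21)
  cb <- hdm_codebook(cfg)
  cache <- hdmodem:::am_cache(cb$im)
  set.seed(5)
  for (i in 1:10) {
    u <- random_bits(cfg$total_bits)
    x <- hdm_encode(u, cb$im, cb$perms, cfg)
    y <- awgn(x, 15, signal_power = 7)
    d_fp <- hdm_decode(y, cb$im, cb$perms, cfg,
                       decoder_config("soft", fixed_point = c(4, 1)),
                       cache = cache)
    d_rq <- hdm_decode(y, cb$im, cb$perms, cfg,
                       decoder_config("soft", readout_levels = 7),
                       cache = cache)
    expect_identical(d_fp$bits, u)
    expect_identical(d_rq$bits, u)
  }
})
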