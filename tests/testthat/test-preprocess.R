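test_that("moving average matches the direct window-mean oracle", {
  expect_equal(moving_average(c(0, 1, 0, 1, 0), 3),
               c(0, 1 / 3, 2 / 3, 1 / 3, 0))
  set.seed(8)
  x <- rnorm(40)
  for (w in c(3, 7, 11)) {
    got <- moving_average(x, w)
    h <- (w - 1) / 2
    want <- vapply(seq_along(x), function(i) {
      k <- min(h, i - 1, length(x) - i)
      mean(x[(i - k):(i + k)])
    }, 1)
    expect_equal(got, want)
  }
  expect_equal(moving_average(rep(2, 10), 5), rep(2, 10))
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 41), "exceeds")
})

test_that("moving average shrinks white noise sd like 1/sqrt(w)", {
  set.seed(9)
  n <- 1e4
  x <- rnorm(n)
  for (w in c(7, 15)) {
    sm <- moving_average(x, w)[seq(50, n - 50)]
    expect_lt(abs(sd(sm) - 1 / sqrt(w)) * sqrt(w), 0.10)
  }
})

test_that("larger MA windows flatten a narrow absorption feature more", {
  wl <- seq(874, 1734, 5)
  spec <- 0.8 - 0.2 * exp(-(wl - 1300)^2 / (2 * 12^2))  # narrow dip
  depth <- vapply(c(7, 11, 15, 19, 23), function(w)
    0.8 - min(moving_average(spec, w)), 1)
  expect_true(all(diff(depth) < 0))
})

test_that("wavelet transform is orthogonal and perfectly reconstructing", {
  for (wav in c("haar", "db4")) {
    n <- 64
    # build the transform matrix column-by-column: the independent oracle
    W <- vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- 1
      w <- dwt_periodized(e, wav, 3)
      c(w$approx, unlist(rev(w$details)))
    }, numeric(n))
    expect_equal(W %*% t(W), diag(n), tolerance = 1e-10)
    set.seed(10)
    x <- rnorm(n)
    w <- dwt_periodized(x, wav, 3)
    expect_equal(c(w$approx, unlist(rev(w$details))),
                 as.numeric(W %*% x), tolerance = 1e-10)
    expect_equal(idwt_periodized(w), x, tolerance = 1e-10)
  }
})

test_that("zero-threshold wavelet denoising is the identity", {
  x <- clean_signal() + rnorm(173, 0, 0.02)  # length not a power of two
  expect_lt(max(abs(wavelet_denoise(x, threshold = 0) - x)), 1e-10)
  expect_lt(max(abs(wavelet_denoise(rep(0.4, 64)) - 0.4)), 1e-10)
  expect_error(wavelet_denoise(rnorm(8), level = 4), "too deep")
})

test_that("wavelet denoising moves noisy spectra toward the clean signal", {
  clean <- clean_signal()
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(length(clean), 0, 0.02)
    mean((wavelet_denoise(noisy) - clean)^2) < mean((noisy - clean)^2)
  }, TRUE)
  expect_gte(sum(wins), 95)
  # SURE rule also denoises
  set.seed(1)
  noisy <- clean + rnorm(length(clean), 0, 0.02)
  expect_lt(mean((wavelet_denoise(noisy, rule = "sure") - clean)^2),
            mean((noisy - clean)^2))
})

test_that("EMD is complete and passes monotone signals through", {
  x <- clean_signal() + rnorm(173, 0, 0.02)
  dec <- emd(x)
  expect_gte(ncol(dec$imfs), 1)
  expect_lt(max(abs(rowSums(cbind(dec$imfs, dec$residual)) - x)), 1e-8)
  mono <- seq(0, 1, length.out = 50)
  expect_equal(ncol(emd(mono)$imfs), 0)
  expect_identical(emd_denoise(mono), mono)
})

test_that("EMD denoising moves noisy spectra toward the clean signal", {
  clean <- clean_signal()
  wins <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    noisy <- clean + rnorm(length(clean), 0, 0.02)
    mean((emd_denoise(noisy) - clean)^2) < mean((noisy - clean)^2)
  }, TRUE)
  expect_gte(sum(wins), 95)
})

test_that("median filtering dims the foreground as the window grows", {
  cfg <- small_cfg(rows = 64, cols = 64, beans_per_scene = 4,
                   wavelengths = seq(1000, 1045, 5))
  ms <- masked_scene(cfg)
  fg_mean <- vapply(c(3, 5, 7, 9, 11, 15), function(w) {
    out <- median_filter_cube(ms$cube, w, ms$lmap)
    mean(out$data[rep(ms$lmap$mask, length(cfg$wavelengths))])
  }, 1)
  expect_true(all(diff(fg_mean) <= 1e-12))
})

test_that("MF output stays within each pixel's spatial window range", {
  cfg <- small_cfg(rows = 40, cols = 40, beans_per_scene = 2,
                   wavelengths = c(1000, 1005))
  ms <- masked_scene(cfg)
  out <- median_filter_cube(ms$cube, 3)
  fg <- which(ms$lmap$mask, arr.ind = TRUE)
  for (r in seq_len(min(20, nrow(fg)))) {
    i <- fg[r, 1]; j <- fg[r, 2]
    if (i < 2 || j < 2 || i > 39 || j > 39) next
    for (b in 1:2) {
      win <- ms$cube$data[(i - 1):(i + 1), (j - 1):(j + 1), b]
      expect_gte(out$data[i, j, b], min(win))
      expect_lte(out$data[i, j, b], max(win))
    }
  }
})

test_that("preprocess_cube dispatches and preserves the background", {
  cfg <- small_cfg(rows = 48, cols = 48, beans_per_scene = 2,
                   wavelengths = seq(1000, 1155, 5))
  ms <- masked_scene(cfg)
  expect_identical(preprocess_cube(ms$cube, ms$lmap,
                                   preprocess_config("none")), ms$cube)
  for (m in c("MA", "WT", "EMD", "MF")) {
    pre <- preprocess_config(m, wt_level = 3)
    out <- preprocess_cube(ms$cube, ms$lmap, pre)
    bg <- !ms$lmap$mask
    expect_true(all(out$data[rep(bg, dim(out)[3])] == 0), info = m)
  }
  expect_error(preprocess_config("bogus"))
})

test_that("MA commutes with bean averaging (linearity)", {
  cfg <- small_cfg(noise_sd = 0)
  ms <- masked_scene(cfg)
  px <- extract_pixel_spectra(ms$cube, ms$lmap, 1)
  pre <- preprocess_config("MA", ma_points = 7)
  a <- average_by_bean(preprocess_spectra(px, pre))
  b <- preprocess_spectra(average_by_bean(px), pre)
  expect_lt(max(abs(a$X - b$X)), 1e-10)
})

test_that("all four methods leave constant spectra untouched", {
  const <- rep(0.5, 64)
  expect_equal(moving_average(const, 11), const)
  expect_lt(max(abs(wavelet_denoise(const) - const)), 1e-10)
  expect_identical(emd_denoise(const), const)
  expect_equal(median_filter_band(matrix(0.5, 10, 10), 5),
               matrix(0.5, 10, 10))
})
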