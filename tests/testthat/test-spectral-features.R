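make_stream <- function(duration_s, fs = 50, seed = 1) {
  simulate_activity(default_activity_specs()$WA, duration_s, fs, seed)
}

test_that("segmentation produces 50%-overlapping windows, partials dropped", {
  wins <- segment_stream(make_stream(10), window_seconds = 3,
                         overlap_fraction = 0.5)
  expect_length(wins, 5)
  expect_equal(vapply(wins, function(w) w$start_time, numeric(1)),
               c(0, 1.5, 3, 4.5, 6))
  expect_true(all(vapply(wins, function(w) nrow(w$channels), numeric(1)) == 150))
  expect_true(all(vapply(wins, function(w) w$label, character(1)) == "WA"))

  expect_length(segment_stream(make_stream(3)), 1)
  expect_warning(empty <- segment_stream(make_stream(2.9)), "shorter")
  expect_length(empty, 0)
  expect_error(segment_stream(make_stream(10), overlap_fraction = 1), "\\[0, 1\\)")
})

test_that("spectrogram equals a direct evaluation of the windowed-sum", {
  set.seed(5)
  cases <- list(
    list(x = sin(2 * pi * 5 * (0:199) / 50), seg = 64, hop = 32, nfft = 128),
    list(x = rnorm(256), seg = 128, hop = 64, nfft = 256),
    list(x = rnorm(100), seg = 100, hop = 50, nfft = 256)
  )
  for (cs in cases) {
    got <- spectrogram(cs$x, fs = 50, fft_length = cs$nfft,
                       segment_length = cs$seg, hop = cs$hop)
    want <- stft_bruteforce(cs$x, cs$nfft, cs$seg, cs$hop)
    expect_equal(dim(got), dim(want))
    scale <- max(want)
    expect_lt(max(abs(got - want)) / scale, 1e-8)
  }
})

test_that("spectrogram localises a pure sinusoid to within one bin", {
  fs <- 50; f0 <- 5
  x <- sin(2 * pi * f0 * (0:299) / fs)
  sp <- spectrogram(x, fs)               # defaults: 512-point FFT, 128 seg
  expected_bin <- f0 * attr(sp, "fft_length") / fs  # zero-based
  for (m in seq_len(ncol(sp))) {
    expect_lte(abs((which.max(sp[, m]) - 1) - expected_bin), 1)
  }
})

test_that("spectrogram of silence is zero and entries are never negative", {
  z <- spectrogram(numeric(150), fs = 50)
  expect_equal(dim(z), c(257, 1))
  expect_true(all(z == 0))
  s <- spectrogram(rnorm(150), fs = 50)
  expect_true(all(s >= 0))
  expect_error(spectrogram(rnorm(10), 50, fft_length = 64, segment_length = 128),
               "exceed")
  expect_error(spectrogram(rnorm(10), 50, segment_length = 64), "shorter")
})

test_that("least/largest selection matches an exhaustive sort", {
  sel <- harspect:::sl_select(10:1, S = 2, L = 3)
  expect_equal(sel$small, c(1, 2))
  expect_equal(sel$large, c(8, 9, 10))
  set.seed(8)
  for (rep in 1:20) {
    pool <- runif(sample(20:200, 1))
    S <- sample(1:5, 1); L <- sample(1:5, 1)
    sel <- harspect:::sl_select(pool, S, L)
    full <- sort(pool)
    expect_identical(sel$small, full[1:S])
    expect_identical(sel$large, full[(length(full) - L + 1):length(full)])
  }
  expect_error(harspect:::sl_select(1:4, 3, 3), "exceeds")
})

test_that("feature vectors have length 2(S+L) with ordered blocks", {
  w <- segment_stream(make_stream(3))[[1]]
  v100 <- extract_features(w, S = 25, L = 25)
  expect_length(v100, 100)
  v200 <- extract_features(w, S = 50, L = 50)
  expect_length(v200, 200)
  expect_true(all(v100 >= 0))
  # block structure: SA ascending, below LeA; likewise for gyroscope
  expect_lte(max(v100[1:25]), min(v100[26:50]))
  expect_lte(max(v100[51:75]), min(v100[76:100]))

  zero <- analysis_window(matrix(0, 150, 6), fs = 50, label = "SI")
  expect_true(all(extract_features(zero) == 0))
})

test_that("selection agrees with a full sort of the pooled spectrograms", {
  w <- segment_stream(make_stream(3))[[1]]
  v <- extract_features(w, S = 10, L = 10)
  pool_acc <- sort(unlist(lapply(1:3, function(j) {
    as.numeric(spectrogram(w$channels[, j], w$fs))
  })))
  pool_gyr <- sort(unlist(lapply(4:6, function(j) {
    as.numeric(spectrogram(w$channels[, j], w$fs))
  })))
  expect_equal(unname(v[1:10]), pool_acc[1:10])
  expect_equal(unname(v[11:20]), tail(pool_acc, 10))
  expect_equal(unname(v[21:30]), pool_gyr[1:10])
  expect_equal(unname(v[31:40]), tail(pool_gyr, 10))
})

test_that("pooling is invariant to axis order within a sensor", {
  w <- segment_stream(make_stream(3))[[1]]
  v1 <- extract_features(w)
  w_perm <- analysis_window(w$channels[, c(3, 1, 2, 5, 6, 4)], w$fs, w$label)
  v2 <- extract_features(w_perm)
  expect_equal(unname(v1), unname(v2))
})

test_that("scaling a window by c scales every feature by c^2", {
  w <- segment_stream(make_stream(3))[[1]]
  v <- extract_features(w)
  w2 <- analysis_window(w$channels * 1.7, w$fs, w$label)
  v2 <- extract_features(w2)
  expect_equal(unname(v2), unname(v) * 1.7^2, tolerance = 1e-12)
})

test_that("build_feature_set preserves order, labels and counts", {
  streams <- list(make_stream(10, seed = 1),
                  simulate_activity(default_activity_specs()$SI, 10, 50, 2))
  fs <- build_feature_set(streams)
  expect_equal(dim(fs), c(10, 100))
  expect_equal(as.character(fs$labels), rep(c("WA", "SI"), each = 5))
  expect_identical(fs$provenance, "OR")
  expect_error(build_feature_set(list()), "non-empty")
})
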