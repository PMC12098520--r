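# Preprocessing pipeline: resampling, epoch segmentation, STFT, resize,
# tensor assembly, leakage-free normalization.

make_recording <- function(signal, fs, hyp) {
  structure(list(subject_id = 0L, fs = fs, signal = signal,
                 channel_names = CHANNELS[seq_len(nrow(signal))],
                 hypnogram = hyp),
            class = "raw_recording")
}

test_that("resampling preserves tones and obeys the length contract", {
  x <- matrix(sin(2 * pi * 10 * (0:(200 * 60 - 1)) / 200), nrow = 1)
  y <- resample_signal(x, 200, 128)
  expect_equal(ncol(y), 60 * 128)
  ps <- psd_oracle(y[1, ], 128)
  expect_lt(abs(ps$freq[which.max(ps$spec)] - 10), 0.5)
  # identity when rates match
  expect_identical(resample_signal(x, 128, 128), x)
  expect_error(resample_signal(x, 100, 128), "upsample")
  x[1, 5] <- NaN
  expect_error(resample_signal(x, 200, 128), "non-finite")
})

test_that("segmentation yields whole 30-s epochs and drops the remainder", {
  sig <- matrix(rnorm(10 * 300 * 128), nrow = 10)
  rec <- make_recording(sig, 128, rep("N2", 10))
  eps <- segment_epochs(rec)
  expect_length(eps, 10)
  expect_equal(dim(eps[[1]]$x), c(10L, 3840L))
  # 95 s -> 3 epochs, 5 s discarded
  rec95 <- make_recording(sig[, 1:(95 * 128)], 128, rep("W", 3))
  eps95 <- segment_epochs(rec95)
  expect_length(eps95, 3)
  # conservation: concatenated epochs reproduce the leading samples
  expect_equal(do.call(cbind, lapply(eps95, `[[`, "x")),
               sig[, 1:(3 * 3840)], ignore_attr = TRUE)
  # hypnogram mismatch is a data error
  expect_error(segment_epochs(make_recording(sig, 128, rep("W", 4))),
               "hypnogram")
})

test_that("STFT magnitude matches its definition", {
  expect_equal(stft_magnitude(numeric(3840)), matrix(0, 65, 59))
  x <- sin(2 * pi * 10 * (0:3839) / 128)
  S <- stft_magnitude(x)
  expect_equal(dim(S), c(65L, 59L))
  expect_true(all(S >= 0))
  # 10 Hz tone peaks in bin 10 (row 11) in every frame
  expect_true(all(apply(S, 2, which.max) == 11))
  # first frame against the DFT definition, evaluated literally
  win <- signal::hamming(128)
  frame <- x[1:128] * win
  k <- 0:64
  ref <- vapply(k, function(kk)
    Mod(sum(frame * exp(-2i * pi * kk * (0:127) / 128))), numeric(1))
  expect_equal(S[, 1], ref, tolerance = 1e-10)
  expect_error(stft_magnitude(numeric(100)), "3840")
})

test_that("bilinear resize interpolates and bounds the range", {
  m <- matrix(3.5, 65, 59)
  out <- resize_spectrogram(m)
  expect_equal(out, matrix(3.5, 128, 128))
  m2 <- matrix(0, 65, 59); m2[33, 30] <- 1
  out2 <- resize_spectrogram(m2)
  expect_equal(dim(out2), c(128L, 128L))
  expect_true(max(out2) <= 1 && min(out2) >= 0)
  hot <- which(out2 == max(out2), arr.ind = TRUE)[1, ]
  # mapped coordinate of the source hot pixel under aligned endpoints
  expect_lt(abs(hot[1] - (1 + 32 * 127 / 64)), 2.5)
  expect_lt(abs(hot[2] - (1 + 29 * 127 / 58)), 2.5)
  # bilinear interpolation of a plane reproduces the plane at the mapped
  # coordinates exactly (direct formula oracle)
  m3 <- outer(seq_len(65), seq_len(59), function(i, j) 2 * i + 5 * j)
  out3 <- resize_spectrogram(m3)
  ii <- 1 + (seq_len(128) - 1) * 64 / 127
  jj <- 1 + (seq_len(128) - 1) * 58 / 127
  expect_equal(out3, outer(ii, jj, function(i, j) 2 * i + 5 * j),
               tolerance = 1e-12)
  expect_error(resize_spectrogram(matrix(0, 64, 59)), "65 x 59")
})

test_that("epoch tensors have the contracted shape and channel mapping", {
  expect_equal(build_epoch_tensor(matrix(0, 10, 3840)),
               array(0, dim = c(128, 128, 10)))
  set.seed(4)
  ep <- matrix(rnorm(10 * 3840), 10)
  tn <- build_epoch_tensor(ep)
  expect_equal(dim(tn), c(128L, 128L, 10L))
  expect_true(all(is.finite(tn)) && all(tn >= 0))
  ep3 <- ep; ep3[3, ] <- 0
  tn3 <- build_epoch_tensor(ep3)
  expect_equal(tn3[, , 3], matrix(0, 128, 128))
  expect_equal(tn3[, , -3], tn[, , -3])
  ep_bad <- ep; ep_bad[7, 100] <- NaN
  expect_error(build_epoch_tensor(ep_bad), "channel 7")
})

test_that("tensor values never decrease when the raw epoch is amplified", {
  set.seed(8)
  ep <- matrix(rnorm(10 * 3840), 10)
  t1 <- build_epoch_tensor(ep)
  t2 <- build_epoch_tensor(2.5 * ep)
  expect_true(all(t2 >= t1 - 1e-12))
})

test_that("normalization uses training statistics only", {
  set.seed(5)
  mk <- function(mu) array(rnorm(16 * 16 * 2, mean = mu),
                           dim = c(16, 16, 2))
  train <- lapply(1:4, function(i) mk(i))
  testA <- list(mk(10)); testB <- list(mk(-3))
  ndA <- normalize_dataset(train, testA)
  # training set is standardized per channel
  pooled <- sapply(1:2, function(ch)
    unlist(lapply(ndA$train, function(t) t[, , ch])))
  expect_equal(colMeans(pooled), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(pooled, 2, sd), c(1, 1), tolerance = 1e-2)
  # transform is independent of what the test set contains
  ndB <- normalize_dataset(train, testB)
  expect_identical(ndA$stats, ndB$stats)
  expect_equal(ndA$train, ndB$train)
  # constant channel maps to zero via the sd floor
  const <- list(array(7, dim = c(4, 4, 1)))
  ndc <- normalize_dataset(const)
  expect_equal(ndc$train[[1]], array(0, dim = c(4, 4, 1)))
  expect_error(normalize_dataset(list()), "empty")
})

test_that("the full preprocessing pipeline is deterministic", {
  sm <- small_prepared_cohort()
  rec <- sm$cohort[[1]]
  e1 <- preprocess_recording(rec)
  expect_identical(e1[[1]]$tensor, sm$epochs[[1]]$tensor)
  expect_equal(length(e1), length(rec$hypnogram))
  expect_equal(vapply(e1, `[[`, integer(1), "stage_label"),
               adgsleep:::stage_to_label(rec$hypnogram))
})
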