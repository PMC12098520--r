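# Raw multichannel recordings -> (128 x 128 x 10) time-frequency tensors.
#
# Fixed conventions: 128 Hz working rate; 30-s epochs (3840 samples);
# STFT with a 128-sample Hamming window, hop 64, no boundary padding,
# one-sided magnitude (65 bins x 59 frames); bilinear resize to 128 x 128;
# log(1 + x) compression; per-channel z-scoring with TRAINING statistics.

TARGET_FS <- 128L
EPOCH_SEC <- 30L
STFT_NFFT <- 128L
STFT_HOP <- 64L
SPEC_SIZE <- 128L

#' Resample a multichannel signal
#'
#' Anti-aliased polyphase resampling (via [signal::resample()]) of each
#' channel to the working rate. Only downsampling (or the identity) is
#' supported: the model's working rate of 128 Hz is below every supported
#' acquisition rate, and upsampling would fabricate spectral content.
#'
#' @param x Channels x samples matrix (or a single numeric vector).
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output sampling rate (Hz), default 128.
#' @return Matrix with `round(n * fs_out / fs_in)` samples per channel.
#' @export
resample_signal <- function(x, fs_in, fs_out = TARGET_FS) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite values in input signal")
  if (fs_out <= 0 || fs_in <= 0) stop("sampling rates must be positive")
  if (fs_in < fs_out)
    stop("refusing to upsample: fs_in = ", fs_in, " < fs_out = ", fs_out)
  if (fs_in == fs_out) return(x)
  if (fs_in %% 1 != 0 || fs_out %% 1 != 0)
    stop("sampling rates must be integer Hz")
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  d <- gcd(as.integer(fs_out), as.integer(fs_in))
  p <- as.integer(fs_out / d); q <- as.integer(fs_in / d)
  n_out <- round(ncol(x) * fs_out / fs_in)
  out <- t(apply(x, 1, function(ch) {
    y <- signal::resample(ch, p, q)
    length(y) <- n_out            # pin the documented length contract
    y[is.na(y)] <- 0
    y
  }))
  rownames(out) <- rownames(x)
  out
}

#' Split a recording into labelled 30-s epochs
#'
#' @param rec A `raw_recording` at 128 Hz.
#' @return List of epochs, each a list with `x` (10 x 3840 matrix), `stage`,
#'   `stage_label` (0--4) and `subject_id`. A trailing partial epoch is
#'   dropped; the hypnogram must cover exactly the complete epochs.
#' @export
segment_epochs <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs != TARGET_FS)
    stop("recording must be at ", TARGET_FS, " Hz (resample first)")
  n_per <- as.integer(TARGET_FS * EPOCH_SEC)
  n_ep <- floor(ncol(rec$signal) / n_per)
  if (length(rec$hypnogram) != n_ep)
    stop("hypnogram length (", length(rec$hypnogram),
         ") does not match complete epoch count (", n_ep, ")")
  lapply(seq_len(n_ep), function(i) {
    list(x = rec$signal[, ((i - 1) * n_per + 1):(i * n_per), drop = FALSE],
         stage = rec$hypnogram[i],
         stage_label = stage_to_label(rec$hypnogram[i]),
         subject_id = rec$subject_id)
  })
}

#' One-sided STFT magnitude of a 30-s channel
#'
#' 128-sample Hamming window, 50% overlap (hop 64), no FFT zero-padding and
#' no boundary padding, so a 3840-sample input yields exactly
#' `1 + (3840 - 128)/64 = 59` frames of `128/2 + 1 = 65` one-sided bins.
#'
#' @param x Numeric vector of length 3840.
#' @return 65 x 59 non-negative magnitude matrix; row `k` is frequency bin
#'   `k - 1` (i.e. `(k - 1) * 128/128` Hz at the 128 Hz working rate).
#' @export
stft_magnitude <- function(x) {
  n_expect <- TARGET_FS * EPOCH_SEC
  if (length(x) != n_expect)
    stop("expected ", n_expect, " samples, got ", length(x))
  win <- signal::hamming(STFT_NFFT)
  starts <- seq(1L, length(x) - STFT_NFFT + 1L, by = STFT_HOP)
  frames <- vapply(starts,
                   function(s) x[s:(s + STFT_NFFT - 1L)] * win,
                   numeric(STFT_NFFT))
  S <- mvfft(frames)
  Mod(S[1:(STFT_NFFT / 2 + 1), , drop = FALSE])
}

# linear interpolation weight matrix mapping n_in samples onto n_out,
# endpoints aligned ("align corners"); rows sum to 1
.interp_matrix <- function(n_in, n_out) {
  pos <- seq(0, n_in - 1, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 2)
  w <- pos - lo
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), lo + 1)] <- 1 - w
  A[cbind(seq_len(n_out), lo + 2)] <- w
  A
}

#' Bilinear resize of a spectrogram to 128 x 128
#'
#' Separable bilinear interpolation with aligned endpoints, expressed as two
#' interpolation-matrix products, so output values are convex combinations of
#' input values (output range never exceeds the input range).
#'
#' @param m 65 x 59 magnitude matrix.
#' @param size Output side length (default 128).
#' @return `size` x `size` matrix.
#' @export
resize_spectrogram <- function(m, size = SPEC_SIZE) {
  if (!is.matrix(m) || nrow(m) != STFT_NFFT / 2 + 1 ||
      ncol(m) != 1 + (TARGET_FS * EPOCH_SEC - STFT_NFFT) / STFT_HOP)
    stop("expected a 65 x 59 spectrogram, got ",
         paste(dim(m), collapse = " x "))
  A <- .interp_matrix(nrow(m), size)
  B <- .interp_matrix(ncol(m), size)
  A %*% m %*% t(B)
}

#' Build the model input tensor for one epoch
#'
#' Per channel: STFT magnitude, bilinear resize to 128 x 128, then
#' `log(1 + x)` compression of the wide spectrogram dynamic range.
#'
#' @param epoch 10 x 3840 epoch matrix.
#' @return 128 x 128 x 10 array.
#' @export
build_epoch_tensor <- function(epoch) {
  stopifnot(is.matrix(epoch), nrow(epoch) == 10,
            ncol(epoch) == TARGET_FS * EPOCH_SEC)
  out <- array(0, dim = c(SPEC_SIZE, SPEC_SIZE, 10))
  for (ch in 1:10) {
    if (anyNA(epoch[ch, ]) || !all(is.finite(epoch[ch, ])))
      stop("non-finite samples in channel ", ch)
    out[, , ch] <- log1p(resize_spectrogram(stft_magnitude(epoch[ch, ])))
  }
  out
}

#' Preprocess a recording end to end
#'
#' @param rec A `raw_recording` at any rate >= 128 Hz.
#' @return List of `spectrogram_epoch` objects: `tensor` (128 x 128 x 10),
#'   `stage`, `stage_label`, `subject_id`, `domain_label` (NA until a fold
#'   assigns one).
#' @export
preprocess_recording <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs != TARGET_FS) {
    rec$signal <- resample_signal(rec$signal, rec$fs, TARGET_FS)
    rec$fs <- TARGET_FS
  }
  lapply(segment_epochs(rec), function(ep) {
    structure(list(tensor = build_epoch_tensor(ep$x), stage = ep$stage,
                   stage_label = ep$stage_label, subject_id = ep$subject_id,
                   domain_label = NA_integer_),
              class = "spectrogram_epoch")
  })
}

#' Normalize tensors with training-set statistics
#'
#' Per-channel mean and standard deviation are computed on the TRAINING
#' tensors only and applied to both sets, so no information leaks from the
#' held-out subject. Standard deviations are floored at 1e-8; a constant
#' channel therefore maps to zero.
#'
#' @param train List of `spectrogram_epoch` (or bare arrays); must be
#'   non-empty.
#' @param other Optional second list transformed with the training statistics.
#' @return List with `train`, `other` (normalized copies) and `stats`
#'   (per-channel `mean` and `sd`).
#' @export
normalize_dataset <- function(train, other = list()) {
  if (length(train) == 0) stop("empty training set")
  get_tensor <- function(e) if (is.list(e)) e$tensor else e
  n_ch <- dim(get_tensor(train[[1]]))[3]
  sums <- numeric(n_ch); sqs <- numeric(n_ch); cnt <- 0
  for (e in train) {
    tn <- get_tensor(e)
    m <- matrix(tn, ncol = n_ch)
    sums <- sums + colSums(m)
    sqs <- sqs + colSums(m^2)
    cnt <- cnt + nrow(m)
  }
  mu <- sums / cnt
  sdv <- sqrt(pmax(sqs / cnt - mu^2, 0))
  sdv <- pmax(sdv, 1e-8)
  apply_stats <- function(e) {
    tn <- get_tensor(e)
    for (ch in seq_len(n_ch)) tn[, , ch] <- (tn[, , ch] - mu[ch]) / sdv[ch]
    if (is.list(e)) { e$tensor <- tn; e } else tn
  }
  list(train = lapply(train, apply_stats),
       other = lapply(other, apply_stats),
       stats = list(mean = mu, sd = sdv))
}
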