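# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# tiny but structurally complete model configuration (all four stages, SE,
# Bi-GRU, both heads) for gradient and contract tests
tiny_model_config <- function(...) {
  args <- modifyList(
    list(input_size = 32L, widths = c(4L, 6L, 8L, 8L), gru_hidden = 5L,
         head_hidden = c(7L, 6L), n_domains = 3L, seed = 9L),
    list(...))
  do.call(model_config, args)
}

# 3-subject, 10-epochs-each synthetic cohort, preprocessed; reused by
# training and orchestration tests
small_prepared_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cc <- cohort_config(n_subjects = 3, epochs_per_subject = 10, seed = 7)
    cohort <- generate_cohort(cc)
    eps <- unlist(lapply(cohort, preprocess_recording), recursive = FALSE)
    .fixtures$small <- list(config = cc, cohort = cohort, epochs = eps)
  }
  .fixtures$small
}

# literal, loop-based convolution oracle (stride s, zero padding p)
conv2d_oracle <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); dw <- dim(W)
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), ] <- x
  Ho <- (d[1] + 2 * pad - dw[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - dw[2]) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, dw[4]))
  for (co in seq_len(dw[4]))
    for (i in seq_len(Ho))
      for (j in seq_len(Wo)) {
        acc <- b[co]
        for (ki in seq_len(dw[1]))
          for (kj in seq_len(dw[2]))
            for (ci in seq_len(d[3]))
              acc <- acc + W[ki, kj, ci, co] *
                xp[(i - 1) * stride + ki, (j - 1) * stride + kj, ci]
        out[i, j, co] <- acc
      }
  out
}

# literal squeeze-excitation oracle
se_oracle <- function(o, p) {
  d <- dim(o)
  z <- vapply(seq_len(d[3]), function(c) mean(o[, , c]), numeric(1))
  a <- pmax(as.vector(p$W1 %*% z) + p$b1, 0)
  s <- 1 / (1 + exp(-(as.vector(p$W2 %*% a) + p$b2)))
  out <- o
  for (c in seq_len(d[3])) out[, , c] <- s[c] * o[, , c]
  list(out = out, z = z, s = s)
}

# Welch-style power spectral density via smoothed periodogram
psd_oracle <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 9,
                          plot = FALSE, taper = 0, detrend = FALSE)
  list(freq = sp$freq, spec = sp$spec)
}

# fraction of spectral power below f_hi
bandpower_fraction <- function(x, fs, f_hi) {
  ps <- psd_oracle(x, fs)
  sum(ps$spec[ps$freq < f_hi]) / sum(ps$spec)
}

# log bandpower features for the nearest-centroid separability oracle
bandpower_features <- function(epoch_mat, fs = 128) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                sigma = c(12, 16), high = c(20, 45))
  ch_sel <- list(eeg = 1, eog = 7, emg = 9)
  unlist(lapply(ch_sel, function(ch) {
    ps <- psd_oracle(epoch_mat[ch, ], fs)
    vapply(bands, function(b)
      log(sum(ps$spec[ps$freq >= b[1] & ps$freq < b[2]]) + 1e-12),
      numeric(1))
  }))
}
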