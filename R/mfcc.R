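hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_filters Number of triangular filters (default 12).
#' @param n_fft FFT length.
#' @param rate Sampling rate in Hz.
#' @param fmin,fmax Band edges in Hz (default 0 to Nyquist).
#' @return \code{n_filters x (n_fft/2 + 1)} weight matrix.
#' @export
mel_filterbank <- function(n_filters = 12, n_fft, rate, fmin = 0,
                           fmax = rate / 2) {
  n_bins <- n_fft %/% 2L + 1L
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_hz <- (seq_len(n_bins) - 1L) * rate / n_fft
  fb <- matrix(0, n_filters, n_bins)
  for (k in seq_len(n_filters)) {
    lo <- hz_pts[k]; mid <- hz_pts[k + 1L]; hi <- hz_pts[k + 2L]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  fb
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

# Orthonormal DCT-II matrix (n x n); rows are basis vectors.
dct_matrix <- function(n) {
  j <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(pi * outer(j, j + 0.5) / n)
  m[1L, ] <- m[1L, ] / sqrt(2)
  m
}

#' Mel-frequency cepstral coefficients
#'
#' Per frame: Hamming window, power spectrum, 12 triangular mel filters
#' spanning 0 Hz to Nyquist, log of the filterbank energies (floored at
#' \code{log_floor}), orthonormal DCT-II keeping all 12 coefficients
#' (including c0). No pre-emphasis. These choices mimic the nonlinear
#' frequency warping of human hearing; the AFVC feature is computed from the
#' column means of this matrix and of its second-order delta.
#'
#' @param signal An \code{audio_signal}.
#' @param params A \code{frame_params}; default 25 ms frames with 10 ms hop.
#' @param n_mels Number of mel filters (default 12).
#' @param log_floor Floor applied to filterbank energies before the log
#'   (default 1e-10).
#' @return \code{N x n_mels} coefficient matrix (frames in rows).
#' @export
mfcc <- function(signal, params = NULL, n_mels = 12, log_floor = 1e-10) {
  rate <- audio_rate(signal)
  if (is.null(params)) params <- frame_params_ms(rate)
  min_len <- params$frame_len + 4L * params$hop
  if (length(signal) < min_len)
    stop(sprintf("mfcc: signal too short; need >= 5 frames (%d samples)", min_len))
  fr <- frame_signal(signal, params)
  fr <- fr * hamming_window(params$frame_len)
  n_fft <- 2L^ceiling(log2(params$frame_len))
  padded <- rbind(fr, matrix(0, n_fft - params$frame_len, ncol(fr)))
  spec <- stats::mvfft(padded)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  pow <- Mod(spec)^2
  fb <- mel_filterbank(n_mels, n_fft, rate)
  energies <- fb %*% pow                      # n_mels x N
  logE <- log(pmax(energies, log_floor))
  coef <- t(dct_matrix(n_mels) %*% logE)      # N x n_mels
  dimnames(coef) <- NULL
  coef
}

#' Second-order delta of MFCC frames
#'
#' Dynamic supplement to the static MFCC matrix: per coefficient column the
#' five-frame kernel \code{(-2, -1, 0, 1, 2) / 3} is applied across frames
#' (the denominator 3 is used as such, not the conventional sum-of-squares
#' normalisation). The first and last two frames are edge-replicated before
#' the kernel is applied, so the output has the shape of the input.
#'
#' @param m \code{N x K} MFCC matrix with \code{N >= 5}.
#' @return \code{N x K} delta matrix.
#' @export
delta2_mfcc <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 5L) stop("delta2_mfcc: need at least 5 frames")
  pad <- rbind(m[1L, , drop = FALSE], m[1L, , drop = FALSE], m,
               m[n, , drop = FALSE], m[n, , drop = FALSE])
  i <- seq_len(n) + 2L
  (-2 * pad[i - 2L, , drop = FALSE] - pad[i - 1L, , drop = FALSE] +
      pad[i + 1L, , drop = FALSE] + 2 * pad[i + 2L, , drop = FALSE]) / 3
}

#' Auditory frequency variation coefficient (AFVC)
#'
#' Coefficient of variation of the 24-element parameter sequence formed by
#' the 12 column means of the MFCC matrix followed by the 12 column means of
#' its second-order delta. The numerator is the population SD (divisor 24)
#' of the 24 values and the denominator is the absolute mean of all 24.
#' Low AFVC corresponds to flat perceived pitch variation.
#'
#' @param m \code{N x 12} MFCC matrix.
#' @param dm \code{N x 12} second-order delta matrix, same shape as \code{m}.
#' @param eps Degenerate-input guard: if \code{|mean|} of the parameter
#'   sequence falls below \code{eps} the ratio is undefined and an error is
#'   raised (default 1e-9).
#' @return Non-negative scalar.
#' @export
afvc <- function(m, dm, eps = 1e-9) {
  m <- as.matrix(m); dm <- as.matrix(dm)
  if (!identical(dim(m), dim(dm)))
    stop("afvc: 'm' and 'dm' must have identical dimensions")
  if (nrow(m) < 1L) stop("afvc: empty matrix")
  ps <- c(colMeans(m), colMeans(dm))
  mean_ps <- mean(ps)
  if (abs(mean_ps) < eps)
    stop("afvc: |mean| of the parameter sequence below eps; coefficient of variation undefined")
  sqrt(sum((ps - mean_ps)^2) / length(ps)) / abs(mean_ps)
}
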