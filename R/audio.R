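#' Construct an audio signal
#'
#' A minimal container for mono audio: a numeric sample vector with a
#' sampling rate. Amplitudes are dimensionless and normally within
#' \code{[-1, 1]}.
#'
#' @param samples Numeric vector of samples (finite, non-empty).
#' @param rate Sampling rate in samples/second (positive).
#' @return An object of class \code{audio_signal}: the sample vector with a
#'   \code{rate} attribute.
#' @examples
#' s <- audio_signal(sin(2 * pi * 220 * seq(0, 1, by = 1 / 8000)), 8000)
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio_signal: 'samples' must be non-empty")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("audio_signal: 'samples' must be finite with no NA")
  rate <- as.numeric(rate)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("audio_signal: 'rate' must be a single positive number")
  structure(samples, rate = rate, class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.2f s)>\n",
              length(x), attr(x, "rate"), length(x) / attr(x, "rate")))
  invisible(x)
}

#' Sampling rate of an audio signal
#' @param signal An \code{audio_signal}.
#' @return Sampling rate in Hz.
#' @export
audio_rate <- function(signal) attr(signal, "rate")

#' Frame parameters
#'
#' Frame length and hop in samples. \code{frame_params_ms()} converts the
#' conventional 25 ms frame / 10 ms hop speech framing to samples for a given
#' rate.
#'
#' @param frame_len Samples per frame.
#' @param hop Samples between consecutive frame starts; \code{0 < hop <=
#'   frame_len}.
#' @return A \code{frame_params} list with elements \code{frame_len},
#'   \code{hop}.
#' @export
frame_params <- function(frame_len, hop) {
  frame_len <- as.integer(frame_len)
  hop <- as.integer(hop)
  if (frame_len < 1L) stop("frame_params: frame_len must be >= 1")
  if (hop < 1L || hop > frame_len)
    stop("frame_params: need 0 < hop <= frame_len")
  structure(list(frame_len = frame_len, hop = hop), class = "frame_params")
}

#' @rdname frame_params
#' @param rate Sampling rate in Hz.
#' @param frame_ms Frame length in milliseconds (default 25).
#' @param hop_ms Hop in milliseconds (default 10).
#' @export
frame_params_ms <- function(rate, frame_ms = 25, hop_ms = 10) {
  frame_params(round(rate * frame_ms / 1000), round(rate * hop_ms / 1000))
}

#' Slice a signal into fixed-length frames
#'
#' Frames cover the signal at the configured hop; a trailing remainder
#' shorter than one frame is dropped. Within a frame the signal is treated as
#' stationary, which is what justifies summarising each frame by a single
#' intensity value.
#'
#' @param signal An \code{audio_signal} (or plain numeric vector).
#' @param params A \code{frame_params}.
#' @return A \code{frame_len x num_f} numeric matrix, one frame per column.
#' @export
frame_signal <- function(signal, params) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < params$frame_len)
    stop(sprintf("frame_signal: signal has %d samples, shorter than one frame (%d)",
                 n, params$frame_len))
  starts <- seq.int(1L, n - params$frame_len + 1L, by = params$hop)
  idx <- outer(seq_len(params$frame_len) - 1L, starts, `+`)
  matrix(x[idx], nrow = params$frame_len)
}

#' Per-frame mean intensity track
#'
#' Each frame is summarised by the mean of its per-sample intensity. Under
#' the default power convention the per-sample intensity is the squared
#' amplitude; \code{convention = "amplitude"} uses the absolute amplitude
#' instead. Downstream intensity-variation features depend on this choice.
#'
#' @param frames Numeric matrix from \code{frame_signal()} (frames in
#'   columns), or a list of numeric vectors.
#' @param convention \code{"power"} (squared amplitude, default) or
#'   \code{"amplitude"}.
#' @return An \code{intensity_track}: numeric vector of per-frame means.
#' @export
intensity_means <- function(frames, convention = c("power", "amplitude")) {
  convention <- match.arg(convention)
  if (is.list(frames)) {
    if (any(lengths(frames) == 0L)) stop("intensity_means: empty frame")
    vals <- vapply(frames, function(f) {
      f <- as.numeric(f)
      if (convention == "power") mean(f^2) else mean(abs(f))
    }, numeric(1))
  } else {
    if (nrow(frames) == 0L) stop("intensity_means: empty frame")
    vals <- if (convention == "power") colMeans(frames^2) else colMeans(abs(frames))
  }
  structure(as.numeric(vals), class = "intensity_track")
}

#' Phonatory intensity variation diversity (PIVD)
#'
#' The spread of frame-to-frame intensity change. The first-order difference
#' of the per-frame mean-intensity sequence is taken, and PIVD is the
#' standard deviation of that difference sequence with divisor
#' \code{num_f - 1} (the length of the difference sequence). Flat, monotonous
#' loudness gives PIVD near 0; lively intensity variation gives large PIVD.
#'
#' @param track An \code{intensity_track} (numeric vector of per-frame mean
#'   intensities), length \code{num_f >= 3}.
#' @return Non-negative scalar.
#' @export
pivd <- function(track) {
  v <- as.numeric(track)
  num_f <- length(v)
  if (num_f < 3L)
    stop("pivd: need at least 3 frames (difference sequence of length >= 2)")
  d <- diff(v)
  # divisor num_f - 1 = length of the difference sequence
  sqrt(sum((d - mean(d))^2) / (num_f - 1L))
}

#' Baseline intensity summary statistics
#'
#' Comparator feature set: mean, min, max and sample SD of the per-frame
#' intensity means. Order-free summaries that ignore the intensity
#' trajectory, unlike \code{\link{pivd}}.
#'
#' @param track An \code{intensity_track} of length >= 2.
#' @return Named numeric vector \code{c(mean, min, max, sd)}.
#' @export
baseline_intensity_stats <- function(track) {
  v <- as.numeric(track)
  if (length(v) < 2L) stop("baseline_intensity_stats: need >= 2 frames")
  c(mean = mean(v), min = min(v), max = max(v), sd = stats::sd(v))
}

#' Baseline pitch statistics from an autocorrelation F0 tracker
#'
#' Comparator feature: mean and SD of the fundamental frequency over voiced
#' frames. Framewise normalized autocorrelation; a frame is voiced when the
#' best normalized autocorrelation peak in the candidate lag range exceeds
#' \code{voicing}; its F0 is \code{rate / lag} at that peak.
#'
#' @param signal An \code{audio_signal}.
#' @param fmin,fmax F0 search range in Hz (default 60-400).
#' @param voicing Voicing threshold on the normalized autocorrelation peak
#'   (default 0.3).
#' @param frame_ms,hop_ms Analysis framing in ms (default 40/10; the frame
#'   must cover at least two periods of \code{fmin}).
#' @return Named numeric vector \code{c(mean, sd)} in Hz.
#' @export
baseline_pitch_stats <- function(signal, fmin = 60, fmax = 400, voicing = 0.3,
                                 frame_ms = 40, hop_ms = 10) {
  rate <- audio_rate(signal)
  x <- as.numeric(signal)
  # decimate to ~11 kHz (moving-average anti-alias): ample for F0 <= 400 Hz
  dec <- max(1L, floor(rate / 11025))
  if (dec > 1L) {
    n_keep <- (length(x) %/% dec) * dec
    x <- colMeans(matrix(x[seq_len(n_keep)], nrow = dec))
    rate <- rate / dec
  }
  signal <- audio_signal(x, rate)
  fp <- frame_params_ms(rate, frame_ms, hop_ms)
  fr <- frame_signal(signal, fp)
  fr <- sweep(fr, 2, colMeans(fr))          # remove DC per frame
  lag_min <- max(2L, floor(rate / fmax))
  lag_max <- ceiling(rate / fmin)
  if (lag_max >= fp$frame_len)
    stop("baseline_pitch_stats: frame too short for the requested fmin")
  # autocorrelation by FFT, per frame
  nfft <- 2L^ceiling(log2(2L * fp$frame_len))
  padded <- rbind(fr, matrix(0, nfft - fp$frame_len, ncol(fr)))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  f0 <- rep(NA_real_, ncol(fr))
  for (j in seq_len(ncol(fr))) {
    if (r0[j] <= 0) next
    seg <- ac[(lag_min + 1L):(lag_max + 1L), j] / r0[j]
    k <- which.max(seg)
    if (seg[k] >= voicing) {
      lag <- lag_min + k - 1L
      # parabolic interpolation of the autocorrelation peak
      if (k > 1L && k < length(seg)) {
        denom <- seg[k - 1L] - 2 * seg[k] + seg[k + 1L]
        if (denom < 0) lag <- lag + 0.5 * (seg[k - 1L] - seg[k + 1L]) / denom
      }
      f0[j] <- rate / lag
    }
  }
  f0 <- f0[!is.na(f0)]
  if (length(f0) == 0L)
    stop("baseline_pitch_stats: no voiced frames detected")
  c(mean = mean(f0), sd = if (length(f0) > 1L) stats::sd(f0) else 0)
}
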