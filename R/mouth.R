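#' Mouth aspect ratio sequence from landmarks
#'
#' Per frame, MAR = distance(P52, P58) / distance(P49, P55): mouth width
#' (upper to lower lip midpoints) over mouth length (corner to corner).
#' Frames whose landmarks failed detection can be passed as \code{NA}
#' coordinates and are linearly interpolated from neighbouring valid frames
#' (edges replicate the nearest valid value).
#'
#' @param lm A \code{landmark_sequence} (NA coordinates allowed only for
#'   wholly missing frames).
#' @return A \code{mar_sequence}: numeric vector of ratios with an
#'   \code{fps} attribute.
#' @export
mar_sequence <- function(lm) {
  fps <- attr(lm, "fps")
  p49 <- lm[, 49L, , drop = FALSE]; p55 <- lm[, 55L, , drop = FALSE]
  p52 <- lm[, 52L, , drop = FALSE]; p58 <- lm[, 58L, , drop = FALSE]
  dl <- sqrt((p49[, 1L, 1L] - p55[, 1L, 1L])^2 + (p49[, 1L, 2L] - p55[, 1L, 2L])^2)
  dw <- sqrt((p52[, 1L, 1L] - p58[, 1L, 1L])^2 + (p52[, 1L, 2L] - p58[, 1L, 2L])^2)
  missing <- is.na(dl) | is.na(dw)
  zero_len <- which(!missing & dl == 0)
  if (length(zero_len))
    stop(sprintf("mar_sequence: zero mouth length (coincident corners) at frame %d",
                 zero_len[1L]))
  vals <- dw / dl
  if (any(missing)) vals <- interpolate_gaps(vals)
  structure(as.numeric(vals), fps = fps, class = "mar_sequence")
}

# Linear interpolation over NA runs; leading/trailing NAs replicate the
# nearest valid value.
interpolate_gaps <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0L) stop("interpolate_gaps: no valid frames")
  stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
}

#' Construct a MAR sequence directly
#' @param values Non-negative numeric vector of mouth aspect ratios.
#' @param fps Frames per second.
#' @return A \code{mar_sequence}.
#' @export
mar_values <- function(values, fps) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("mar_values: values must be finite and >= 0")
  if (fps <= 0) stop("mar_values: fps must be positive")
  structure(values, fps = fps, class = "mar_sequence")
}

#' Time-domain map of a MAR sequence
#'
#' Length-normalising RGB encoding of the raw sequence: the i-th value is
#' written (row-major) into a square grid of side \code{ceiling(sqrt(L))}
#' (zero padded), its R channel pixel is \code{round(200 * value)} clipped to
#' [0, 255], and G = B = 0. The grid is then resized by nearest-neighbour to
#' \code{out_side} so that every sequence element is represented exactly.
#'
#' @param seq A \code{mar_sequence} (or numeric vector).
#' @param out_side Output image side in pixels (default 224, the backbone
#'   input size).
#' @return A \code{fluency_image}: integer array \code{out_side x out_side x
#'   3} in [0, 255] with attribute \code{kind = "time_map"}.
#' @export
time_domain_map <- function(seq, out_side = 224) {
  v <- as.numeric(seq)
  if (length(v) == 0L) stop("time_domain_map: empty sequence")
  px <- pmin(255L, pmax(0L, as.integer(round(200 * v))))
  side <- ceiling(sqrt(length(px)))
  cells <- integer(side * side)
  cells[seq_along(px)] <- px
  grid <- matrix(cells, side, side, byrow = TRUE)  # row-major fill
  r <- resize_nn(grid, out_side)
  img <- array(0L, dim = c(out_side, out_side, 3L))
  img[, , 1L] <- r
  structure(img, kind = "time_map", class = "fluency_image")
}

# Nearest-neighbour resize of a matrix to side x side.
resize_nn <- function(m, side) {
  ri <- pmin(nrow(m), floor((seq_len(side) - 0.5) * nrow(m) / side) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(side) - 0.5) * ncol(m) / side) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Short-time segmentation layout of a sequence
#'
#' @param len Sequence length in frames.
#' @param fps Frames per second.
#' @param seg_s Segment length in seconds (default 3).
#' @param hop_s Segmentation interval in seconds (default 1).
#' @return List with \code{seg_len}, \code{hop}, \code{n_segments},
#'   \code{starts} (1-based).
#' @export
segment_layout <- function(len, fps, seg_s = 3, hop_s = 1) {
  seg_len <- as.integer(round(seg_s * fps))
  hop <- as.integer(round(hop_s * fps))
  if (len < seg_len)
    stop(sprintf("segment_layout: sequence (%d frames) shorter than one %gs segment",
                 len, seg_s))
  n_seg <- (len - seg_len) %/% hop + 1L
  list(seg_len = seg_len, hop = hop, n_segments = n_seg,
       starts = seq.int(1L, by = hop, length.out = n_seg))
}

#' Per-segment magnitude spectra of a MAR sequence
#'
#' Short-time Fourier analysis with 3 s segments every 1 s: each segment is
#' Hamming-windowed and transformed with an FFT of the segment length (one
#' transform per segment, no sub-windowing).
#'
#' @param seq A \code{mar_sequence}.
#' @param seg_s,hop_s Segment length / interval in seconds (default 3/1).
#' @return List with \code{magnitude} (\code{n_bins x n_segments} matrix),
#'   \code{freqs} (Hz per bin, DC to Nyquist), \code{times} (segment start
#'   seconds).
#' @export
segment_spectra <- function(seq, seg_s = 3, hop_s = 1) {
  fps <- attr(seq, "fps")
  if (is.null(fps)) stop("segment_spectra: sequence lacks fps")
  v <- as.numeric(seq)
  lay <- segment_layout(length(v), fps, seg_s, hop_s)
  w <- hamming_window(lay$seg_len)
  n_bins <- lay$seg_len %/% 2L + 1L
  mag <- vapply(lay$starts, function(s) {
    seg <- v[s:(s + lay$seg_len - 1L)]
    mu <- mean(seg)
    # de-mean before windowing so the window does not smear the (large)
    # constant mouth-opening level into the low bins; the DC bin carries
    # the mean at the window's gain
    m <- Mod(stats::fft((seg - mu) * w))[seq_len(n_bins)]
    m[1L] <- abs(mu) * sum(w)
    m
  }, numeric(n_bins))
  mag <- matrix(mag, nrow = n_bins)
  list(magnitude = mag,
       freqs = (seq_len(n_bins) - 1L) * fps / lay$seg_len,
       times = (lay$starts - 1L) / fps)
}

#' 3-D spectrogram image of a MAR sequence
#'
#' Renders the time x frequency x magnitude surface of
#' \code{\link{segment_spectra}} as a deterministic fixed-viewpoint waterfall
#' projection: segments are drawn back to front with a fixed oblique offset,
#' each spectral column filled from its baseline up to a height proportional
#' to magnitude and coloured by magnitude with the viridis colormap.
#' Magnitudes are normalized by the global maximum of the recording, so the
#' image is bit-identical across runs for identical inputs.
#'
#' @param seq A \code{mar_sequence} lasting at least \code{seg_s} seconds.
#' @param out_side Image side in pixels (default 224).
#' @param seg_s,hop_s Segment length / interval in seconds (default 3/1).
#' @param drop_dc Drop the DC bin before rendering so the (large) constant
#'   mouth-opening level does not dominate the colour scale (default TRUE).
#' @return A \code{fluency_image} with attribute \code{kind = "spectrogram"}.
#' @export
spectrogram_3d <- function(seq, out_side = 224, seg_s = 3, hop_s = 1,
                           drop_dc = TRUE) {
  sp <- segment_spectra(seq, seg_s, hop_s)
  mag <- sp$magnitude
  if (drop_dc && nrow(mag) > 1L) mag <- mag[-1L, , drop = FALSE]
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  n_seg <- ncol(mag); n_bins <- nrow(mag)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256L, "viridis")))
  img <- array(0L, dim = c(out_side, out_side, 3L))
  depth <- max(1L, floor(out_side / (3L * max(1L, n_seg))))
  base0 <- out_side - 1L - depth * (n_seg - 1L)
  hmax <- floor(out_side * 0.55)
  xspan <- out_side - depth * (n_seg - 1L)
  for (s in n_seg:1L) {                      # back to front
    xoff <- depth * (s - 1L)
    ybase <- base0 + depth * (s - 1L)
    for (bx in seq_len(xspan)) {
      bin <- pmin(n_bins, floor((bx - 0.5) * n_bins / xspan) + 1L)
      m <- mag[bin, s]
      h <- floor(m * hmax)
      col <- pal[pmin(256L, floor(m * 255) + 1L), ]
      rows <- max(0L, ybase - h):ybase
      img[rows + 1L, xoff + bx, 1L] <- col[1L]
      img[rows + 1L, xoff + bx, 2L] <- col[2L]
      img[rows + 1L, xoff + bx, 3L] <- col[3L]
    }
  }
  structure(img, kind = "spectrogram", class = "fluency_image")
}

#' Write a fluency image as a lossless PNG
#' @param img A \code{fluency_image}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fluency_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
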