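#' Construct a facial-landmark sequence
#'
#' Per-video-frame 68-point 2-D landmarks in pixel coordinates (1-based point
#' indexing; x grows rightward, y grows downward as in image axes). Points
#' 1-17 are the jaw/head contour used for head-movement features; mouth
#' points 49/52/55/58 feed the mouth aspect ratio.
#'
#' @param frames Either a 3-d array \code{n_frames x 68 x 2} or a list of
#'   \code{68 x 2} matrices.
#' @param fps Frames per second (positive; 30 for the reading-task videos).
#' @return A \code{landmark_sequence}: array \code{n_frames x 68 x 2} with an
#'   \code{fps} attribute.
#' @export
landmark_sequence <- function(frames, fps) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("landmark_sequence: no frames")
    bad <- which(vapply(frames, function(f) !all(dim(as.matrix(f)) == c(68L, 2L)),
                        logical(1)))
    if (length(bad))
      stop(sprintf("landmark_sequence: frame %d does not have 68 x-y points", bad[1L]))
    arr <- aperm(simplify2array(lapply(frames, as.matrix)), c(3L, 1L, 2L))
  } else {
    arr <- frames
  }
  if (length(dim(arr)) != 3L || dim(arr)[2L] != 68L || dim(arr)[3L] != 2L)
    stop("landmark_sequence: expected n_frames x 68 x 2 coordinates")
  if (anyNA(arr) || any(!is.finite(arr)))
    stop("landmark_sequence: coordinates must be finite")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("landmark_sequence: fps must be a single positive number")
  structure(arr, fps = fps, class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence: %d frames x 68 points @ %g fps>\n",
              dim(x)[1L], attr(x, "fps")))
  invisible(x)
}

#' Frames-per-second of a landmark sequence
#' @param lm A \code{landmark_sequence}.
#' @return fps.
#' @export
landmark_fps <- function(lm) attr(lm, "fps")

#' Reading-task metadata
#' @param n_lines Number of text lines read (>= 1).
#' @return A \code{reading_meta} list.
#' @export
reading_meta <- function(n_lines) {
  n_lines <- as.integer(n_lines)
  if (is.na(n_lines) || n_lines < 1L) stop("reading_meta: n_lines must be >= 1")
  structure(list(n_lines = n_lines), class = "reading_meta")
}

#' Head-movement trajectory from the contour landmarks
#'
#' Per adjacent frame pair, the mean coordinate difference of the 17 head
#' contour points (points 1-17): the horizontal component \code{hm_r} tracks
#' movement in the repeated-reading (Rr) dimension, the vertical component
#' \code{hm_u} the unconscious-movement (Um) dimension.
#'
#' @param lm A \code{landmark_sequence} with at least 2 frames.
#' @return A \code{head_trajectory} list with numeric vectors \code{hm_r} and
#'   \code{hm_u}, each of length \code{n_frames - 1} (pixels/frame-step,
#'   signed).
#' @export
head_trajectory <- function(lm) {
  n <- dim(lm)[1L]
  if (n < 2L) stop("head_trajectory: need at least 2 frames")
  cx <- rowMeans(lm[, 1:17, 1L, drop = FALSE][, , 1L])
  cy <- rowMeans(lm[, 1:17, 2L, drop = FALSE][, , 1L])
  structure(list(hm_r = diff(cx), hm_u = diff(cy)),
            class = "head_trajectory")
}

#' Binarize the Rr-dimension trajectory into movement direction
#'
#' Rightward motion maps to 1 and leftward motion to 0. Steps within the
#' symmetric dead-band \code{|value| <= eps} carry the previously emitted
#' state (they are treated as no decisive motion); leading dead-band frames
#' take the first decisive direction, and an entirely dead trajectory is a
#' single constant state (1 by convention).
#'
#' @param hm_r Numeric vector of signed Rr frame differences.
#' @param eps Dead-band half-width in pixels/frame-step (default 0.2).
#' @return Integer vector of 0/1 of the same length.
#' @export
binarize_rr <- function(hm_r, eps = 0.2) {
  hm_r <- as.numeric(hm_r)
  if (length(hm_r) == 0L) stop("binarize_rr: empty trajectory")
  state <- ifelse(hm_r > eps, 1L, ifelse(hm_r < -eps, 0L, NA_integer_))
  if (all(is.na(state))) return(rep(1L, length(state)))
  first <- state[which(!is.na(state))[1L]]
  if (is.na(state[1L])) state[1L] <- first
  for (i in seq_along(state)[-1L]) if (is.na(state[i])) state[i] <- state[i - 1L]
  state
}

#' Count head-rotation events in a binarized trajectory
#'
#' A rotation is one 1-to-0 transition (the leftward return ending a
#' rightward reading sweep). Runs shorter than \code{min_run} frames are
#' first absorbed into the preceding run's state (the leading run into the
#' following one), which suppresses landmark jitter.
#'
#' @param b Integer/logical vector of 0/1 states.
#' @param min_run Minimum run length in frames (default 3).
#' @return Non-negative integer count of rotations.
#' @export
count_rotations <- function(b, min_run = 3) {
  b <- as.integer(b)
  if (length(b) == 0L) stop("count_rotations: empty sequence")
  repeat {
    r <- rle(b)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    k <- short[1L]
    r$values[k] <- if (k > 1L) r$values[k - 1L] else r$values[k + 1L]
    b <- inverse.rle(r)
  }
  r <- rle(b)
  v <- r$values
  sum(v[-length(v)] == 1L & v[-1L] == 0L)
}

#' Repeated-reading head-rotation ratio (RHR)
#'
#' Number of head rotations divided by the number of text lines. Values near
#' 1 correspond to straight-through reading (one return sweep per line);
#' values above 1 indicate re-reading.
#'
#' @param n_r Non-negative rotation count.
#' @param meta A \code{reading_meta} (or the line count itself).
#' @return Non-negative scalar.
#' @export
rhr <- function(n_r, meta) {
  n_l <- if (inherits(meta, "reading_meta")) meta$n_lines else as.integer(meta)
  if (is.na(n_l) || n_l < 1L) stop("rhr: n_lines must be >= 1")
  if (n_r < 0) stop("rhr: n_r must be >= 0")
  n_r / n_l
}

#' Unconscious head-movement degree (UHD)
#'
#' Sum of the absolute vertical (Um-dimension) head displacement per text
#' line. The necessary per-line vertical shift is similar across subjects,
#' so the excess reflects unconscious head movement.
#'
#' @param hm_u Numeric vector of signed Um frame differences.
#' @param meta A \code{reading_meta} (or the line count itself).
#' @return Non-negative scalar (pixels per line).
#' @export
uhd <- function(hm_u, meta) {
  n_l <- if (inherits(meta, "reading_meta")) meta$n_lines else as.integer(meta)
  if (is.na(n_l) || n_l < 1L) stop("uhd: n_lines must be >= 1")
  hm_u <- as.numeric(hm_u)
  if (length(hm_u) == 0L) stop("uhd: empty trajectory")
  sum(abs(hm_u)) / n_l
}

#' Motion-energy baseline from grayscale frame differences
#'
#' The trajectory-blind comparator: per adjacent frame pair, absolute pixel
#' differences inside a region of interest are summed where they exceed a
#' noise threshold, normalized by the ROI area; the feature is the mean over
#' frame pairs. Quantifies the amount of movement only.
#'
#' @param frames 3-d array \code{h x w x n_frames} of grayscale intensities
#'   (any consistent scale; threshold must be on the same scale).
#' @param threshold Noise threshold on absolute differences (default
#'   \code{10/255}, i.e. 10 gray levels of an 8-bit image scaled to [0,1]).
#' @param roi Optional list with integer vectors \code{rows}, \code{cols}
#'   selecting the head region; default whole frame.
#' @return Non-negative scalar motion energy.
#' @export
mea_motion_energy <- function(frames, threshold = 10 / 255, roi = NULL) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L || d[3L] < 2L)
    stop("mea_motion_energy: need an h x w x n array with >= 2 frames")
  if (!is.null(roi)) frames <- frames[roi$rows, roi$cols, , drop = FALSE]
  d <- dim(frames)
  area <- d[1L] * d[2L]
  dif <- abs(frames[, , -1L, drop = FALSE] - frames[, , -d[3L], drop = FALSE])
  dif[dif <= threshold] <- 0
  sum(dif) / ((d[3L] - 1L) * area)
}

#' Head region of interest from contour landmarks
#'
#' Bounding box of contour points 1-17 over all frames, dilated by a
#' fraction of its size, clipped to the frame.
#'
#' @param lm A \code{landmark_sequence}.
#' @param h,w Frame height and width in pixels.
#' @param dilate Fractional dilation of the box (default 0.2).
#' @return A list with integer vectors \code{rows} and \code{cols}.
#' @export
landmark_roi <- function(lm, h, w, dilate = 0.2) {
  xs <- lm[, 1:17, 1L]; ys <- lm[, 1:17, 2L]
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  dx <- (x1 - x0) * dilate / 2; dy <- (y1 - y0) * dilate / 2
  rows <- max(1L, floor(y0 - dy)):min(h, ceiling(y1 + dy))
  cols <- max(1L, floor(x0 - dx)):min(w, ceiling(x1 + dx))
  list(rows = rows, cols = cols)
}
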