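#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM 16-bit and IEEE float-32
#' files. Stereo input is downmixed to mono (channel mean) with a warning.
#'
#' @param path Path to a .wav file.
#' @return An \code{audio_signal} with samples in [-1, 1].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("read_wav: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("read_wav: not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(code = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  rate = readBin(con, "integer", 1, 4, endian = "little"),
                  byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
                  block = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("read_wav: corrupt WAV (missing fmt or data chunk): ", path)
  if (fmt$code == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
                 endian = "little") / 32768
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) %/% 4L, 4,
                 endian = "little")
  } else {
    stop(sprintf("read_wav: unsupported format (code %d, %d bits)",
                 fmt$code, fmt$bits))
  }
  if (fmt$channels > 1L) {
    warning(sprintf("read_wav: downmixing %d channels to mono", fmt$channels))
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_signal(x, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param signal An \code{audio_signal} with samples in [-1, 1].
#' @param path Output path.
#' @param bits 16 (PCM, default) or 32 (IEEE float).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  x <- as.numeric(signal)
  bits <- as.integer(bits)
  rate <- as.integer(audio_rate(signal))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 16) {
    pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    n_bytes <- 2L * length(pcm); code <- 1L
  } else if (bits == 32) {
    n_bytes <- 4L * length(x); code <- 3L
  } else stop("write_wav: bits must be 16 or 32")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * (bits %/% 8L)), con, size = 4, endian = "little")
  writeBin(bits %/% 8L, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  if (bits == 16) writeBin(pcm, con, size = 2, endian = "little")
  else writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a landmark sequence from CSV or JSON
#'
#' CSV schema: one row per frame with columns \code{frame_idx, x1, y1, ...,
#' x68, y68}. JSON schema: object with fields \code{fps} and \code{frames},
#' each frame an array of 68 [x, y] pairs.
#'
#' @param path Input path (format chosen by extension).
#' @param fps Frames per second; required for CSV, overrides JSON header if
#'   given.
#' @return A \code{landmark_sequence}.
#' @export
read_landmarks <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("read_landmarks: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(fps)) fps <- obj$fps
    fr <- obj$frames
    if (is.list(fr)) {
      bad <- which(vapply(fr, function(f) !all(dim(as.matrix(f)) == c(68L, 2L)),
                          logical(1)))
      if (length(bad))
        stop(sprintf("read_landmarks: frame %d does not have 68 points", bad[1L]))
      arr <- aperm(simplify2array(lapply(fr, as.matrix)), c(3L, 1L, 2L))
    } else arr <- fr
    return(landmark_sequence(arr, fps))
  }
  d <- utils::read.csv(path)
  if (ncol(d) != 137L)
    stop(sprintf("read_landmarks: expected 137 columns (frame_idx + 68 x-y pairs), got %d",
                 ncol(d)))
  if (is.null(fps)) stop("read_landmarks: fps must be supplied for CSV input")
  m <- as.matrix(d[, -1L])
  arr <- array(0, dim = c(nrow(m), 68L, 2L))
  arr[, , 1L] <- m[, seq(1L, 135L, by = 2L)]
  arr[, , 2L] <- m[, seq(2L, 136L, by = 2L)]
  landmark_sequence(arr, fps)
}

#' Write a landmark sequence as CSV
#'
#' @param lm A \code{landmark_sequence}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  n <- dim(lm)[1L]
  m <- matrix(0, n, 136L)
  m[, seq(1L, 135L, by = 2L)] <- lm[, , 1L]
  m[, seq(2L, 136L, by = 2L)] <- lm[, , 2L]
  d <- data.frame(frame_idx = seq_len(n) - 1L, m)
  names(d) <- c("frame_idx", paste0(rep(c("x", "y"), 68),
                                    rep(seq_len(68L), each = 2L)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
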