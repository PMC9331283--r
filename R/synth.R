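#' Group parameter block for the synthetic cohort
#'
#' The knobs through which the two groups differ, mirroring the directions
#' reported clinically: patients show flatter intensity variation (lower
#' \code{am_depth}), flatter pitch variation (lower \code{pitch_mod_depth}),
#' more re-reading head rotations (higher \code{extra_rotation_rate}), more
#' vertical head jitter (higher \code{jitter_sd}) and more dysfluent pauses
#' (higher \code{pause_rate}).
#'
#' @param am_depth Amplitude-modulation depth of the audio envelope
#'   (dimensionless, >= 0).
#' @param pitch_mod_depth Relative slow pitch-modulation depth (>= 0).
#' @param loudness Overall vocal gain (linear amplitude; reduced vocal
#'   intensity is part of flat affect).
#' @param extra_rotation_rate Poisson mean of extra (re-reading) head
#'   rotations per text line (>= 0).
#' @param jitter_sd SD of the per-frame vertical head jitter in pixels
#'   (>= 0).
#' @param pause_rate Rate of inserted reading pauses per second (>= 0).
#' @return A \code{group_block} list.
#' @export
group_block <- function(am_depth, pitch_mod_depth, loudness,
                        extra_rotation_rate, jitter_sd, pause_rate) {
  vals <- c(am_depth, pitch_mod_depth, loudness, extra_rotation_rate,
            jitter_sd, pause_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("group_block: all parameters must be finite and >= 0")
  structure(list(am_depth = am_depth, pitch_mod_depth = pitch_mod_depth,
                 loudness = loudness,
                 extra_rotation_rate = extra_rotation_rate,
                 jitter_sd = jitter_sd, pause_rate = pause_rate),
            class = "group_block")
}

#' Default control-group parameter block
#' @return A \code{group_block}.
#' @export
control_block <- function() group_block(am_depth = 0.5, pitch_mod_depth = 0.30,
                                        loudness = 0.25,
                                        extra_rotation_rate = 0.2,
                                        jitter_sd = 0.5, pause_rate = 0.05)

#' Default patient-group parameter block
#' @return A \code{group_block}.
#' @export
patient_block <- function() group_block(am_depth = 0.15, pitch_mod_depth = 0.05,
                                        loudness = 0.12,
                                        extra_rotation_rate = 1.5,
                                        jitter_sd = 2.0, pause_rate = 0.35)

#' Synthetic cohort specification
#'
#' Defaults mirror the reading-task study design: 20 subjects per group,
#' 4 text segments per subject (160 segments in total), 30 fps video with
#' 44,100 Hz audio.
#'
#' @param n_per_group Subjects per group (default 20).
#' @param segments_per_subject Segments per subject (default 4).
#' @param duration_s Segment duration in seconds (default 10).
#' @param fps Video frame rate (default 30).
#' @param audio_rate Audio sampling rate in Hz (default 44100).
#' @param n_lines Text lines per segment (default 8).
#' @param control,patient \code{group_block}s for the two groups.
#' @param seed Integer master seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_per_group = 20, segments_per_subject = 4,
                        duration_s = 10, fps = 30, audio_rate = 44100,
                        n_lines = 8, control = control_block(),
                        patient = patient_block(), seed = 1) {
  if (n_per_group < 1 || segments_per_subject < 1 || duration_s <= 0 ||
      fps <= 0 || audio_rate <= 0 || n_lines < 1)
    stop("cohort_spec: sizes, rates and durations must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 segments_per_subject = as.integer(segments_per_subject),
                 duration_s = duration_s, fps = fps, audio_rate = audio_rate,
                 n_lines = as.integer(n_lines), control = control,
                 patient = patient, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Synthesize a reading-task audio segment
#'
#' Harmonic carrier (decaying harmonics of a slowly pitch-modulated
#' fundamental) with syllable-rate sinusoid-plus-lowpass-noise amplitude
#' modulation of the configured depth, a weak aspiration-noise component,
#' and a fixed linear gain. No per-recording level normalization is applied,
#' so intensity features reflect the configured loudness directly.
#' Deterministic for a given seed. This is synthetic harmonic material, not
#' speech; the acoustic features operate on any signal.
#'
#' @param duration_s Duration in seconds (>= 1).
#' @param rate Sampling rate in Hz.
#' @param am_depth Amplitude-modulation depth (>= 0; 0 gives a constant
#'   envelope).
#' @param pitch_mod_depth Relative pitch-modulation depth (>= 0).
#' @param loudness Linear output gain (default 0.2).
#' @param breathiness Aspiration-noise amplitude relative to the carrier
#'   (default 0.05).
#' @param f0 Mean fundamental in Hz (default 140).
#' @param n_harmonics Number of harmonics (default 10).
#' @param am_hz Syllabic modulation frequency in Hz (default 3.5).
#' @param seed Integer seed.
#' @return An \code{audio_signal}.
#' @export
synth_audio <- function(duration_s, rate, am_depth, pitch_mod_depth,
                        loudness = 0.2, breathiness = 0.05, f0 = 140,
                        n_harmonics = 10, am_hz = 3.5, seed = 1) {
  if (duration_s < 1) stop("synth_audio: duration must be >= 1 s")
  if (am_depth < 0 || pitch_mod_depth < 0)
    stop("synth_audio: modulation depths must be >= 0")
  if (loudness <= 0) stop("synth_audio: loudness must be > 0")
  set.seed(seed)
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  f0_t <- f0 * (1 + pitch_mod_depth * sin(2 * pi * 0.4 * t + ph1))
  phase <- 2 * pi * cumsum(f0_t) / rate
  x <- numeric(n)
  hph <- stats::runif(n_harmonics, 0, 2 * pi)
  for (h in seq_len(n_harmonics)) x <- x + sin(h * phase + hph[h]) / h
  x <- x / stats::sd(x)
  # slow noise component of the envelope: 80 ms moving average of white noise
  w <- max(2L, round(rate * 0.08))
  cs <- cumsum(stats::rnorm(n + w))
  slow <- (cs[(w + 1L):(n + w)] - cs[seq_len(n)]) / w
  slow <- slow / max(1e-12, stats::sd(slow))
  env <- 1 + am_depth * (0.7 * sin(2 * pi * am_hz * t + ph2) + 0.3 * slow)
  env <- pmax(env, 0.05)
  noise <- if (breathiness > 0) breathiness * stats::rnorm(n) else 0
  audio_signal(loudness * env * (x + noise), rate)
}

# Base 68-point face template (pixels); contour 1-17 on a lower semicircle,
# mouth corner points 49/55 horizontal, 52/58 vertical about the mouth center.
face_template <- function(cx = 320, cy = 240) {
  pts <- matrix(0, 68, 2)
  ang <- seq(pi, 2 * pi, length.out = 17)                 # jaw contour
  pts[1:17, 1] <- cx + 110 * cos(ang)
  pts[1:17, 2] <- cy - 110 * sin(ang) + 60
  brow <- seq(-60, 60, length.out = 10)
  pts[18:27, ] <- cbind(cx + brow, cy - 60)               # brows
  pts[28:36, ] <- cbind(cx, cy - 40 + 8 * (0:8))          # nose
  pts[37:42, ] <- cbind(cx - 45 + 6 * (0:5), cy - 25)     # eyes
  pts[43:48, ] <- cbind(cx + 15 + 6 * (0:5), cy - 25)
  mc <- c(cx, cy + 55)                                    # mouth
  pts[49, ] <- mc + c(-20, 0); pts[55, ] <- mc + c(20, 0)
  pts[52, ] <- mc + c(0, -8); pts[58, ] <- mc + c(0, 8)
  other_mouth <- setdiff(49:68, c(49, 52, 55, 58))
  amg <- seq(0, 2 * pi, length.out = length(other_mouth) + 1L)[-1L]
  pts[other_mouth, 1] <- mc[1] + 15 * cos(amg)
  pts[other_mouth, 2] <- mc[2] + 8 * sin(amg)
  pts
}

#' Synthesize a reading-task landmark sequence
#'
#' Constructs a rigidly moving 68-point face whose contour follows
#' per-line rightward reading sweeps with leftward returns (plus Poisson
#' extra re-reading sweeps), a deterministic downward step per text line,
#' and i.i.d. vertical jitter; mouth points 49/52/55/58 carry a
#' syllable-rate aspect-ratio oscillation interrupted by inserted pauses.
#'
#' @param duration_s Duration in seconds.
#' @param fps Frames per second.
#' @param n_lines Number of text lines.
#' @param extra_rotation_rate Poisson mean of extra sweeps per line.
#' @param jitter_sd Vertical jitter SD in pixels.
#' @param pause_rate Pause insertions per second.
#' @param syllable_hz Mouth oscillation frequency (default 4).
#' @param sweep_speed Rightward sweep speed in px/frame (default 1.5).
#' @param line_step Deterministic downward shift per line in pixels
#'   (default 6).
#' @param seed Integer seed.
#' @return List: \code{landmarks} (a \code{landmark_sequence}), \code{meta}
#'   (a \code{reading_meta}), \code{truth} (realized sweep count, per-frame
#'   MAR, parameters).
#' @export
synth_landmarks <- function(duration_s, fps, n_lines, extra_rotation_rate,
                            jitter_sd, pause_rate, syllable_hz = 4,
                            sweep_speed = 1.5, line_step = 6, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fps)
  extras <- stats::rpois(n_lines, extra_rotation_rate)
  if (n %/% n_lines < 8L)
    stop(sprintf("synth_landmarks: infeasible timing; %d lines do not fit %d frames",
                 n_lines, n))
  # the fixed duration bounds how many re-reading sweeps fit
  max_sweeps <- n %/% 8L
  while (sum(1L + extras) > max_sweeps) {
    j <- which(extras > 0L)
    pick <- j[sample.int(length(j), 1L)]
    extras[pick] <- extras[pick] - 1L
  }
  sweeps_per_line <- 1L + extras
  total_sweeps <- sum(sweeps_per_line)
  per <- n %/% total_sweeps
  fwd <- max(4L, round(0.7 * per)); ret <- per - fwd
  if (ret < 4L) { ret <- 4L; fwd <- per - ret }
  vx <- numeric(n); vy_det <- numeric(n)
  pos <- 0L
  for (l in seq_len(n_lines)) {
    for (s in seq_len(sweeps_per_line[l])) {
      f_idx <- pos + seq_len(fwd)
      r_idx <- pos + fwd + seq_len(ret)
      vx[f_idx] <- sweep_speed
      vx[r_idx] <- -sweep_speed * fwd / ret
      if (s == sweeps_per_line[l]) vy_det[r_idx] <- line_step / ret
      pos <- pos + per
    }
  }
  x_path <- cumsum(vx)
  y_path <- cumsum(vy_det) + (if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd) else 0)
  # mouth aspect ratio with inserted pauses
  tt <- (seq_len(n) - 1L) / fps
  mar <- 0.45 + 0.3 * sin(2 * pi * syllable_hz * tt)
  n_pause <- stats::rpois(1, pause_rate * duration_s)
  if (n_pause > 0) {
    starts <- stats::runif(n_pause, 0, duration_s)
    lens <- stats::runif(n_pause, 0.4, 1.0)
    for (k in seq_len(n_pause)) {
      idx <- which(tt >= starts[k] & tt < starts[k] + lens[k])
      mar[idx] <- 0.12
    }
  }
  mar <- pmax(mar, 0.05)
  tmpl <- face_template()
  frames <- array(0, dim = c(n, 68L, 2L))
  for (i in seq_len(n)) {
    f <- tmpl
    f[, 1] <- f[, 1] + x_path[i]
    f[, 2] <- f[, 2] + y_path[i]
    mcx <- f[49, 1] + 20; mcy <- f[49, 2]
    f[52, ] <- c(mcx, mcy - 20 * mar[i])
    f[58, ] <- c(mcx, mcy + 20 * mar[i])
    frames[i, , ] <- f
  }
  list(landmarks = landmark_sequence(frames, fps),
       meta = reading_meta(n_lines),
       truth = list(total_sweeps = total_sweeps, extras = extras,
                    mar = mar, line_step = line_step,
                    jitter_sd = jitter_sd, pause_rate = pause_rate))
}

# Between-subject SDs of the generator parameters: subjects within a group
# are not clones, which keeps single features informative but imperfect.
SUBJECT_SPREAD <- c(am_depth = 0.15, pitch_mod_depth = 0.08, loudness = 0.05,
                    extra_rotation_rate = 0.5, jitter_sd = 0.6,
                    pause_rate = 0.12)
SUBJECT_FLOOR <- c(am_depth = 0.02, pitch_mod_depth = 0, loudness = 0.08,
                   extra_rotation_rate = 0, jitter_sd = 0, pause_rate = 0)

#' Per-segment generation plan of a cohort
#'
#' Expands a \code{cohort_spec} into one row per (subject, segment).
#' Subject-level parameters are drawn around the group block values with
#' fixed between-subject spreads (truncated at small floors), and every
#' segment gets a derived sub-seed, so that generation can be streamed
#' segment by segment. Deterministic for a given spec.
#'
#' @param spec A \code{cohort_spec}.
#' @return Data frame: subject, group, label, segment, subject-level
#'   parameters, seed.
#' @export
cohort_manifest <- function(spec) {
  n_seg <- 2L * spec$n_per_group * spec$segments_per_subject
  set.seed(spec$seed)
  sub_seeds <- sample.int(2147480000L, n_seg)
  rows <- list(); i <- 0L
  for (grp in c("control", "patient")) {
    blk <- spec[[grp]]
    for (s in seq_len(spec$n_per_group)) {
      subj <- sprintf("%s%02d", if (grp == "control") "C" else "P", s)
      pars <- vapply(names(SUBJECT_SPREAD), function(p)
        max(SUBJECT_FLOOR[[p]],
            stats::rnorm(1, blk[[p]], SUBJECT_SPREAD[[p]])), numeric(1))
      for (g in seq_len(spec$segments_per_subject)) {
        i <- i + 1L
        rows[[i]] <- data.frame(subject = subj, group = grp,
                                label = as.integer(grp == "patient"),
                                segment = g,
                                am_depth = pars[["am_depth"]],
                                pitch_mod_depth = pars[["pitch_mod_depth"]],
                                loudness = pars[["loudness"]],
                                extra_rotation_rate = pars[["extra_rotation_rate"]],
                                jitter_sd = pars[["jitter_sd"]],
                                pause_rate = pars[["pause_rate"]],
                                seed = sub_seeds[i])
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate one synthetic segment from a manifest row
#'
#' @param row One row of \code{\link{cohort_manifest}} (as a list or
#'   one-row data frame).
#' @param spec The \code{cohort_spec}.
#' @return List with \code{audio}, \code{landmarks}, \code{meta},
#'   \code{truth}.
#' @export
synth_segment <- function(row, spec) {
  au <- synth_audio(spec$duration_s, spec$audio_rate, row$am_depth,
                    row$pitch_mod_depth, loudness = row$loudness,
                    seed = row$seed)
  lm <- synth_landmarks(spec$duration_s, spec$fps, spec$n_lines,
                        row$extra_rotation_rate, row$jitter_sd,
                        row$pause_rate, seed = row$seed + 1L)
  c(list(audio = au), lm)
}

#' Rasterize a landmark sequence into grayscale frames
#'
#' Renders each frame's 68 landmarks as 3x3 white dots on a black canvas,
#' with a common scale over the whole sequence, producing the grayscale
#' frame stack that the motion-energy baseline consumes. A crude stand-in
#' for real video: it carries the same motion, none of the appearance.
#'
#' @param lm A \code{landmark_sequence}.
#' @param side Canvas side in pixels (default 64).
#' @return Array \code{side x side x n_frames} with values in [0, 1].
#' @export
render_landmark_frames <- function(lm, side = 64) {
  n <- dim(lm)[1L]
  xs <- lm[, , 1L]; ys <- lm[, , 2L]
  x0 <- min(xs); y0 <- min(ys)
  sc <- (side - 9L) / max(max(xs) - x0, max(ys) - y0)
  arr <- array(0, dim = c(side, side, n))
  for (i in seq_len(n)) {
    cx <- pmin(side - 1L, pmax(2L, round((xs[i, ] - x0) * sc) + 3L))
    cy <- pmin(side - 1L, pmax(2L, round((ys[i, ] - y0) * sc) + 3L))
    for (p in seq_len(68L))
      arr[cy[p] + (-1:1), cx[p] + (-1:1), i] <- 1
  }
  arr
}

#' Generate a full synthetic two-group cohort
#'
#' Materializes every segment's audio and landmarks in memory. For the
#' default 160-segment cohort this holds roughly 0.6 GB of audio; use
#' \code{\link{cohort_features}} to stream feature extraction instead when
#' only features are needed.
#'
#' @param spec A \code{cohort_spec}.
#' @return List: \code{manifest} data frame (with realized ground truth
#'   columns \code{total_sweeps}), \code{segments} list of generated
#'   segments in manifest order.
#' @export
synth_cohort <- function(spec) {
  man <- cohort_manifest(spec)
  segs <- vector("list", nrow(man))
  man$total_sweeps <- NA_integer_
  for (i in seq_len(nrow(man))) {
    segs[[i]] <- synth_segment(man[i, ], spec)
    man$total_sweeps[i] <- segs[[i]]$truth$total_sweeps
  }
  list(manifest = man, segments = segs)
}
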