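test_that("mar_sequence is width over length of the mouth landmarks", {
  arr <- random_landmarks(1, seed = 1)
  arr[1, 49, ] <- c(0, 0); arr[1, 55, ] <- c(4, 0)
  arr[1, 52, ] <- c(2, 1); arr[1, 58, ] <- c(2, -2)
  expect_equal(as.numeric(mar_sequence(landmark_sequence(arr, 30))), 0.75)

  # width = length -> 1; closed mouth -> 0
  arr[1, 52, ] <- c(2, 2); arr[1, 58, ] <- c(2, -2)
  expect_equal(as.numeric(mar_sequence(landmark_sequence(arr, 30))), 1)
  arr[1, 52, ] <- c(2, 1); arr[1, 58, ] <- c(2, 1)
  expect_equal(as.numeric(mar_sequence(landmark_sequence(arr, 30))), 0)

  set.seed(17)
  for (i in 1:100) {
    a <- random_landmarks(sample(1:6, 1), seed = 2000 + i)
    got <- as.numeric(mar_sequence(landmark_sequence(a, 30)))
    expect_equal(got, oracle_mar(a), tolerance = 1e-10)
  }
})

test_that("coincident mouth corners raise a frame-indexed error", {
  arr <- random_landmarks(3, seed = 4)
  arr[2, 55, ] <- arr[2, 49, ]
  expect_error(mar_sequence(landmark_sequence(arr, 30)), "frame 2")
})

test_that("time_domain_map encodes 200x value in R with zero G and B", {
  img <- time_domain_map(mar_values(c(0.5, 0, 1.3, 0.25), 30), out_side = 8)
  expect_s3_class(img, "fluency_image")
  expect_equal(dim(img), c(8, 8, 3))
  expect_true(all(img[, , 2] == 0) && all(img[, , 3] == 0))
  expect_setequal(unique(as.vector(img[, , 1])), c(100, 0, 255, 50))
  # 0.5 -> 100; 1.3 clips at 255; 0 -> 0
  expect_equal(sort(unique(as.vector(img[, , 1]))), c(0, 50, 100, 255))
})

test_that("time_domain_map distinguishes sequences differing by >= 1/200", {
  set.seed(8)
  for (i in 1:25) {
    v <- stats::runif(sample(5:40, 1), 0, 1.2)
    j <- sample(length(v), 1)
    v2 <- v
    v2[j] <- min(1.27, v[j] + stats::runif(1, 1 / 200, 0.2))
    i1 <- time_domain_map(mar_values(v, 30))
    i2 <- time_domain_map(mar_values(v2, 30))
    expect_false(identical(i1, i2))
  }
  # determinism
  v <- stats::runif(30)
  expect_identical(time_domain_map(mar_values(v, 30)),
                   time_domain_map(mar_values(v, 30)))
})

test_that("segment layout matches the closed-form count", {
  expect_equal(segment_layout(300, 30)$n_segments, 8)  # 10 s at 30 fps
  set.seed(99)
  for (i in 1:50) {
    fps <- sample(c(24, 25, 30, 50), 1)
    L <- sample((3 * fps):(40 * fps), 1)
    expect_equal(segment_layout(L, fps)$n_segments,
                 floor((L - 3 * fps) / fps) + 1)
  }
  expect_error(segment_layout(89, 30), "shorter")
})

test_that("segment spectra concentrate where the signal does", {
  # constant sequence: all energy in the DC bin
  sp <- segment_spectra(mar_values(rep(0.4, 150), 30))
  expect_true(all(sp$magnitude[1, ] > 0))
  expect_lt(max(sp$magnitude[-1, ]), 1e-10 * min(sp$magnitude[1, ]))
  # 3 Hz sinusoid: per-segment peak at the bin nearest 3 Hz
  t <- (0:299) / 30
  sp3 <- segment_spectra(mar_values(0.5 + 0.3 * sin(2 * pi * 3 * t), 30))
  peak_bins <- apply(sp3$magnitude[-1, ], 2, which.max) + 1L
  nearest <- which.min(abs(sp3$freqs - 3))
  expect_true(all(peak_bins == nearest))
})

test_that("spectrogram_3d renders deterministically at the requested size", {
  v <- mar_values(0.5 + 0.3 * sin(2 * pi * 4 * (0:299) / 30), 30)
  img <- spectrogram_3d(v)
  expect_equal(dim(img), c(224, 224, 3))
  expect_equal(attr(img, "kind"), "spectrogram")
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(img, spectrogram_3d(v))
  expect_error(spectrogram_3d(mar_values(rep(0.4, 50), 30)), "shorter")
})

test_that("inserted pauses drain spectral energy at the syllable frequency", {
  band_energy <- function(pause_rate, seed) {
    lm <- synth_landmarks(8, 30, 5, 0, 0, pause_rate, syllable_hz = 4,
                          seed = seed)
    sp <- segment_spectra(mar_sequence(lm$landmarks))
    band <- which(sp$freqs >= 3.5 & sp$freqs <= 4.5)
    mean(sp$magnitude[band, ])
  }
  fluent <- vapply(1:20, function(s) band_energy(0, 3000 + s), numeric(1))
  dysfluent <- vapply(1:20, function(s) band_energy(0.6, 3000 + s), numeric(1))
  expect_gt(mean(fluent), mean(dysfluent))
  # strict separation of the seeded means
  expect_gt(min(fluent), max(dysfluent) * 0.99)
})

test_that("missing frames interpolate linearly with edge replication", {
  v <- c(NA, 2, NA, 4, NA)
  expect_equal(readtaskdx:::interpolate_gaps(v), c(2, 2, 3, 4, 4))
})

test_that("fluency images round-trip through PNG", {
  v <- mar_values(stats::runif(100), 30)
  img <- time_domain_map(v)
  path <- tempfile(fileext = ".png")
  write_fluency_png(img, path)
  back <- png::readPNG(path)
  expect_equal(round(back * 255), unclass(img), ignore_attr = TRUE)
  unlink(path)
})
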