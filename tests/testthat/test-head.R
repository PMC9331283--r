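make_seq <- function(arr, fps = 30) landmark_sequence(arr, fps)

test_that("head_trajectory averages contour-point frame differences", {
  arr <- random_landmarks(2, seed = 1)
  arr[2, , ] <- arr[1, , ]                       # identical frames
  tr <- head_trajectory(make_seq(arr))
  expect_equal(tr$hm_r, 0)
  expect_equal(tr$hm_u, 0)

  arr2 <- random_landmarks(3, seed = 2)
  arr2[2, , 1] <- arr2[1, , 1] + 2               # rigid (+2, -1)
  arr2[2, , 2] <- arr2[1, , 2] - 1
  arr2[3, , ] <- arr2[2, , ]
  tr2 <- head_trajectory(make_seq(arr2))
  expect_equal(tr2$hm_r, c(2, 0))
  expect_equal(tr2$hm_u, c(-1, 0))

  # split shift: 8 contour points move +4 in x, 9 stay
  arr3 <- random_landmarks(2, seed = 3)
  arr3[2, , ] <- arr3[1, , ]
  arr3[2, 1:8, 1] <- arr3[1, 1:8, 1] + 4
  expect_equal(head_trajectory(make_seq(arr3))$hm_r, 8 * 4 / 17)

  expect_error(head_trajectory(make_seq(random_landmarks(1))), "2 frames")
})

test_that("head_trajectory matches the loop oracle and is translation equivariant", {
  set.seed(31)
  for (i in 1:100) {
    arr <- random_landmarks(sample(2:8, 1), seed = 1000 + i)
    tr <- head_trajectory(make_seq(arr))
    orc <- oracle_head_trajectory(arr)
    expect_equal(tr$hm_r, orc$hm_r, tolerance = 1e-10)
    expect_equal(tr$hm_u, orc$hm_u, tolerance = 1e-10)
  }
  arr <- random_landmarks(6, seed = 77)
  shifted <- arr
  shifted[, , 1] <- shifted[, , 1] + 12.5
  shifted[, , 2] <- shifted[, , 2] - 3.25
  expect_equal(head_trajectory(make_seq(arr)),
               head_trajectory(make_seq(shifted)))
})

test_that("binarize_rr maps direction with a carried dead-band", {
  expect_equal(binarize_rr(c(3, 2, -1, -2), eps = 0.5), c(1, 1, 0, 0))
  expect_equal(binarize_rr(c(1, 0.1, -1), eps = 0.5), c(1, 1, 0))
  expect_equal(binarize_rr(c(0, 0, 0)), rep(1L, 3))      # all dead-band
  expect_equal(binarize_rr(c(0.1, -1, 2), eps = 0.5), c(0, 0, 1))  # leading carry
  expect_error(binarize_rr(numeric(0)), "empty")
})

test_that("count_rotations counts 1->0 transitions after min-run filtering", {
  expect_equal(count_rotations(rep(1, 10)), 0)
  expect_equal(count_rotations(c(1,1,1,0,0,0,1,1,1,0,0,0), min_run = 3), 2)
  expect_equal(count_rotations(c(1,1,1,0,1,1,1,0,0,0), min_run = 3), 1)
  # trailing frames of the same state do not add rotations
  b <- c(1,1,1,0,0,0)
  expect_equal(count_rotations(c(b, rep(0, 7))), count_rotations(b))
})

test_that("rhr and uhd are the line-normalized ratios", {
  expect_equal(rhr(4, reading_meta(4)), 1)
  expect_equal(rhr(0, reading_meta(5)), 0)
  expect_equal(rhr(7, reading_meta(4)), 1.75)
  expect_error(rhr(3, 0), ">= 1")

  expect_equal(uhd(rep(0, 10), reading_meta(3)), 0)
  expect_equal(uhd(c(1, -2, 3), reading_meta(2)), 3)
  hm <- stats::rnorm(20)
  expect_equal(uhd(hm, 4), uhd(-hm, 4))
  set.seed(3)
  for (i in 1:50) {
    hm <- stats::rnorm(sample(2:30, 1))
    nl <- sample(1:10, 1)
    expect_equal(uhd(hm, nl), oracle_uhd(hm, nl), tolerance = 1e-10)
  }
})

test_that("duration padding with motionless frames leaves RHR and UHD unchanged", {
  lm <- synth_landmarks(8, 30, 6, 1, 0.8, 0.1, seed = 9)
  arr <- lm$landmarks
  n <- dim(arr)[1]
  parr <- array(0, dim = c(n + 30, 68, 2))
  parr[1:n, , ] <- arr
  for (i in (n + 1):(n + 30)) parr[i, , ] <- arr[n, , ]
  padded <- landmark_sequence(parr, 30)
  f1 <- extract_head_features(lm$landmarks, lm$meta)
  f2 <- extract_head_features(padded, lm$meta)
  expect_equal(f1, f2)
})

test_that("mea_motion_energy thresholds and normalizes frame differences", {
  f <- array(0.4, dim = c(10, 10, 3))
  expect_equal(mea_motion_energy(f), 0)
  # one pixel of a 10x10 ROI changes by 50 gray levels (0-255 scale, thr 10)
  f2 <- array(100, dim = c(10, 10, 2))
  f2[3, 7, 2] <- 150
  expect_equal(mea_motion_energy(f2, threshold = 10), 50 / 100)
  # doubling the changed pixels doubles the energy
  f3 <- f2; f3[5, 2, 2] <- 150
  expect_equal(mea_motion_energy(f3, threshold = 10),
               2 * mea_motion_energy(f2, threshold = 10))
  # sub-threshold changes are ignored
  f4 <- array(100, dim = c(10, 10, 2)); f4[1, 1, 2] <- 105
  expect_equal(mea_motion_energy(f4, threshold = 10), 0)
  expect_error(mea_motion_energy(array(0, dim = c(4, 4, 1))), ">= 2")
})

test_that("trajectory features separate groups better than motion energy", {
  # the injected signal is trajectory-structured: the groups differ only in
  # re-reading rotation rate, not in motion amount (equal jitter and speed),
  # so the amount-only MEA baseline has little to work with
  ctrl <- group_block(am_depth = 0.5, pitch_mod_depth = 0.3, loudness = 0.25,
                      extra_rotation_rate = 0.2, jitter_sd = 1, pause_rate = 0.05)
  pat <- group_block(am_depth = 0.5, pitch_mod_depth = 0.3, loudness = 0.25,
                     extra_rotation_rate = 1.5, jitter_sd = 1, pause_rate = 0.05)
  spec <- cohort_spec(n_per_group = 8, segments_per_subject = 1,
                      duration_s = 6, audio_rate = 8000, n_lines = 5,
                      control = ctrl, patient = pat, seed = 404)
  man <- cohort_manifest(spec)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    seg <- synth_segment(man[i, ], spec)
    hf <- extract_head_features(seg$landmarks, seg$meta)
    frames <- render_landmark_frames(seg$landmarks, side = 48)
    data.frame(subject = man$subject[i], segment = man$segment[i],
               label = man$label[i], rhr = hf["rhr"], uhd = hf["uhd"],
               mea = mea_motion_energy(frames))
  })
  tab <- do.call(rbind, rows)
  cfg <- cv_config(folds = 4, repeats = 2, seed = 11)
  auc_traj <- cross_validate(tab[c("subject", "segment", "label", "rhr", "uhd")],
                             "svm", cfg)$summary$auc
  auc_mea <- cross_validate(tab[c("subject", "segment", "label", "mea")],
                            "svm", cfg)$summary$auc
  expect_gt(auc_traj, auc_mea)
})
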