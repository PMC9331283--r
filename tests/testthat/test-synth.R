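test_that("synth_audio is seed-deterministic and validates depths", {
  a1 <- synth_audio(1, 8000, 0.4, 0.2, seed = 12)
  a2 <- synth_audio(1, 8000, 0.4, 0.2, seed = 12)
  expect_identical(a1, a2)
  expect_false(identical(a1, synth_audio(1, 8000, 0.4, 0.2, seed = 13)))
  expect_error(synth_audio(1, 8000, -0.1, 0.2), "depths")
  expect_error(synth_audio(0.5, 8000, 0.1, 0.2), "duration")
})

test_that("zero modulation depth yields a near-flat intensity track", {
  fp <- frame_params_ms(8000)
  flat <- synth_audio(3, 8000, 0, 0, breathiness = 0, f0 = 160, seed = 21)
  mod <- synth_audio(3, 8000, 0.5, 0, breathiness = 0, f0 = 160, seed = 21)
  p_flat <- pivd(intensity_means(frame_signal(flat, fp)))
  p_mod <- pivd(intensity_means(frame_signal(mod, fp)))
  expect_lt(p_flat, 1e-6 * p_mod)
})

test_that("doubling modulation depth at fixed seed increases PIVD", {
  fp <- frame_params_ms(8000)
  for (s in 1:20) {
    p1 <- pivd(intensity_means(frame_signal(
      synth_audio(2, 8000, 0.2, 0.1, seed = s), fp)))
    p2 <- pivd(intensity_means(frame_signal(
      synth_audio(2, 8000, 0.4, 0.1, seed = s), fp)))
    expect_gt(p2, p1)
  }
})

test_that("constructed trajectories recover rotations and vertical travel exactly", {
  # zero extras, zero jitter: one return per line
  lm <- synth_landmarks(10, 30, 8, 0, 0, 0, seed = 31)
  tr <- head_trajectory(lm$landmarks)
  n_r <- count_rotations(binarize_rr(tr$hm_r))
  expect_equal(n_r, 8)
  expect_equal(rhr(n_r, lm$meta), 1)
  # zero jitter: UHD is the deterministic per-line step
  expect_equal(uhd(tr$hm_u, lm$meta), lm$truth$line_step, tolerance = 1e-9)
  # infeasible timing errors
  expect_error(synth_landmarks(1, 30, 10, 0, 0, 0), "infeasible")
})

test_that("synthetic groups separate in the documented directions", {
  fp <- frame_params_ms(8000)
  piv <- function(am, seeds) vapply(seeds, function(s)
    pivd(intensity_means(frame_signal(
      synth_audio(2, 8000, am, 0.1, seed = s), fp))), numeric(1))
  low <- piv(0.15, 1:20); high <- piv(0.5, 101:120)
  expect_gt(stats::median(high), stats::median(low))

  r_of <- function(rate, seeds) vapply(seeds, function(s) {
    lm <- synth_landmarks(8, 30, 5, rate, 0, 0, seed = s)
    tr <- head_trajectory(lm$landmarks)
    rhr(count_rotations(binarize_rr(tr$hm_r)), lm$meta)
  }, numeric(1))
  expect_gt(stats::median(r_of(1.5, 1:20)), stats::median(r_of(0, 201:220)))

  u_of <- function(j, seeds) vapply(seeds, function(s) {
    lm <- synth_landmarks(8, 30, 5, 0, j, 0, seed = s)
    uhd(head_trajectory(lm$landmarks)$hm_u, lm$meta)
  }, numeric(1))
  expect_gt(stats::median(u_of(2, 1:20)), stats::median(u_of(0.3, 301:320)))
})

test_that("cohort manifests have the study layout and are seed-stable", {
  spec <- cohort_spec()
  man <- cohort_manifest(spec)
  expect_equal(nrow(man), 160)                     # 40 subjects x 4 segments
  expect_equal(length(unique(man$subject)), 40)
  expect_equal(sum(man$label == 1), 80)
  expect_identical(man, cohort_manifest(spec))
  man2 <- cohort_manifest(cohort_spec(seed = 2))
  expect_false(identical(man$seed, man2$seed))
})

test_that("swapping group blocks swaps every feature difference direction", {
  base <- cohort_spec(n_per_group = 6, segments_per_subject = 1,
                      duration_s = 5, audio_rate = 8000, n_lines = 4, seed = 7)
  swapped <- cohort_spec(n_per_group = 6, segments_per_subject = 1,
                         duration_s = 5, audio_rate = 8000, n_lines = 4,
                         control = patient_block(), patient = control_block(),
                         seed = 7)
  fp <- frame_params_ms(8000)
  med_diff <- function(spec) {
    man <- cohort_manifest(spec)
    vals <- vapply(seq_len(nrow(man)), function(i) {
      seg <- synth_segment(man[i, ], spec)
      tr <- head_trajectory(seg$landmarks)
      c(pivd(intensity_means(frame_signal(seg$audio, fp))),
        rhr(count_rotations(binarize_rr(tr$hm_r)), seg$meta))
    }, numeric(2))
    c(pivd = stats::median(vals[1, man$label == 0]) -
        stats::median(vals[1, man$label == 1]),
      rhr = stats::median(vals[2, man$label == 0]) -
        stats::median(vals[2, man$label == 1]))
  }
  d1 <- med_diff(base); d2 <- med_diff(swapped)
  expect_gt(d1[["pivd"]], 0); expect_lt(d2[["pivd"]], 0)
  expect_lt(d1[["rhr"]], 0); expect_gt(d2[["rhr"]], 0)
})

test_that("rendered frames move only when the face moves", {
  lm <- synth_landmarks(3, 30, 2, 0, 0, 0, seed = 5)
  arr <- lm$landmarks
  still <- array(rep(arr[1, , ], each = dim(arr)[1]), dim = dim(arr))
  frames <- render_landmark_frames(landmark_sequence(still, 30))
  expect_equal(mea_motion_energy(frames, threshold = 0.04), 0)
  moving <- render_landmark_frames(lm$landmarks)
  expect_gt(mea_motion_energy(moving, threshold = 0.04), 0)
})
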