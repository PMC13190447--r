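test_that("ground-truth motion respects the configured kinematics", {
  cfg <- sim_config(seed = 601)
  set.seed(601)
  # null motion
  cfg0 <- sim_config(pitch_amplitude_deg = c(0, 0), yaw_amplitude_R_deg = 0,
                     roll_amplitude_deg = 0)
  null_ref <- generate_ground_truth(cfg0, "L")
  # yaw bump in L trials is also scaled by... only pitch/roll/yaw amps; yaw_L
  # has a fixed small 1.5 deg bump, so magnitudes stay under 2 deg
  expect_lt(max(magnitude_series(null_ref)$magnitude_deg), 2)
  # L trials: peak excursion in the configured flexion band, tiny yaw
  set.seed(602)
  peaks <- replicate(100, {
    full <- generate_ground_truth(cfg, "L")
    win <- extract_impact_window(full, cfg$impact_ms)
    c(max(magnitude_series(win)$magnitude_deg),
      max(abs(as.data.frame(win)$yaw)))
  })
  expect_true(all(peaks[1, ] >= 21.9 & peaks[1, ] <= 36.3))
  expect_true(all(peaks[2, ] < 5))
  # R trials: yaw ramp reaches the target at the window end
  set.seed(603)
  full_r <- generate_ground_truth(cfg, "R")
  win_r <- extract_impact_window(full_r, cfg$impact_ms)
  final_yaw <- utils::tail(as.data.frame(win_r)$yaw, 1)
  expect_lt(abs(final_yaw - cfg$yaw_amplitude_R_deg) /
              cfg$yaw_amplitude_R_deg, 0.1)
  # smoothness: bounded finite-difference angular acceleration
  inc <- increment_series(win_r)$increment_deg
  expect_lt(max(abs(diff(inc))), 0.05)
})

test_that("generated markers close the loop with the ACS construction", {
  cfg <- sim_config(marker_noise_mm = 0)
  set.seed(611)
  win <- extract_impact_window(generate_ground_truth(cfg, "R"),
                               cfg$impact_ms)
  mk <- generate_markers(win, cfg)
  for (i in c(1, 50, 100)) {
    m <- lapply(MARKER_LABELS, function(l) {
      as.numeric(mk[i, paste0(l, "_", c("x", "y", "z"))])
    })
    names(m) <- MARKER_LABELS
    expect_lt(max(abs(construct_acs(m)$rotation - win$R[, , i])), 1e-9)
  }
  # identity sequence: markers constant up to the head path
  cfg2 <- sim_config(pitch_amplitude_deg = c(0, 0), yaw_amplitude_R_deg = 0,
                     roll_amplitude_deg = 0, marker_noise_mm = 0)
  set.seed(612)
  win2 <- extract_impact_window(generate_ground_truth(cfg2, "L"),
                                cfg2$impact_ms)
  # remove the 1.5 deg L-trial yaw bump by zeroing: use relative spread
  mk2 <- generate_markers(win2, cfg2)
  rel <- mk2$EAM_L_y - mk2$EAM_R_y  # invariant under translation
  expect_lt(max(abs(rel - rel[1])), 0.5)
})

test_that("visibility profiles dip at impact and honour occlusion depth", {
  cfg <- sim_config(occlusion_depth = 0)
  set.seed(621)
  v0 <- replicate(200, {
    generate_visibility(cfg, "L", "F", rep(0, 6))$visibility_raw
  })
  # no ball dip: only baseline/arm variation, impact frame no worse than
  # the rest
  expect_true(all(v0 >= 0.6))
  expect_lt(abs(mean(v0[2, ]) - mean(v0[-2, ])), 0.03)
  cfg6 <- sim_config(occlusion_depth = 0.6)
  set.seed(622)
  dips <- replicate(50, {
    generate_visibility(cfg6, "L", "F", rep(0, 6))$visibility_raw[2]
  })
  expect_equal(mean(dips), 0.4, tolerance = 0.1)
  expect_true(all(dips == pmin(dips, 1)))
  # side camera loses visibility with yaw (self-occlusion on R trials)
  set.seed(623)
  yaw <- c(0, 5, 20, 31, 40, 45)
  v_side <- replicate(50, {
    mean(generate_visibility(cfg6, "R", "S", yaw)$visibility_raw)
  })
  set.seed(624)
  v_front <- replicate(50, {
    mean(generate_visibility(cfg6, "R", "F", yaw)$visibility_raw)
  })
  expect_lt(mean(v_side), mean(v_front))
})

test_that("emitted boxes reproduce the intended visibility ratios", {
  cfg <- sim_config(occlusion_depth = 0.6)
  set.seed(631)
  vis <- generate_visibility(cfg, "L", "F", rep(0, 6))
  areas <- vapply(vis$boxes$frames, function(f) {
    visible_face_area(f$face, f$occluders)
  }, 0)
  face_area <- 120 * 140
  expect_equal(areas / face_area, vis$visibility_raw, tolerance = 1e-9)
})

test_that("predictions carry the offset, the frame change and the noise", {
  cfg <- sim_config()
  set.seed(641)
  win <- extract_impact_window(generate_ground_truth(cfg, "L"),
                               cfg$impact_ms)
  fmap <- map_video_frames()
  refv <- win[fmap$mocap_index]
  refv$t_ms <- fmap$t_ms
  ext <- default_extrinsics()$F
  # noiseless with identity offset: pipeline recovers GE == 0 end-to-end
  p0 <- generate_predictions(refv, rep(1, 6), diag(3), ext,
                             sigma0_deg = 0, sigma1_deg = 0)
  expect_equal(p0$frame, "C:F")
  g0 <- camera_to_global(p0, ext)
  expect_equal(max(geodesic_error_series(refv, g0)$ge_deg), 0,
               tolerance = 1e-9)
  # noiseless 15 deg offset: alignment recovers it exactly
  D <- rot_exp(c(1, 2, -1) / sqrt(6) * 15 * pi / 180)
  p1 <- generate_predictions(refv, rep(1, 6), D, ext, 0, 0)
  fit <- fit_alignment(refv, camera_to_global(p1, ext))
  expect_lt(max(abs(fit$delta - t(D))), 1e-8)
  expect_equal(geodesic_error_series(refv,
                                     camera_to_global(p1, ext))$ge_deg,
               rep(15, 6), tolerance = 1e-6)
  expect_lt(max(fit$ge_after_deg), 1e-5)
  # visibility-dependent noise: lower visibility, larger average error
  set.seed(642)
  vlo <- rep(0.1, 6); vhi <- rep(1, 6)
  ge_lo <- replicate(100, {
    p <- generate_predictions(refv, vlo, diag(3), ext, 2, 6)
    mean(geodesic_error_series(refv, camera_to_global(p, ext))$ge_deg)
  })
  ge_hi <- replicate(100, {
    p <- generate_predictions(refv, vhi, diag(3), ext, 2, 6)
    mean(geodesic_error_series(refv, camera_to_global(p, ext))$ge_deg)
  })
  expect_gt(mean(ge_lo), mean(ge_hi) * 2)
})

test_that("dataset generation is deterministic and structurally complete", {
  cfg <- sim_config(n_participants = 2, trials_per_type = 2, seed = 99)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_equal(length(ds1$records), 2 * 4 * 2)  # participants x trials x cams
  expect_identical(ds1$records[[5]]$predictions$face_high$R,
                   ds2$records[[5]]$predictions$face_high$R)
  expect_identical(ds1$manifest$offsets, ds2$manifest$offsets)
  types <- vapply(ds1$records, function(r) r$trial_type, "")
  cams <- vapply(ds1$records, function(r) r$camera, "")
  expect_setequal(unique(types), c("L", "R"))
  expect_setequal(unique(cams), c("F", "S"))
  rec <- ds1$records[[1]]
  expect_equal(length(rec$reference), 100L)
  expect_equal(length(rec$reference_video), 6L)
  expect_equal(rec$reference_video$t_ms, c(0, 20, 40, 60, 80, 100))
  expect_equal(length(rec$predictions), 3L)
  # reference_video frames are the mapped mocap samples of the window
  fmap <- map_video_frames()
  expect_equal(rec$reference_video$R,
               rec$reference$R[, , fmap$mocap_index])
  # file outputs: same seed -> byte-identical
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_true(length(f1) > 10)
  same <- vapply(f1, function(f) {
    identical(readLines(file.path(d1, f), warn = FALSE),
              readLines(file.path(d2, f), warn = FALSE))
  }, TRUE)
  expect_true(all(same))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("true offsets are recoverable from the generated dataset", {
  cfg <- sim_config(n_participants = 2, trials_per_type = 2, seed = 17)
  ds <- generate_dataset(cfg, markers = FALSE)
  prof <- "body_low"
  D <- ds$offsets[[prof]]
  deltas <- lapply(ds$records, function(rec) {
    pred <- camera_to_global(rec$predictions[[prof]],
                             ds$extrinsics[[rec$camera]])
    fit_alignment(rec$reference_video, pred)$delta
  })
  # per-trial estimates scatter around the true offset ...
  errs <- vapply(deltas, function(dl) rot_dist(dl, t(D)), 0) * 180 / pi
  expect_lt(mean(errs), 2.5)
  # ... and their Karcher average recovers it well within 2 degrees
  pooled <- karcher_mean(deltas)$mean
  expect_lt(rot_dist(pooled, t(D)) * 180 / pi, 2)
  # manifest records the same offsets
  m_off <- ds$manifest$offsets[[which(vapply(ds$manifest$offsets,
                                             `[[`, "", "profile") == prof)]]
  expect_equal(m_off$angle_deg, cfg$offset_angle_deg, tolerance = 1e-9)
})
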