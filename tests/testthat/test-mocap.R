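test_that("zero-lag filtering preserves DC and cancels phase", {
  x <- rep(5, 200)
  expect_lt(max(abs(butterworth_zero_lag(x, 50, 1000) - 5)), 1e-9)
  t <- seq(0, 0.999, by = 1e-3)
  s <- sin(2 * pi * 10 * t)
  y <- butterworth_zero_lag(s, 50, 1000)
  cc <- stats::ccf(y, s, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # two passes of -3 dB at the cutoff: amplitude gain 0.5
  sc <- sin(2 * pi * 50 * t)
  yc <- butterworth_zero_lag(sc, 50, 1000)
  expect_equal(max(abs(yc[300:700])), 0.5, tolerance = 0.05)
  expect_error(butterworth_zero_lag(c(1, NA, 3, rep(0, 20)), 50, 1000),
               "gap")
})

test_that("residual analysis recovers the noise floor and picks a cutoff", {
  t <- seq(0, 1.999, by = 1e-3)
  grid <- seq(10, 300, by = 10)
  clean <- 10 * sin(2 * pi * 5 * t)
  res <- select_cutoff_residual(clean, 1000, grid)
  # residual is tiny (relative to the 10 mm amplitude) once the cutoff
  # clears the signal band; the noiseless intercept is essentially zero
  expect_true(all(res$residuals$rms[res$residuals$cutoff_hz >= 20] < 0.05))
  expect_lt(res$intercept, 0.01)
  # Monte-Carlo: intercept estimates the known noise RMS within 20%
  set.seed(71)
  rel_err <- replicate(50, {
    noisy <- clean + rnorm(length(t), sd = 0.5)
    r <- select_cutoff_residual(noisy, 1000, grid)
    (r$intercept - 0.5) / 0.5
  })
  expect_lt(abs(mean(rel_err)), 0.2)
  # white noise only: residual decreases as the cutoff rises
  set.seed(72)
  ok <- replicate(20, {
    r <- select_cutoff_residual(rnorm(500), 1000, seq(50, 450, by = 50))
    all(diff(r$residuals$rms) < 0)
  })
  expect_true(all(ok))
  expect_error(select_cutoff_residual(clean, 1000, c(10, 20, 30)),
               "at least 4")
})

test_that("fft threshold check returns the highest retained frequency", {
  t <- seq(0, 1.999, by = 1e-3)
  pure <- sin(2 * pi * 8 * t)
  expect_equal(fft_threshold_check(pure, 1000), 8, tolerance = 0.5)
  two_small <- pure + 0.05 * sin(2 * pi * 40 * t)
  expect_equal(fft_threshold_check(two_small, 1000), 8, tolerance = 0.5)
  two_big <- pure + 0.2 * sin(2 * pi * 40 * t)
  expect_equal(fft_threshold_check(two_big, 1000), 40, tolerance = 0.5)
})

test_that("ACS construction is exact on the canonical head and equivariant", {
  m <- canonical_markers()
  acs <- construct_acs(m)
  expect_equal(acs$rotation, diag(3), tolerance = 1e-12)
  expect_equal(acs$origin, c(0, 0, 0))
  # equivariance under an arbitrary rigid motion
  set.seed(81)
  for (i in 1:20) {
    R <- rand_rotation(); tv <- rnorm(3, sd = 100)
    acs2 <- construct_acs(canonical_markers(R, tv))
    expect_lt(max(abs(acs2$rotation - R)), 1e-9)
    expect_equal(acs2$origin, as.numeric(tv), tolerance = 1e-9)
  }
  expect_equal(construct_acs(canonical_markers(rot_z(45)))$rotation,
               rot_z(45), tolerance = 1e-10)
  # 0.5 mm marker noise keeps the mean orientation error below 1 degree
  set.seed(82)
  errs <- replicate(1000, {
    m2 <- lapply(canonical_markers(), function(p) p + rnorm(3, sd = 0.5))
    rot_dist(project_rotation(construct_acs(m2)$rotation), diag(3))
  })
  expect_lt(mean(errs) * 180 / pi, 1)
  bad <- canonical_markers()
  bad$EAM_L <- bad$EAM_R
  expect_error(construct_acs(bad), "degenerate")
})

test_that("rigid fit recovers exact transforms and beats random rotations", {
  g <- headkin:::.DEFAULT_MARKER_GEOMETRY
  f0 <- rigid_fit(g, g)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(f0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(f0$rmsd, 1e-10)
  set.seed(91)
  R <- rand_rotation(); tv <- c(10, -20, 30)
  obs <- t(R %*% t(g) + tv)
  f1 <- rigid_fit(g, obs)
  expect_lt(max(abs(f1$rotation - R)), 1e-10)
  expect_equal(f1$translation, tv, tolerance = 1e-10)
  expect_lt(f1$rmsd, 1e-10)
  # one displaced marker: the LS solution dominates 1000 random rotations
  obs2 <- obs; obs2[1, ] <- obs2[1, ] + 5
  f2 <- rigid_fit(g, obs2)
  expect_gt(f2$rmsd, 0)
  ss <- function(Rc) {
    ctr_g <- colMeans(g); ctr_o <- colMeans(obs2)
    pred <- t(Rc %*% t(sweep(g, 2, ctr_g))) +
      matrix(ctr_o, nrow(g), 3, byrow = TRUE)
    sum((obs2 - pred)^2)
  }
  ss_fit <- ss(f2$rotation)
  expect_true(all(replicate(1000, ss(rand_rotation())) >= ss_fit - 1e-9))
  expect_error(rigid_fit(g[1:2, ], g[1:2, ]), "at least 3")
  lin <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(rigid_fit(lin, lin), "collinear")
})

test_that("construct_acs and rigid_fit agree on noiseless markers", {
  set.seed(95)
  R <- rand_rotation()
  m <- canonical_markers(R, c(5, 5, 5))
  g <- headkin:::.DEFAULT_MARKER_GEOMETRY
  obs <- do.call(rbind, m)
  expect_lt(max(abs(construct_acs(m)$rotation -
                    rigid_fit(g, obs)$rotation)), 1e-9)
})

test_that("impact windows have the study frame counts and relative times", {
  full <- zseq(rep(0, 1000) + seq(0, 99.9, by = 0.1),
               t_ms = 0:999, rate = 1000)
  w <- extract_impact_window(full, impact_ms = 500)
  expect_equal(length(w), 100L)
  expect_equal(w$t_ms, 0:99)
  # conservation regardless of impact time
  for (imp in c(100, 333, 777)) {
    expect_equal(length(extract_impact_window(full, imp)), 100L)
  }
  expect_error(extract_impact_window(full, impact_ms = 10), "outside")
  expect_error(extract_impact_window(full, 500, pre_ms = 0, post_ms = 0),
               "empty window")
  # 50 Hz input: frames at 0, 20, 40, 60, 80 ms under the half-open window
  s50 <- zseq(seq(0, 45, by = 5), t_ms = seq(400, 580, by = 20), rate = 50)
  w50 <- extract_impact_window(s50, impact_ms = 500)
  expect_equal(w50$t_ms, c(0, 20, 40, 60, 80))
})

test_that("video frames map to the documented mocap samples", {
  fmap <- map_video_frames()
  expect_equal(fmap$mocap_index - 1L, c(0L, 20L, 40L, 60L, 80L, 99L))
  expect_equal(fmap$t_ms[2], 20)  # impact frame
})

test_that("marker tables round-trip, reject bad data and fill short gaps", {
  cfg <- sim_config(n_participants = 1, trials_per_type = 1, seed = 5)
  set.seed(5)
  ref <- generate_ground_truth(cfg, "L")
  win <- extract_impact_window(ref, cfg$impact_ms)
  mk <- generate_markers(win, cfg)
  path <- tempfile(fileext = ".tsv")
  write_marker_tsv(mk, path)
  mk2 <- read_marker_tsv(path)
  expect_equal(mk2$EAM_L_x, mk$EAM_L_x, tolerance = 1e-9)
  # gaps: short interior gap filled linearly, long gap rejected
  mk3 <- mk
  mk3$SNA_x[40:45] <- NA
  filled <- fill_marker_gaps(mk3)
  expect_false(anyNA(filled$SNA_x))
  expect_equal(filled$SNA_x[40],
               approx(c(39, 46), mk$SNA_x[c(39, 46)] * 0 +
                        c(mk3$SNA_x[39], mk3$SNA_x[46]), xout = 40)$y)
  mk4 <- mk
  mk4$SNA_x[30:55] <- NA
  expect_error(fill_marker_gaps(mk4), "longer than")
  mk5 <- mk; mk5$EAM_L_x[1] <- 2e4
  write_marker_tsv(mk5, path)
  expect_error(read_marker_tsv(path), "capture")
})

test_that("marker-to-orientation closure recovers the generating sequence", {
  cfg <- sim_config(n_participants = 1, trials_per_type = 1, seed = 7)
  set.seed(7)
  ref <- generate_ground_truth(cfg, "R")
  win <- extract_impact_window(ref, cfg$impact_ms)
  # noiseless: exact recovery through the ACS construction
  cfg0 <- cfg; cfg0$marker_noise_mm <- 0
  mk0 <- generate_markers(win, cfg0)
  rec0 <- markers_to_rotseq(mk0, cutoff = NULL, method = "acs")
  expect_lt(max(abs(rec0$R - win$R)), 1e-9)
  # default noise, full path (filter + rigid fit): mean error < 0.5 deg
  mk1 <- generate_markers(win, cfg)
  rec1 <- markers_to_rotseq(mk1, rate = 1000, cutoff = 50)
  errs <- vapply(seq_len(length(win)), function(i) {
    rot_dist(rec1$R[, , i], win$R[, , i])
  }, 0) * 180 / pi
  expect_lt(mean(errs), 0.5)
  # rigid-fit rmsd reflects the injected noise level within 50%
  f <- rigid_fit(headkin:::.DEFAULT_MARKER_GEOMETRY,
                 do.call(rbind, canonical_markers()) +
                   matrix(rnorm(15, sd = 0.5), 5, 3))
  expect_gt(f$rmsd, 0.5 * 0.5)
  expect_lt(f$rmsd, 1.5 * 0.5 * sqrt(3))
})

test_that("filtering and frame construction approximately commute", {
  cfg <- sim_config(n_participants = 1, trials_per_type = 1, seed = 9,
                    marker_noise_mm = 0)
  set.seed(9)
  ref <- generate_ground_truth(cfg, "L")
  win <- extract_impact_window(ref, cfg$impact_ms)
  mk <- generate_markers(win, cfg)
  filt_then_frames <- markers_to_rotseq(mk, cutoff = 50, method = "acs")
  frames_raw <- markers_to_rotseq(mk, cutoff = NULL, method = "acs")
  e_raw <- as.data.frame(frames_raw)
  e_smooth <- as.data.frame(filt_then_frames)
  for (ch in c("yaw", "pitch", "roll")) {
    filtered_channel <- butterworth_zero_lag(e_raw[[ch]], 50, 1000)
    expect_lt(max(abs(filtered_channel - e_smooth[[ch]])), 0.5)
  }
})
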