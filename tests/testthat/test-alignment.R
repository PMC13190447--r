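test_that("camera-to-global transforms by left multiplication", {
  set.seed(101)
  s <- smooth_seq(6)
  s$frame <- "C:F"
  cam_id <- camera_extrinsics(diag(3), label = "F")
  out <- camera_to_global(s, cam_id)
  expect_equal(out$R, s$R)
  expect_equal(out$frame, "G")
  idseq <- zseq(rep(0, 3), t_ms = c(0, 20, 40))
  idseq$frame <- "C:F"
  idseq$R[, , 1:3] <- array(rep(diag(3), 3), c(3, 3, 3))
  cam_x <- camera_extrinsics(rot_x(90), label = "F")
  out2 <- camera_to_global(idseq, cam_x)
  expect_equal(out2$R[, , 2], rot_x(90), tolerance = 1e-12)
  # definition check under random extrinsics and poses
  cam_r <- camera_extrinsics(rand_rotation(), label = "F")
  s2 <- smooth_seq(4); s2$frame <- "C:F"
  out3 <- camera_to_global(s2, cam_r)
  for (i in 1:4) {
    expect_equal(rot_dist(out3$R[, , i],
                          cam_r$rotation_GC %*% s2$R[, , i]), 0,
                 tolerance = 1e-12)
  }
  s2$frame <- "C:S"
  expect_error(camera_to_global(s2, cam_r), "camera 'F'")
  s2$frame <- "G"
  expect_error(camera_to_global(s2, cam_r), "expected a camera frame")
})

test_that("framewise relative errors match the defining product", {
  set.seed(111)
  ref <- smooth_seq(3)
  expect_equal(framewise_relative_errors(ref, ref)[, , 2], diag(3),
               tolerance = 1e-12)
  D <- rot_exp(c(0.1, -0.2, 0.15))
  pred <- compose_seq(ref, right = D)
  d <- framewise_relative_errors(ref, pred)
  for (i in 1:3) {
    expect_lt(max(abs(d[, , i] - t(D))), 1e-12)  # delta_i = t(D) exactly
  }
  pred2 <- smooth_seq(3)
  d2 <- framewise_relative_errors(ref, pred2)
  for (i in 1:3) {
    expect_equal(d2[, , i], t(pred2$R[, , i]) %*% ref$R[, , i])
  }
  short <- ref[1:2]
  expect_error(framewise_relative_errors(ref, short), "lengths")
})

test_that("Karcher mean matches closed forms and a brute-force minimiser", {
  km0 <- karcher_mean(list(rot_z(25), rot_z(25), rot_z(25)))
  expect_equal(km0$mean, rot_z(25), tolerance = 1e-9)
  expect_equal(km0$iterations, 1L)
  km1 <- karcher_mean(list(rot_z(10), rot_z(30)))
  expect_lt(max(abs(km1$mean - rot_z(20))), 1e-9)
  # brute-force objective minimisation oracle (direct optimisation of the
  # sum of squared geodesic distances over a tangent parameterisation)
  set.seed(121)
  for (rep in 1:5) {
    rots <- simplify2array(lapply(1:5, function(i) {
      rot_z(0) %*% rand_rotation(sigma = 15 * pi / 180)
    }))
    km <- karcher_mean(rots)$mean
    obj <- function(v) karcher_objective(rot_exp(v), rots)
    opt <- optim(rot_log(project_rotation(apply(rots, c(1, 2), mean))),
                 obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_lt(rot_dist(km, rot_exp(opt$par)), 1e-4)
    expect_lte(karcher_objective(km, rots), opt$value + 1e-8)
  }
  # equivariance under fixed left/right composition
  set.seed(122)
  worst <- 0
  for (rep in 1:20) {
    rots <- simplify2array(lapply(1:4, function(i) {
      rand_rotation(sigma = 0.2)
    }))
    A <- rand_rotation(); B <- rand_rotation()
    conj <- rots
    for (i in 1:4) conj[, , i] <- A %*% rots[, , i] %*% B
    lhs <- karcher_mean(conj)$mean
    rhs <- A %*% karcher_mean(rots)$mean %*% B
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  expect_lt(worst, 1e-8)
  # dispersion beyond the uniqueness ball is rejected
  expect_error(karcher_mean(list(rot_z(0), rot_z(115), rot_z(235))),
               "dispersed|singular|not unique")
})

test_that("alignment removes an exact constant offset completely", {
  set.seed(131)
  ref <- smooth_seq(6, step_deg = 6)
  fit0 <- fit_alignment(ref, ref)
  expect_equal(fit0$delta, diag(3), tolerance = 1e-9)
  expect_equal(predict(fit0)$R, ref$R, tolerance = 1e-9)
  for (off_deg in c(5, 15, 40)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    D <- rot_exp(ax * off_deg * pi / 180)
    pred <- compose_seq(ref, right = D)
    fit <- fit_alignment(ref, pred)
    expect_lt(max(abs(fit$aligned$R - ref$R)), 1e-8)
    expect_equal(mean(fit$ge_before_deg), off_deg, tolerance = 1e-6)
    expect_lt(max(fit$ge_after_deg), 1e-6)
  }
  # single-frame sequence aligns exactly
  fit1 <- fit_alignment(ref[1], compose_seq(ref[1], right = rot_x(25)))
  expect_lt(rot_dist(fit1$aligned$R[, , 1], ref$R[, , 1]), 1e-9)
})

test_that("alignment recovers a noisy offset and never hurts on average", {
  set.seed(141)
  D <- rot_exp(c(0.12, 0.18, -0.08))
  # Monte-Carlo recovery at the study's 6-frame sequence length
  errs <- replicate(500, {
    ref <- smooth_seq(6, step_deg = 6)
    noisy <- compose_seq(ref, right = D)
    for (i in 1:6) {
      noisy$R[, , i] <- noisy$R[, , i] %*%
        rand_rotation(sigma = 2 * pi / 180)
    }
    rot_dist(fit_alignment(ref, noisy)$delta, t(D)) * 180 / pi
  })
  expect_lt(mean(errs), 2)
  # mean GE and mean squared GE never increase (200 random noisy pairs)
  set.seed(142)
  for (rep in 1:200) {
    ref <- smooth_seq(6, step_deg = 5)
    pred <- compose_seq(ref, right = rand_rotation(sigma = 0.1))
    for (i in 1:6) {
      pred$R[, , i] <- pred$R[, , i] %*% rand_rotation(sigma = 0.05)
    }
    fit <- fit_alignment(ref, pred)
    expect_lte(mean(fit$ge_after_deg^2), mean(fit$ge_before_deg^2) + 1e-9)
    expect_lte(mean(fit$ge_after_deg), mean(fit$ge_before_deg) + 1e-9)
  }
})

test_that("residual error after alignment is frame-choice invariant", {
  set.seed(151)
  ref <- smooth_seq(6)
  pred <- compose_seq(ref, right = rot_exp(c(0.1, 0, 0.2)))
  for (i in 1:6) {
    pred$R[, , i] <- pred$R[, , i] %*% rand_rotation(sigma = 0.03)
  }
  ge1 <- fit_alignment(ref, pred)$ge_after_deg
  A <- rand_rotation()
  ge2 <- fit_alignment(compose_seq(ref, left = A),
                       compose_seq(pred, left = A))$ge_after_deg
  expect_equal(ge1, ge2, tolerance = 1e-8)
})

test_that("alignment model object exposes the standard methods", {
  set.seed(161)
  ref <- smooth_seq(6)
  pred <- compose_seq(ref, right = rot_y(12))
  fit <- fit_alignment(ref, pred)
  expect_s3_class(fit, "pose_alignment")
  co <- coef(fit)
  expect_equal(unname(co["angle_deg"]), 12, tolerance = 1e-6)
  expect_equal(residuals(fit), fit$ge_after_deg)
  s <- summary(fit)
  expect_equal(s$n, 6L)
  expect_output(print(fit), "offset")
  expect_output(print(s), "mean GE")
  newpred <- compose_seq(ref[1:3], right = rot_y(12))
  expect_lt(max(abs(predict(fit, newpred)$R - ref[1:3]$R)), 1e-8)
  path <- tempfile(fileext = ".json")
  write_alignment_json(fit, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$delta_angle_deg, 12, tolerance = 1e-6)
  expect_true(j$converged)
})

test_that("extrinsics JSON round-trips", {
  cam <- default_extrinsics()$S
  path <- tempfile(fileext = ".json")
  write_extrinsics_json(cam, path)
  cam2 <- read_extrinsics_json(path)
  expect_equal(cam2$rotation_GC, cam$rotation_GC, tolerance = 1e-12)
  expect_equal(cam2$position_m, c(-0.1, 3.0, 0.9))
  expect_equal(cam2$label, "S")
})
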