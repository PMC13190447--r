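#' Anatomical alignment of predicted orientation sequences
#'
#' Monocular pose models express head orientation in the camera frame and
#' with their own notion of the head's anatomical axes. Comparing them with
#' motion-capture reference orientations therefore needs two corrections:
#' a change of frame into the global coordinate system using the camera
#' extrinsics (\code{camera_to_global}), and removal of the constant
#' anatomical-axis offset between the model's head frame and the
#' experimental anatomical coordinate system. The offset is estimated as
#' the Karcher (Frechet) mean on SO(3) of the framewise relative errors and
#' removed by a constant right-composition (\code{fit_alignment}).
#'
#' @name alignment
#' @keywords internal
NULL

#' Camera extrinsics
#'
#' @param rotation_GC rotation mapping camera-frame coordinates to the
#'   global frame.
#' @param position_m camera position in the global frame, metres.
#' @param label camera label, conventionally "F" (front) or "S" (side).
#' @return object of class \code{camera_extrinsics}.
#' @export
camera_extrinsics <- function(rotation_GC, position_m = c(0, 0, 0),
                              label = "F") {
  .check_rotation(rotation_GC, "rotation_GC")
  structure(list(label = label, rotation_GC = rotation_GC,
                 position_m = as.numeric(position_m)),
            class = "camera_extrinsics")
}

#' Read and write extrinsics JSON
#'
#' Schema: \code{{"label": "F", "rotation_row_major": [9 floats],
#' "position_m": [3 floats]}}.
#'
#' @param path file path.
#' @return \code{read_extrinsics_json}: a \code{camera_extrinsics}.
#' @export
read_extrinsics_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_extrinsics(matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                    j$position_m, j$label)
}

#' @rdname read_extrinsics_json
#' @param x a \code{camera_extrinsics}.
#' @export
write_extrinsics_json <- function(x, path) {
  jsonlite::write_json(list(label = x$label,
                            rotation_row_major = as.vector(t(x$rotation_GC)),
                            position_m = x$position_m),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-express a camera-frame sequence in the global frame
#'
#' Left-multiplies every rotation by the camera-to-global extrinsic
#' rotation: \code{R_HG = R_GC R_HC}.
#'
#' @param seq a \code{rotseq} whose frame label starts with "C".
#' @param cam a \code{camera_extrinsics}; when \code{seq$frame} carries a
#'   camera label ("C:F"), it must match \code{cam$label}.
#' @return a \code{rotseq} in frame "G".
#' @export
camera_to_global <- function(seq, cam) {
  stopifnot(inherits(seq, "rotseq"), inherits(cam, "camera_extrinsics"))
  if (!startsWith(seq$frame, "C")) {
    stop("sequence frame is '", seq$frame, "', expected a camera frame",
         call. = FALSE)
  }
  cam_tag <- sub("^C:?", "", seq$frame)
  if (nzchar(cam_tag) && cam_tag != cam$label) {
    stop("sequence is in camera frame '", cam_tag, "' but extrinsics are ",
         "for camera '", cam$label, "'", call. = FALSE)
  }
  out <- seq
  for (i in seq_len(length(seq))) {
    out$R[, , i] <- cam$rotation_GC %*% seq$R[, , i]
  }
  out$frame <- "G"
  out
}

#' Framewise relative errors
#'
#' \code{delta_i = t(predicted_i) \%*\% reference_i} for each frame; the
#' inputs for the Karcher-mean offset estimate.
#'
#' @param reference,predicted \code{rotseq} objects of equal length with
#'   matching times, both in the global frame.
#' @return 3x3xN array of rotations.
#' @export
framewise_relative_errors <- function(reference, predicted) {
  .check_matched(reference, predicted)
  n <- length(reference)
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    out[, , i] <- crossprod(predicted$R[, , i], reference$R[, , i])
  }
  out
}

.check_matched <- function(reference, predicted) {
  stopifnot(inherits(reference, "rotseq"), inherits(predicted, "rotseq"))
  if (length(reference) != length(predicted)) {
    stop("sequences have different lengths (", length(reference), " vs ",
         length(predicted), ")", call. = FALSE)
  }
  if (any(abs(reference$t_ms - predicted$t_ms) > 1e-6)) {
    stop("sequence timestamps do not match", call. = FALSE)
  }
  invisible(TRUE)
}

#' Karcher mean on SO(3)
#'
#' Iterative log-exp averaging: starting from the first element, iterate
#' \code{mu <- mu \%*\% rot_exp(mean_i rot_log(t(mu) \%*\% R_i))} until the
#' tangent-mean norm drops below \code{tol}. The returned point is a
#' stationary point of the sum of squared geodesic distances. Inputs must
#' lie within a geodesic ball of radius pi/2 of their (projected) chordal
#' mean, where the mean is unique.
#'
#' @param rotations 3x3xN array or list of rotation matrices (non-empty).
#' @param tol convergence tolerance on the tangent-mean norm, radians.
#' @param max_iter maximum iterations.
#' @return list with \code{mean} (3x3), \code{iterations},
#'   \code{final_step_norm} and \code{converged}.
#' @export
karcher_mean <- function(rotations, tol = 1e-9, max_iter = 100L) {
  if (is.list(rotations)) rotations <- simplify2array(rotations)
  if (is.matrix(rotations)) rotations <- array(rotations, c(3, 3, 1))
  n <- dim(rotations)[3]
  if (is.na(n) || n < 1L) stop("empty rotation set", call. = FALSE)
  # dispersion guard: distances from the projected chordal mean
  chordal <- project_rotation(apply(rotations, c(1, 2), mean))
  dmax <- max(vapply(seq_len(n),
                     function(i) rot_dist(chordal, rotations[, , i]), 0))
  if (dmax >= pi / 2) {
    stop("rotation set too dispersed (radius ", signif(dmax, 3),
         " rad >= pi/2): Karcher mean not unique", call. = FALSE)
  }
  mu <- rotations[, , 1]
  step <- Inf
  for (it in seq_len(max_iter)) {
    v <- rowMeans(vapply(seq_len(n), function(i) {
      rot_log(crossprod(mu, rotations[, , i]))
    }, numeric(3)))
    step <- sqrt(sum(v^2))
    if (step < tol) {
      return(list(mean = mu, iterations = it, final_step_norm = step,
                  converged = TRUE))
    }
    mu <- project_rotation(mu %*% rot_exp(v))
  }
  stop("Karcher mean did not converge in ", max_iter,
       " iterations (last step ", signif(step, 3), " rad)", call. = FALSE)
}

#' Estimate and remove the constant anatomical offset
#'
#' The package's central estimator. Given matched reference and predicted
#' sequences in the global frame, the framewise relative errors
#' \code{delta_i = t(predicted_i) reference_i} are averaged on SO(3) by the
#' Karcher mean, and the aligned predictions
#' \code{aligned_i = predicted_i \%*\% Delta} cancel the constant offset: if
#' \code{predicted_i = reference_i \%*\% D} for a fixed anatomical offset D,
#' the aligned sequence reproduces the reference exactly. One alignment
#' rotation is estimated per trial-camera sequence.
#'
#' @param reference,predicted \code{rotseq} objects, equal length, matching
#'   times, global frame.
#' @param tol,max_iter passed to \code{karcher_mean}.
#' @return an object of class \code{pose_alignment}: a list with the
#'   estimated offset \code{delta} (3x3), \code{framewise_errors}
#'   (3x3xN array of delta_i), the \code{aligned} sequence, per-frame
#'   geodesic errors before/after alignment (degrees), and convergence
#'   diagnostics. Methods: \code{print}, \code{summary}, \code{coef}
#'   (axis-angle of the offset), \code{predict} (apply the offset to a new
#'   sequence), \code{residuals}, \code{plot}.
#' @export
fit_alignment <- function(reference, predicted, tol = 1e-9,
                          max_iter = 100L) {
  .check_matched(reference, predicted)
  deltas <- framewise_relative_errors(reference, predicted)
  km <- karcher_mean(deltas, tol = tol, max_iter = max_iter)
  n <- length(reference)
  aligned <- predicted
  for (i in seq_len(n)) {
    aligned$R[, , i] <- project_rotation(predicted$R[, , i] %*% km$mean)
  }
  ge_before <- vapply(seq_len(n), function(i) {
    rot_dist(reference$R[, , i], predicted$R[, , i])
  }, 0) * 180 / pi
  ge_after <- vapply(seq_len(n), function(i) {
    rot_dist(reference$R[, , i], aligned$R[, , i])
  }, 0) * 180 / pi
  structure(list(delta = km$mean, framewise_errors = deltas,
                 aligned = aligned, reference = reference,
                 predicted = predicted, ge_before_deg = ge_before,
                 ge_after_deg = ge_after, iterations = km$iterations,
                 final_step_norm = km$final_step_norm,
                 converged = km$converged, tol = tol),
            class = "pose_alignment")
}

#' @export
print.pose_alignment <- function(x, ...) {
  aa <- rot_log(x$delta)
  ang <- sqrt(sum(aa^2)) * 180 / pi
  cat("Anatomical alignment (Karcher mean of framewise relative errors)\n")
  cat(sprintf("  offset: %.3f deg about axis (%.3f, %.3f, %.3f)\n", ang,
              if (ang > 0) aa[1] / sqrt(sum(aa^2)) else 0,
              if (ang > 0) aa[2] / sqrt(sum(aa^2)) else 0,
              if (ang > 0) aa[3] / sqrt(sum(aa^2)) else 1))
  cat(sprintf("  frames: %d; mean GE %.3f -> %.3f deg; %d iterations\n",
              length(x$reference), mean(x$ge_before_deg),
              mean(x$ge_after_deg), x$iterations))
  invisible(x)
}

#' @export
summary.pose_alignment <- function(object, ...) {
  out <- list(
    offset_deg = sqrt(sum(rot_log(object$delta)^2)) * 180 / pi,
    offset_axis_angle = rot_log(object$delta),
    n = length(object$reference),
    mean_ge_before_deg = mean(object$ge_before_deg),
    mean_ge_after_deg = mean(object$ge_after_deg),
    median_ge_after_deg = stats::median(object$ge_after_deg),
    iterations = object$iterations,
    converged = object$converged
  )
  class(out) <- "summary.pose_alignment"
  out
}

#' @export
print.summary.pose_alignment <- function(x, ...) {
  cat(sprintf("Alignment offset %.3f deg (n = %d)\n", x$offset_deg, x$n))
  cat(sprintf("  mean GE before %.3f deg, after %.3f deg (median %.3f)\n",
              x$mean_ge_before_deg, x$mean_ge_after_deg,
              x$median_ge_after_deg))
  cat(sprintf("  converged: %s in %d iterations\n", x$converged,
              x$iterations))
  invisible(x)
}

#' @export
coef.pose_alignment <- function(object, ...) {
  v <- rot_log(object$delta)
  c(axis_angle_x = v[1], axis_angle_y = v[2], axis_angle_z = v[3],
    angle_deg = sqrt(sum(v^2)) * 180 / pi)
}

#' @export
residuals.pose_alignment <- function(object, ...) object$ge_after_deg

#' Apply a fitted alignment to a sequence
#'
#' @param object a \code{pose_alignment}.
#' @param newdata a \code{rotseq} of predictions in the global frame;
#'   defaults to the sequence the alignment was fitted to.
#' @param ... ignored.
#' @return aligned \code{rotseq}.
#' @export
predict.pose_alignment <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$aligned)
  stopifnot(inherits(newdata, "rotseq"))
  out <- newdata
  for (i in seq_len(length(newdata))) {
    out$R[, , i] <- project_rotation(newdata$R[, , i] %*% object$delta)
  }
  out
}

#' @export
plot.pose_alignment <- function(x, ...) {
  t <- x$reference$t_ms
  graphics::plot(t, x$ge_before_deg, type = "b", pch = 1,
                 ylim = c(0, max(x$ge_before_deg, x$ge_after_deg, 1)),
                 xlab = "time (ms)", ylab = "geodesic error (deg)", ...)
  graphics::lines(t, x$ge_after_deg, type = "b", pch = 16)
  graphics::legend("topright", c("before alignment", "after alignment"),
                   pch = c(1, 16), lty = 1, bty = "n")
  invisible(x)
}

#' Serialise an alignment result to JSON
#'
#' Writes the estimated offset (row-major matrix and axis-angle), the
#' per-frame error summary and convergence diagnostics.
#'
#' @param x a \code{pose_alignment}.
#' @param path output path.
#' @export
write_alignment_json <- function(x, path) {
  v <- rot_log(x$delta)
  jsonlite::write_json(list(
    delta_row_major = as.vector(t(x$delta)),
    delta_axis_angle_rad = v,
    delta_angle_deg = sqrt(sum(v^2)) * 180 / pi,
    n = length(x$reference),
    mean_ge_before_deg = mean(x$ge_before_deg),
    mean_ge_after_deg = mean(x$ge_after_deg),
    iterations = x$iterations,
    final_step_norm = x$final_step_norm,
    converged = x$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
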