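#' Geodesic pose-error metrics
#'
#' Accuracy is measured on the rotation group itself, avoiding the
#' convention- and gimbal-lock sensitivity of Euler-angle errors. The
#' geodesic error (GE) is the minimal angle separating reference and
#' predicted orientations at a frame. The incremental geodesic error (IGE)
#' compares frame-to-frame rotational change between the two sequences:
#' the angles of the consecutive-frame relative rotations are computed in
#' each sequence and their absolute difference is taken, which makes IGE
#' blind to any constant offset and hence to the alignment step.
#'
#' @name metrics
#' @keywords internal
NULL

#' Per-frame geodesic error
#'
#' @param reference,predicted matched \code{rotseq}s.
#' @return data.frame with \code{t_ms} and \code{ge_deg}.
#' @export
geodesic_error_series <- function(reference, predicted) {
  .check_matched(reference, predicted)
  n <- length(reference)
  ge <- vapply(seq_len(n), function(i) {
    rot_dist(reference$R[, , i], predicted$R[, , i])
  }, 0) * 180 / pi
  data.frame(t_ms = reference$t_ms, ge_deg = ge)
}

#' Per-pair incremental geodesic error
#'
#' For i = 2..N the angle of \code{t(R[i-1]) R[i]} is computed in each
#' sequence and \code{ige = |angle_ref - angle_pred|} reported at the time
#' of the later frame.
#'
#' @param reference,predicted matched \code{rotseq}s of length >= 2.
#' @return data.frame with \code{t_ms} (later frame of each pair) and
#'   \code{ige_deg}, length N-1.
#' @export
incremental_geodesic_error_series <- function(reference, predicted) {
  .check_matched(reference, predicted)
  if (length(reference) < 2L) {
    stop("incremental errors need at least 2 frames", call. = FALSE)
  }
  ir <- increment_series(reference)
  ip <- increment_series(predicted)
  data.frame(t_ms = ir$t_ms, ige_deg = abs(ir$increment_deg - ip$increment_deg))
}

#' Rotation-magnitude and increment series
#'
#' \code{magnitude_series} returns the per-frame rotation magnitude
#' d(R, I); \code{increment_series} the per-pair frame-to-frame angular
#' displacement d(R[i-1], R[i]). Both in degrees; these are the quantities
#' shown in frame-wise agreement (scatter and Bland-Altman) analyses.
#'
#' @param seq a \code{rotseq}.
#' @return data.frame (\code{t_ms}, \code{magnitude_deg}) or
#'   (\code{t_ms}, \code{increment_deg}).
#' @export
magnitude_series <- function(seq) {
  stopifnot(inherits(seq, "rotseq"))
  m <- vapply(seq_len(length(seq)), function(i) rot_angle(seq$R[, , i]),
              0) * 180 / pi
  data.frame(t_ms = seq$t_ms, magnitude_deg = m)
}

#' @rdname magnitude_series
#' @export
increment_series <- function(seq) {
  stopifnot(inherits(seq, "rotseq"))
  n <- length(seq)
  if (n < 2L) stop("increments need at least 2 frames", call. = FALSE)
  inc <- vapply(2:n, function(i) {
    rot_dist(seq$R[, , i - 1], seq$R[, , i])
  }, 0) * 180 / pi
  data.frame(t_ms = seq$t_ms[-1], increment_deg = inc)
}

#' Build a long-format error table for one trial
#'
#' One row per frame: geodesic error, incremental error (NA at the first
#' frame), and per-frame metadata for downstream grouping. This is the
#' schema of the pipeline's long errors CSV:
#' \code{participant,trial,trial_type,camera,model,frame,t_ms,ge_deg,
#' ige_deg,visibility}.
#'
#' @param reference,predicted matched \code{rotseq}s.
#' @param participant,trial,trial_type,camera,model grouping labels.
#' @param visibility optional per-frame visibility ratios.
#' @return data.frame.
#' @export
error_table <- function(reference, predicted, participant = NA, trial = NA,
                        trial_type = NA, camera = NA, model = NA,
                        visibility = NULL) {
  ge <- geodesic_error_series(reference, predicted)
  n <- nrow(ge)
  ige <- rep(NA_real_, n)
  if (n >= 2) {
    ige[-1] <- incremental_geodesic_error_series(reference,
                                                 predicted)$ige_deg
  }
  data.frame(participant = participant, trial = trial,
             trial_type = trial_type, camera = camera, model = model,
             frame = seq_len(n) - 1L, t_ms = ge$t_ms, ge_deg = ge$ge_deg,
             ige_deg = ige,
             visibility = if (is.null(visibility)) NA_real_ else visibility)
}

#' Summarise pooled errors by group
#'
#' Pools frames (not per-trial means of means) and reports mean and median
#' GE and IGE per group, with frame counts. Empty groups are dropped with a
#' warning.
#'
#' @param errors long-format error data.frame (as from \code{error_table},
#'   possibly row-bound over trials).
#' @param by character vector of grouping column names (default "model").
#' @return data.frame with one row per group: grouping columns,
#'   \code{n_frames}, \code{mean_ge_deg}, \code{median_ge_deg},
#'   \code{n_increments}, \code{mean_ige_deg}, \code{median_ige_deg}.
#' @export
summarize_errors <- function(errors, by = "model") {
  stopifnot(nrow(errors) > 0, all(by %in% names(errors)))
  key <- interaction(errors[by], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    e <- errors[key == k, , drop = FALSE]
    if (!nrow(e)) {
      warning("empty group '", k, "' omitted", call. = FALSE)
      return(NULL)
    }
    ige <- e$ige_deg[!is.na(e$ige_deg)]
    cbind(e[1, by, drop = FALSE],
          data.frame(n_frames = nrow(e),
                     mean_ge_deg = mean(e$ge_deg),
                     median_ge_deg = stats::median(e$ge_deg),
                     n_increments = length(ige),
                     mean_ige_deg = if (length(ige)) mean(ige) else NA_real_,
                     median_ige_deg = if (length(ige)) stats::median(ige)
                                      else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
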