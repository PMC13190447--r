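#' Synthetic heading-trial generator
#'
#' The participant dataset behind this validation design is not publicly
#' available, so the package ships a generator that emulates its structure
#' end to end: ten participants each performing ten football headers (five
#' linear, five rotational), observed by a frontal and a side 50 Hz video
#' camera and 1000 Hz motion capture; a 100 ms analysis window (20 ms
#' pre-, 80 ms post-impact) holding six video frames and 100 motion-capture
#' frames; head excursions peaking at 22-36 degrees from neutral (with an
#' additional yaw ramp for rotational headers); a constant anatomical-axis
#' offset between each model profile's predictions and the reference frame;
#' and visibility-dependent prediction noise with an occlusion dip around
#' ball contact. Every draw is fixed by the config seed, so each pipeline
#' stage has an exact parameter-recovery target.
#'
#' @name synthetic
#' @keywords internal
NULL

# canonical head-frame marker geometry (mm): EAM/IOR coplanar in z = 0, the
# Frankfort plane of the synthetic head; invented defaults, config-overridable
.DEFAULT_MARKER_GEOMETRY <- rbind(
  EAM_L = c(0, 70, 0),
  EAM_R = c(0, -70, 0),
  IOR_L = c(75, 35, 0),
  IOR_R = c(75, -35, 0),
  SNA   = c(85, 0, 15)
)

#' Built-in model noise profiles
#'
#' Three prediction-noise profiles spanning the behaviours of head-pose
#' model families: two face-driven profiles whose error grows steeply as
#' the face is occluded (high and moderate visibility sensitivity sigma1)
#' and one body-context profile with low baseline noise and a nearly flat
#' visibility response. \code{sigma0_deg} is the per-axis tangent noise at
#' full visibility, \code{sigma1_deg} the additional noise at zero
#' visibility; \code{sigma_frames} the reference smoothing width.
#'
#' @return data.frame with columns profile, sigma0_deg, sigma1_deg,
#'   sigma_frames.
#' @export
model_profiles <- function() {
  data.frame(profile = c("face_high", "face_moderate", "body_low"),
             sigma0_deg = c(2, 2.5, 2.5),
             sigma1_deg = c(25, 12, 1.5),
             sigma_frames = c(1.5, 1.5, 0.5))
}

#' Simulation configuration
#'
#' Defaults reproduce the study design: 10 participants x (5 linear + 5
#' rotational) headers x 2 cameras; 1000 Hz motion capture and 50 Hz video;
#' impact at 100 ms of a 300 ms recording; a 20/80 ms window; flexion
#' amplitude drawn from 22-36 degrees; a 45-degree yaw ramp on rotational
#' trials; a constant 15-degree anatomical offset per model profile; and an
#' occlusion dip of depth 0.7 (about 40 ms wide, asymmetric: fast onset as
#' the ball arrives, slower recovery as ball and arms clear the face).
#'
#' @param n_participants number of participants.
#' @param trials_per_type headers per trial type per participant.
#' @param impact_ms impact time within the recording.
#' @param pre_ms,post_ms analysis window extent, ms.
#' @param recording_ms total recording length, ms.
#' @param mocap_rate,video_rate sampling rates, Hz.
#' @param pitch_amplitude_deg range (lo, hi) of the flexion peak, degrees.
#' @param yaw_amplitude_R_deg yaw ramp target for rotational trials.
#' @param roll_amplitude_deg small roll amplitude.
#' @param offset_angle_deg anatomical offset magnitude per model profile.
#' @param occlusion_depth reference fractional dip of visible face area at
#'   the impact frame.
#' @param occlusion_jitter range of the uniform per-trial multiplier on
#'   the dip depth; the default c(0, 1.3) spans barely-occluded to deeply
#'   occluded headers (product clamped at 0.95), matching the wide
#'   trial-to-trial spread of observed visibility.
#' @param occlusion_width_ms recovery half-width of the dip.
#' @param marker_noise_mm isotropic marker noise, mm.
#' @param image_size video image extent, pixels.
#' @param profiles model-profile table (see \code{model_profiles}).
#' @param seed integer seed fixing every draw.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_participants = 10L, trials_per_type = 5L,
                       impact_ms = 100, pre_ms = 20, post_ms = 80,
                       recording_ms = 300, mocap_rate = 1000,
                       video_rate = 50,
                       pitch_amplitude_deg = c(22, 36),
                       yaw_amplitude_R_deg = 45, roll_amplitude_deg = 2,
                       offset_angle_deg = 15, occlusion_depth = 0.7,
                       occlusion_jitter = c(0, 1.3),
                       occlusion_width_ms = 40, marker_noise_mm = 0.3,
                       image_size = c(1280, 720),
                       profiles = model_profiles(), seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_type >= 1,
            occlusion_depth >= 0, occlusion_depth <= 1,
            all(pitch_amplitude_deg >= 0), yaw_amplitude_R_deg >= 0,
            marker_noise_mm >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Default camera extrinsics of the synthetic capture volume
#'
#' Frontal camera at (5.0, -0.4, 2.6) m and side camera at
#' (-0.1, 3.0, 0.9) m; the side camera's orientation is a 90-degree yaw
#' offset from the front.
#'
#' @return named list of \code{camera_extrinsics} ("F", "S").
#' @export
default_extrinsics <- function() {
  RF <- rot_z(180)
  list(F = camera_extrinsics(RF, c(5.0, -0.4, 2.6), "F"),
       S = camera_extrinsics(rot_z(-90) %*% RF, c(-0.1, 3.0, 0.9), "S"))
}

# C2 bump: zero value/slope/curvature at |u| = 1, unit peak at u = 0
.bump <- function(u) {
  ifelse(abs(u) < 1, (0.5 * (1 + cos(pi * u)))^2, 0)
}

# C2 smoothstep on [0, 1]
.smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Generate a ground-truth head-orientation recording
#'
#' Pitch is a flexion pulse (squared raised cosine, peaking 40 ms after
#' impact) with amplitude drawn uniformly from the configured range;
#' rotational (R) trials add a smooth yaw ramp reaching the configured
#' amplitude by the window end; a small smooth roll completes the motion.
#' Angles are composed via the package's display Euler convention
#' (intrinsic z-y'-x'') into rotation matrices at the motion-capture rate.
#'
#' @param config a \code{sim_config}.
#' @param trial_type "L" or "R".
#' @return a \code{rotseq} in frame "G" covering the full recording, with
#'   attributes \code{pitch_amplitude_deg} and \code{impact_ms}.
#' @export
generate_ground_truth <- function(config, trial_type = c("L", "R")) {
  trial_type <- match.arg(trial_type)
  dt <- 1000 / config$mocap_rate
  t <- seq(0, config$recording_ms - dt, by = dt)
  amp <- stats::runif(1, config$pitch_amplitude_deg[1],
                      config$pitch_amplitude_deg[2])
  pitch <- amp * .bump((t - (config$impact_ms + 40)) / 120)
  yaw <- if (trial_type == "R") {
    config$yaw_amplitude_R_deg *
      .smoothstep((t - (config$impact_ms - config$pre_ms)) /
                  (config$pre_ms + config$post_ms))
  } else {
    1.5 * .bump((t - (config$impact_ms + 60)) / 150)
  }
  roll <- config$roll_amplitude_deg *
    .bump((t - (config$impact_ms - 10)) / 160)
  n <- length(t)
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    R[, , i] <- rotation_from_euler(yaw[i], pitch[i], roll[i])
  }
  out <- rotseq(R, t, frame = "G", rate = config$mocap_rate, check = FALSE)
  attr(out, "pitch_amplitude_deg") <- amp
  attr(out, "impact_ms") <- config$impact_ms
  out
}

#' Generate marker trajectories from a reference sequence
#'
#' The canonical head-frame marker geometry is rotated by each frame's
#' orientation, translated along a smooth forward head path, and
#' perturbed with isotropic Gaussian noise.
#'
#' @param reference a \code{rotseq} (global frame).
#' @param config a \code{sim_config}.
#' @param geometry marker geometry matrix (rows EAM_L, EAM_R, IOR_L,
#'   IOR_R, SNA; head-frame mm).
#' @return marker data.frame (t_ms + \code{<label>_{x,y,z}}).
#' @export
generate_markers <- function(reference, config,
                             geometry = .DEFAULT_MARKER_GEOMETRY) {
  n <- length(reference)
  t <- reference$t_ms
  path <- cbind(300 * .smoothstep(t / max(t[n], 1)), 0 * t, 1700 + 0 * t)
  out <- data.frame(t_ms = t)
  pos <- array(0, c(n, 3, nrow(geometry)))
  for (i in seq_len(n)) {
    P <- reference$R[, , i] %*% t(geometry)  # 3 x nmark
    pos[i, , ] <- P + path[i, ]
  }
  if (config$marker_noise_mm > 0) {
    pos <- pos + stats::rnorm(length(pos), sd = config$marker_noise_mm)
  }
  for (k in seq_len(nrow(geometry))) {
    lab <- rownames(geometry)[k]
    out[[paste0(lab, "_x")]] <- pos[, 1, k]
    out[[paste0(lab, "_y")]] <- pos[, 2, k]
    out[[paste0(lab, "_z")]] <- pos[, 3, k]
  }
  out
}

# intended raw visibility (fraction of face area visible) per video frame
.visibility_profile <- function(config, trial_type, camera, yaw_deg,
                                depth) {
  t <- (seq_len(6L) - 2L) * 1000 / config$video_rate  # -20 .. 80 rel impact
  w_on <- config$occlusion_width_ms / 2
  w_off <- config$occlusion_width_ms
  g <- ifelse(t < 0, .bump(t / w_on), .bump(t / (2 * w_off)))
  g <- ifelse(abs(t) < 1e-9, 1, g)
  base <- pmin(1, pmax(0.9, 1 - abs(stats::rnorm(6, sd = 0.02))))
  # occlusion severity is largely a property of the whole header: the ball
  # approach path, arm carriage and camera angle that produce a deep dip
  # at contact also obstruct the face throughout the window, so the
  # baseline level is tied to the dip depth; per-frame arm/hand flutter
  # adds small independent variation
  trial_base <- max(0.35, 1 - 0.55 * depth - stats::runif(1, 0, 0.1))
  arms <- stats::runif(6, 0.85, 1)
  v <- base * trial_base * arms * (1 - depth * g)
  if (camera == "S") v <- v * pmax(0.05, cos(yaw_deg * pi / 180)^2)
  pmin(1, pmax(0, v))
}

#' Generate per-frame visibility and annotation boxes
#'
#' Visibility follows a baseline near 1 with an asymmetric occlusion dip
#' centred at the impact frame (depth jittered per trial around the
#' configured value); the side camera additionally loses visible area as
#' the head yaws away (self-occlusion, affecting rotational trials most).
#' Each frame is realised as a fixed-size face box partially covered by an
#' occluder box of matching area fraction, plus a ground-truth head box
#' and a jittered synthetic detection, so that the visibility and
#' detection analyses can run on the emitted boxes alone.
#'
#' @param config a \code{sim_config}.
#' @param trial_type "L" or "R".
#' @param camera "F" or "S".
#' @param yaw_deg per-video-frame reference yaw, degrees (length 6).
#' @return list with \code{visibility_raw} (fraction of face area visible
#'   per frame, before per-camera normalisation) and \code{boxes} (a box
#'   set in the boxes-JSON layout).
#' @export
generate_visibility <- function(config, trial_type, camera, yaw_deg) {
  jit <- config$occlusion_jitter
  if (is.null(jit)) jit <- c(0, 1.3)
  depth <- min(0.95, config$occlusion_depth *
                       stats::runif(1, jit[1], jit[2]))
  v <- .visibility_profile(config, trial_type, camera, yaw_deg, depth)
  face <- c(580, 190, 120, 140)
  frames <- lapply(seq_len(6L), function(k) {
    covered <- 1 - v[k]
    occl <- if (covered > 1e-9) {
      list(c(face[1], face[2], face[3] * covered, face[4]))
    } else list()
    det <- face + c(stats::rnorm(2, sd = 6), stats::rnorm(2, sd = 4))
    det[3:4] <- pmax(det[3:4], 10)
    list(frame = k - 1L, face = face, occluders = occl,
         detections = list(det), ground_truth = list(face))
  })
  list(visibility_raw = v,
       boxes = list(camera = camera, image_size = config$image_size,
                    frames = frames))
}

#' Generate noisy model predictions in the camera frame
#'
#' \code{predicted_i = t(R_GC) (reference_i D exp(e_i))} with D the
#' profile's constant anatomical offset and \code{e_i} right-composed
#' (body-frame) tangent noise with two components: an iid baseline of
#' per-axis standard deviation \code{sigma0} degrees, and an
#' occlusion-driven component of per-axis standard deviation
#' \code{sigma1 (1 - v_i)} degrees whose direction follows a standardised
#' AR(1) process across frames (coefficient \code{ar}). The correlation
#' mimics how face-driven estimators fail coherently while an occluder
#' passes: consecutive occluded frames are wrong in a similar, drifting
#' way rather than independently. With \code{sigma1 = 0} the noise is
#' exactly iid, so the chi-3 closed form for the mean geodesic error
#' applies. The output is camera-frame: consumers must re-express it in
#' the global frame before alignment.
#'
#' @param reference_video 6-frame \code{rotseq} in frame "G".
#' @param visibility per-frame visibility ratios in [0, 1].
#' @param offset constant offset rotation D.
#' @param extrinsics a \code{camera_extrinsics}.
#' @param sigma0_deg,sigma1_deg noise model, degrees.
#' @param ar optional lag-one correlation of the occlusion noise
#'   component (default 0: iid).
#' @return \code{rotseq} in frame \code{"C:<label>"}.
#' @export
generate_predictions <- function(reference_video, visibility, offset,
                                 extrinsics, sigma0_deg = 2,
                                 sigma1_deg = 6, ar = 0) {
  stopifnot(inherits(reference_video, "rotseq"),
            length(visibility) == length(reference_video),
            ar >= 0, ar < 1)
  n <- length(reference_video)
  out <- reference_video
  RtGC <- t(extrinsics$rotation_GC)
  # standardised AR(1) innovation sequence, unit marginal variance per axis
  z <- matrix(0, 3, n)
  z[, 1] <- stats::rnorm(3)
  if (n > 1) {
    for (i in 2:n) {
      z[, i] <- ar * z[, i - 1] + sqrt(1 - ar^2) * stats::rnorm(3)
    }
  }
  for (i in seq_len(n)) {
    e <- stats::rnorm(3, sd = sigma0_deg * pi / 180) +
      z[, i] * sigma1_deg * (1 - visibility[i]) * pi / 180
    out$R[, , i] <- RtGC %*% reference_video$R[, , i] %*% offset %*%
      rot_exp(e)
  }
  out$frame <- paste0("C:", extrinsics$label)
  out$rate <- reference_video$rate
  out
}

#' Generate a complete synthetic dataset
#'
#' Deterministic under \code{config$seed}. Returns one record per
#' participant x trial x camera with the windowed 1000 Hz reference, the
#' six-frame video-rate reference, per-profile camera-frame predictions,
#' marker trajectories, boxes and raw visibility, plus a truth manifest
#' (per-profile offsets, per-trial amplitudes and noise parameters). With
#' \code{dir} set, every pipeline input file is also written: marker TSVs,
#' rotation CSVs, boxes JSONs, extrinsics JSONs and
#' \code{truth_manifest.json}.
#'
#' @param config a \code{sim_config}.
#' @param dir optional output directory (created if missing).
#' @param markers also generate marker trajectories (default TRUE).
#' @return list with \code{records}, \code{manifest}, \code{extrinsics}.
#' @export
generate_dataset <- function(config = sim_config(), dir = NULL,
                             markers = TRUE) {
  set.seed(config$seed)
  ext <- default_extrinsics()
  prof <- config$profiles
  offsets <- lapply(seq_len(nrow(prof)), function(i) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    rot_exp(ax * config$offset_angle_deg * pi / 180)
  })
  names(offsets) <- prof$profile
  records <- list()
  trial_meta <- list()
  fmap <- map_video_frames(
    n_mocap = as.integer((config$pre_ms + config$post_ms) *
                           config$mocap_rate / 1000),
    mocap_rate = config$mocap_rate, video_rate = config$video_rate,
    n_frames = 6L)
  for (p in seq_len(config$n_participants)) {
    trial_no <- 0L
    for (ttype in c("L", "R")) {
      for (rep in seq_len(config$trials_per_type)) {
        trial_no <- trial_no + 1L
        full <- generate_ground_truth(config, ttype)
        refwin <- extract_impact_window(full, config$impact_ms,
                                        config$pre_ms, config$post_ms)
        ref_video <- refwin[fmap$mocap_index]
        ref_video$t_ms <- fmap$t_ms
        ref_video$rate <- config$video_rate
        mk <- if (markers) generate_markers(refwin, config) else NULL
        yaw_deg <- as.data.frame(ref_video)$yaw
        trial_meta[[length(trial_meta) + 1L]] <- list(
          participant = p, trial = trial_no, trial_type = ttype,
          pitch_amplitude_deg = attr(full, "pitch_amplitude_deg"))
        for (cam in c("F", "S")) {
          vis <- generate_visibility(config, ttype, cam, yaw_deg)
          preds <- lapply(seq_len(nrow(prof)), function(i) {
            generate_predictions(ref_video, vis$visibility_raw,
                                 offsets[[i]], ext[[cam]],
                                 prof$sigma0_deg[i], prof$sigma1_deg[i])
          })
          names(preds) <- prof$profile
          records[[length(records) + 1L]] <- list(
            participant = p, trial = trial_no, trial_type = ttype,
            camera = cam, reference = refwin, reference_video = ref_video,
            predictions = preds, markers = mk,
            visibility_raw = vis$visibility_raw, boxes = vis$boxes)
        }
      }
    }
  }
  manifest <- list(
    seed = config$seed,
    n_records = length(records),
    design = list(n_participants = config$n_participants,
                  trials_per_type = config$trials_per_type,
                  cameras = c("F", "S")),
    offsets = lapply(names(offsets), function(nm) {
      v <- rot_log(offsets[[nm]])
      list(profile = nm, axis_angle_rad = v,
           angle_deg = sqrt(sum(v^2)) * 180 / pi)
    }),
    profiles = prof,
    noise = list(occlusion_depth = config$occlusion_depth,
                 occlusion_width_ms = config$occlusion_width_ms,
                 marker_noise_mm = config$marker_noise_mm),
    trials = trial_meta)
  out <- list(records = records, manifest = manifest, extrinsics = ext,
              offsets = offsets)
  if (!is.null(dir)) .write_dataset(out, config, dir)
  out
}

.write_dataset <- function(ds, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cam in names(ds$extrinsics)) {
    write_extrinsics_json(ds$extrinsics[[cam]],
                          file.path(dir, paste0("extrinsics_", cam,
                                                ".json")))
  }
  for (rec in ds$records) {
    stem <- sprintf("p%02d_t%02d_%s_%s", rec$participant, rec$trial,
                    rec$trial_type, rec$camera)
    write_rotation_csv(rec$reference_video,
                       file.path(dir, paste0(stem, "_reference.csv")))
    for (nm in names(rec$predictions)) {
      write_rotation_csv(rec$predictions[[nm]],
                         file.path(dir, paste0(stem, "_pred_", nm, ".csv")))
    }
    write_boxes_json(rec$boxes, file.path(dir, paste0(stem, "_boxes.json")))
    if (!is.null(rec$markers) && rec$camera == "F") {
      write_marker_tsv(rec$markers,
                       file.path(dir, sprintf("p%02d_t%02d_%s_markers.tsv",
                                              rec$participant, rec$trial,
                                              rec$trial_type)))
    }
  }
  jsonlite::write_json(ds$manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
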