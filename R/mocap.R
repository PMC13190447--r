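#' Marker processing: filtering, cutoff selection, anatomical frames
#'
#' Reference head orientation is built from a five-marker set on skeletal
#' landmarks: left/right external auditory meatus (EAM_L, EAM_R), left/right
#' inferior orbital rim (IOR_L, IOR_R) and the nasion (SNA). The EAM and IOR
#' markers define the Frankfort plane, the anatomical horizontal of the
#' head; the anatomical coordinate system (ACS) has its origin midway
#' between the EAMs, y pointing left, z perpendicular to the Frankfort plane
#' (superior) and x anterior along the plane.
#'
#' @name mocap
#' @keywords internal
NULL

MARKER_LABELS <- c("EAM_L", "EAM_R", "IOR_L", "IOR_R", "SNA")

# ---- zero-lag Butterworth -------------------------------------------------

# direct-form II transposed single-pass IIR with given initial state scaling
.iir_filter <- function(b, a, x, zi_unit) {
  n <- length(x)
  nz <- length(b) - 1L
  z <- zi_unit * x[1]
  y <- numeric(n)
  for (t in seq_len(n)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    for (k in seq_len(nz)) {
      z[k] <- if (k < nz) b[k + 1] * xt + z[k + 1] - a[k + 1] * yt
              else        b[k + 1] * xt            - a[k + 1] * yt
    }
    y[t] <- yt
  }
  y
}

# steady-state unit-step initial state (so a constant input passes exactly)
.iir_zi <- function(b, a) {
  nz <- length(b) - 1L
  A <- diag(nz)
  for (k in seq_len(nz)) A[k, 1] <- A[k, 1] + a[k + 1]
  if (nz > 1) for (k in seq_len(nz - 1)) A[k, k + 1] <- A[k, k + 1] - 1
  rhs <- b[-1] - b[1] * a[-1]
  as.numeric(solve(A, rhs))
}

#' Zero-lag Butterworth low-pass filter
#'
#' A net fourth-order zero-phase filter realised as a second-order
#' Butterworth low-pass applied forward and then backward (net order =
#' \code{order}; no cutoff-correction factor is applied). Phase lag cancels
#' exactly. Edges are handled by odd-symmetric signal extension of three
#' filter-order lengths with steady-state initial conditions, so a constant
#' signal is reproduced to machine precision.
#'
#' @param x uniformly sampled numeric series without gaps (NAs).
#' @param cutoff cutoff frequency, Hz (0 < cutoff < rate/2).
#' @param rate sampling rate, Hz.
#' @param order net filter order (even; default 4).
#' @return filtered series, same length as \code{x}.
#' @export
butterworth_zero_lag <- function(x, cutoff, rate, order = 4L) {
  if (anyNA(x)) {
    stop("signal contains gaps (NA); fill gaps first (fill_marker_gaps)",
         call. = FALSE)
  }
  stopifnot(order %% 2 == 0, order >= 2, cutoff > 0, cutoff < rate / 2)
  if (length(x) < 3L * order) {
    stop("signal shorter than 3x filter order", call. = FALSE)
  }
  bf <- signal::butter(order %/% 2, 2 * cutoff / rate, type = "low")
  b <- bf$b; a <- bf$a
  zi <- .iir_zi(b, a)
  npad <- 3L * order
  head_ext <- 2 * x[1] - x[seq(npad + 1, 2)]
  n <- length(x)
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xe <- c(head_ext, x, tail_ext)
  y <- .iir_filter(b, a, xe, zi)
  y <- rev(.iir_filter(b, a, rev(y), zi))
  y[npad + seq_len(n)]
}

#' Cutoff selection by residual analysis
#'
#' Classic residual analysis: for each candidate cutoff the RMS residual
#' between the raw and filtered signal is computed; a straight line is
#' fitted to the high-frequency tail of the residual curve (the upper half
#' of the grid), where the residual is dominated by noise; its
#' zero-frequency intercept estimates the noise RMS; the chosen cutoff is
#' the lowest grid value whose residual does not exceed that intercept.
#'
#' @param x numeric series.
#' @param rate sampling rate, Hz.
#' @param cutoff_grid ascending candidate cutoffs, Hz (>= 4 values).
#' @param order net filter order.
#' @return list with \code{cutoff} (Hz), \code{residuals} (data.frame
#'   cutoff_hz/rms), and \code{intercept} (noise RMS estimate).
#' @export
select_cutoff_residual <- function(x, rate, cutoff_grid, order = 4L) {
  if (length(cutoff_grid) < 4L) {
    stop("cutoff grid must have at least 4 points for the tail line fit",
         call. = FALSE)
  }
  if (is.unsorted(cutoff_grid, strictly = TRUE) ||
      any(cutoff_grid <= 0) || any(cutoff_grid >= rate / 2)) {
    stop("cutoff grid must be strictly ascending within (0, rate/2)",
         call. = FALSE)
  }
  rms <- vapply(cutoff_grid, function(fc) {
    sqrt(mean((x - butterworth_zero_lag(x, fc, rate, order))^2))
  }, 0)
  tail_idx <- seq(ceiling(length(cutoff_grid) / 2) + 1L, length(cutoff_grid))
  if (length(tail_idx) < 2L) tail_idx <- seq_along(cutoff_grid)
  fit <- stats::lm(r ~ f, data.frame(f = cutoff_grid[tail_idx],
                                     r = rms[tail_idx]))
  intercept <- max(0, unname(stats::coef(fit)[1]))
  ok <- which(rms <= intercept)
  cutoff <- if (length(ok)) cutoff_grid[min(ok)] else cutoff_grid[length(cutoff_grid)]
  list(cutoff = cutoff,
       residuals = data.frame(cutoff_hz = cutoff_grid, rms = rms),
       intercept = intercept)
}

#' Highest retained frequency by FFT threshold
#'
#' Sanity check on the chosen cutoff: returns the highest frequency whose
#' one-sided FFT magnitude exceeds \code{threshold_fraction} of the peak
#' non-DC magnitude.
#'
#' @param x uniformly sampled series, length >= 64.
#' @param rate sampling rate, Hz.
#' @param threshold_fraction fraction of the peak non-DC magnitude
#'   (default 0.1).
#' @return frequency in Hz.
#' @export
fft_threshold_check <- function(x, rate, threshold_fraction = 0.1) {
  stopifnot(length(x) >= 64L)
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1L)]
  freq <- (seq_len(n %/% 2 + 1L) - 1L) * rate / n
  mag[1] <- 0  # ignore DC
  keep <- mag > threshold_fraction * max(mag)
  if (!any(keep)) return(0)
  max(freq[keep])
}

# ---- anatomical frame -----------------------------------------------------

#' Construct the anatomical coordinate system from one marker frame
#'
#' Origin at the EAM midpoint; y along EAM_R -> EAM_L (pointing left);
#' provisional anterior direction toward the IOR midpoint; z perpendicular
#' to the Frankfort plane (superior); x = y cross z (anterior). The
#' returned rotation maps head-frame coordinates to the global frame
#' (columns are the head axes in global coordinates).
#'
#' @param markers named list or 3-row/3-column matrix-like of marker
#'   positions (mm, global frame) with names EAM_L, EAM_R, IOR_L, IOR_R
#'   (SNA optional, unused here).
#' @return list with \code{origin} (mm) and \code{rotation} (3x3).
#' @export
construct_acs <- function(markers) {
  if (is.matrix(markers)) {
    markers <- stats::setNames(lapply(seq_len(nrow(markers)),
                                      function(i) markers[i, ]),
                               rownames(markers))
  }
  need <- c("EAM_L", "EAM_R", "IOR_L", "IOR_R")
  if (!all(need %in% names(markers))) {
    stop("markers must include ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- lapply(markers[need], as.numeric)
  if (anyNA(unlist(p))) stop("marker positions contain NA", call. = FALSE)
  origin <- (p$EAM_L + p$EAM_R) / 2
  ydir <- p$EAM_L - p$EAM_R
  ny <- sqrt(sum(ydir^2))
  if (ny < 1e-6) stop("EAM markers coincide: degenerate geometry",
                      call. = FALSE)
  y <- ydir / ny
  a <- (p$IOR_L + p$IOR_R) / 2 - origin
  a <- a - sum(a * y) * y  # anterior direction within the Frankfort plane
  na <- sqrt(sum(a^2))
  if (na < 1e-6) stop("IOR midpoint collinear with EAM axis: degenerate ",
                      "geometry", call. = FALSE)
  a <- a / na
  z <- c(a[2] * y[3] - a[3] * y[2],
         a[3] * y[1] - a[1] * y[3],
         a[1] * y[2] - a[2] * y[1])
  z <- z / sqrt(sum(z^2))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  list(origin = origin, rotation = cbind(x, y, z, deparse.level = 0))
}

#' Least-squares rigid fit (orthogonal Procrustes / Kabsch)
#'
#' Finds the rotation and translation minimising the sum of squared
#' distances between \code{R \%*\% reference + t} and \code{observed}, with
#' determinant +1 enforced. Exploits all available markers, making the
#' reference orientation robust to isotropic marker noise and to a missing
#' marker (>= 3 correspondences required).
#'
#' @param reference,observed 3-column matrices of corresponding points
#'   (rows = points), in mm.
#' @return list with \code{rotation}, \code{translation} (mm) and
#'   \code{rmsd} (mm).
#' @export
rigid_fit <- function(reference, observed) {
  reference <- as.matrix(reference); observed <- as.matrix(observed)
  stopifnot(ncol(reference) == 3L, ncol(observed) == 3L,
            nrow(reference) == nrow(observed))
  if (nrow(reference) < 3L) {
    stop("at least 3 point correspondences required", call. = FALSE)
  }
  cr <- colMeans(reference); co <- colMeans(observed)
  A <- sweep(reference, 2, cr); B <- sweep(observed, 2, co)
  if (svd(A)$d[2] < 1e-9 * max(svd(A)$d[1], 1)) {
    stop("reference points are collinear: rigid fit underdetermined",
         call. = FALSE)
  }
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- co - as.numeric(R %*% cr)
  resid <- observed - (A %*% t(R) + matrix(co, nrow(A), 3, byrow = TRUE))
  list(rotation = R, translation = t, rmsd = sqrt(mean(rowSums(resid^2))))
}

# ---- windows and frame mapping -------------------------------------------

#' Extract the impact window
#'
#' Returns the samples with times in the half-open interval
#' \code{[impact_ms - pre_ms, impact_ms + post_ms)}, with times re-expressed
#' relative to the window start. At 1000 Hz the default 20 ms pre- / 80 ms
#' post-impact window yields exactly 100 frames.
#'
#' @param x a \code{rotseq} or a data.frame with a \code{t_ms} column
#'   (marker table).
#' @param impact_ms impact time in the recording's time base, ms.
#' @param pre_ms,post_ms window extent before/after impact, ms.
#' @return object of the same class, windowed.
#' @export
extract_impact_window <- function(x, impact_ms, pre_ms = 20, post_ms = 80) {
  if (pre_ms + post_ms <= 0) stop("empty window (pre + post <= 0)",
                                  call. = FALSE)
  t0 <- impact_ms - pre_ms; t1 <- impact_ms + post_ms
  tm <- x$t_ms
  dt <- if (length(tm) > 1) stats::median(diff(tm)) else 0
  if (t0 < min(tm) - 1e-9 || t1 > max(tm) + dt + 1e-9) {
    stop("window [", t0, ", ", t1, ") ms extends outside the recording",
         call. = FALSE)
  }
  keep <- tm >= t0 - 1e-9 & tm < t1 - 1e-9
  if (!any(keep)) stop("no samples inside the window", call. = FALSE)
  if (inherits(x, "rotseq")) {
    out <- x[keep]
    out$t_ms <- out$t_ms - t0
    out
  } else {
    out <- x[keep, , drop = FALSE]
    out$t_ms <- out$t_ms - t0
    rownames(out) <- NULL
    out
  }
}

#' Map video frames to motion-capture samples
#'
#' Within a 100 ms window sampled at \code{mocap_rate}, video frame k
#' (k = 0..n_frames-1) at t = k/video_rate maps to the nearest in-window
#' motion-capture sample. At the defaults (1000 Hz mocap, 50 Hz video,
#' 6 frames) the indices are 0, 20, 40, 60, 80 and 99: the final video
#' frame falls on the window boundary and is clamped to the last in-window
#' sample.
#'
#' @param n_mocap number of motion-capture samples in the window.
#' @param mocap_rate motion-capture rate, Hz.
#' @param video_rate video rate, Hz.
#' @param n_frames number of video frames.
#' @return data.frame with \code{video_frame} (0-based), \code{t_ms}, and
#'   \code{mocap_index} (1-based R index).
#' @export
map_video_frames <- function(n_mocap = 100L, mocap_rate = 1000,
                             video_rate = 50, n_frames = 6L) {
  k <- seq_len(n_frames) - 1L
  t_ms <- k * 1000 / video_rate
  idx0 <- round(t_ms * mocap_rate / 1000)
  idx0 <- pmin(pmax(idx0, 0L), n_mocap - 1L)
  data.frame(video_frame = k, t_ms = t_ms, mocap_index = as.integer(idx0) + 1L)
}

# ---- marker tables --------------------------------------------------------

#' Read and write the marker TSV dialect
#'
#' Tab-separated table with header \code{t_ms}, then \code{<label>_x},
#' \code{<label>_y}, \code{<label>_z} for each of the five labels, positions
#' in mm in the global frame; missing samples encoded as empty fields.
#'
#' @param path file path.
#' @return \code{read_marker_tsv}: data.frame with \code{t_ms} and 15
#'   coordinate columns (NA for gaps).
#' @export
read_marker_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"t_ms" %in% names(d)) stop("marker TSV missing 't_ms'", call. = FALSE)
  dt <- diff(d$t_ms)
  if (length(dt) && any(abs(dt - dt[1]) > 1e-6)) {
    stop("marker timestamps not uniformly spaced", call. = FALSE)
  }
  bad <- abs(as.matrix(d[-1])) >= 1e4
  if (any(bad, na.rm = TRUE)) {
    stop("marker positions exceed 10^4 mm: outside any plausible capture ",
         "volume", call. = FALSE)
  }
  d
}

#' @rdname read_marker_tsv
#' @param markers data.frame as returned by \code{read_marker_tsv}.
#' @export
write_marker_tsv <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Fill short marker gaps by linear interpolation
#'
#' Gaps of at most \code{max_gap_ms} are linearly interpolated per
#' coordinate; longer gaps raise an error (the five-marker redundancy and
#' \code{rigid_fit} are the intended fallback when a marker drops out for
#' longer).
#'
#' @param markers marker data.frame (t_ms + coordinate columns).
#' @param max_gap_ms longest gap to bridge, ms (default 10).
#' @return gap-free data.frame.
#' @export
fill_marker_gaps <- function(markers, max_gap_ms = 10) {
  out <- markers
  dt <- if (nrow(markers) > 1) diff(markers$t_ms)[1] else 1
  for (cn in setdiff(names(markers), "t_ms")) {
    v <- markers[[cn]]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    too_long <- r$values & (r$lengths * dt > max_gap_ms |
                            starts == 1L | ends == length(v))
    if (any(too_long)) {
      stop("gap in '", cn, "' longer than ", max_gap_ms,
           " ms (or at a boundary): cannot interpolate", call. = FALSE)
    }
    out[[cn]] <- stats::approx(markers$t_ms[!is.na(v)], v[!is.na(v)],
                               xout = markers$t_ms)$y
  }
  out
}

#' Reference orientation sequence from a marker table
#'
#' The full marker-to-orientation path: optional gap filling, zero-lag
#' Butterworth filtering of every coordinate, then a per-frame orientation.
#' With \code{method = "rigid"} (default) each frame is an orthogonal
#' Procrustes fit of the participant's reference geometry (estimated from
#' the first \code{n_ref} frames in ACS coordinates, all five markers);
#' with \code{method = "acs"} the four-marker ACS construction is applied
#' directly.
#'
#' @param markers marker data.frame (t_ms + \code{<label>_{x,y,z}} columns).
#' @param rate sampling rate, Hz.
#' @param cutoff Butterworth cutoff, Hz; \code{NULL} skips filtering.
#' @param order net filter order.
#' @param method "rigid" or "acs".
#' @param n_ref frames averaged for the reference geometry.
#' @return a \code{rotseq} in the global frame.
#' @export
markers_to_rotseq <- function(markers, rate = 1000, cutoff = 50, order = 4L,
                              method = c("rigid", "acs"), n_ref = 10L) {
  method <- match.arg(method)
  markers <- fill_marker_gaps(markers)
  coord_cols <- setdiff(names(markers), "t_ms")
  if (!is.null(cutoff)) {
    for (cn in coord_cols) {
      markers[[cn]] <- butterworth_zero_lag(markers[[cn]], cutoff, rate,
                                            order)
    }
  }
  labels <- intersect(MARKER_LABELS, unique(sub("_[xyz]$", "", coord_cols)))
  get_frame <- function(i) {
    m <- lapply(labels, function(l) {
      as.numeric(markers[i, paste0(l, "_", c("x", "y", "z"))])
    })
    names(m) <- labels
    m
  }
  n <- nrow(markers)
  R <- array(0, c(3, 3, n))
  if (method == "acs") {
    for (i in seq_len(n)) {
      R[, , i] <- project_rotation(construct_acs(get_frame(i))$rotation)
    }
  } else {
    # per-participant reference geometry in the head frame, averaged over
    # the first n_ref frames
    n_ref <- min(n_ref, n)
    ref_acc <- matrix(0, length(labels), 3)
    for (i in seq_len(n_ref)) {
      m <- get_frame(i)
      acs <- construct_acs(m)
      local <- t(vapply(m, function(p) {
        as.numeric(crossprod(acs$rotation, p - acs$origin))
      }, numeric(3)))
      ref_acc <- ref_acc + local
    }
    ref_geom <- ref_acc / n_ref
    for (i in seq_len(n)) {
      obs <- t(vapply(get_frame(i), as.numeric, numeric(3)))
      R[, , i] <- project_rotation(rigid_fit(ref_geom, obs)$rotation)
    }
  }
  rotseq(R, markers$t_ms, frame = "G", rate = rate, check = FALSE)
}
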