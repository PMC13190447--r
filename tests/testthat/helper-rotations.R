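# shared fixture builders and independent oracles

# quaternion geodesic-distance oracle: 2 * acos(|<q1, q2>|)
quat_dist_oracle <- function(R1, R2) {
  q1 <- headkin:::.mat_to_quat(R1)
  q2 <- headkin:::.mat_to_quat(R2)
  2 * acos(min(1, abs(sum(q1 * q2))))
}

# single-axis z rotation sequence from angles in degrees
zseq <- function(deg, t_ms = NULL, frame = "G", rate = 50) {
  if (is.null(t_ms)) t_ms <- (seq_along(deg) - 1) * 20
  rotseq(simplify2array(lapply(deg, rot_z)), t_ms, frame = frame,
         rate = rate)
}

# random smooth global-frame sequence: slow geodesic drift from a start pose
smooth_seq <- function(n = 6, step_deg = 5, t_ms = NULL) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  R0 <- rand_rotation()
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    R[, , i] <- R0 %*% rot_exp(axis * (i - 1) * step_deg * pi / 180)
  }
  if (is.null(t_ms)) t_ms <- (seq_len(n) - 1) * 20
  rotseq(R, t_ms, frame = "G", rate = 50)
}

# compose a sequence with constant left/right rotations
compose_seq <- function(seq, left = diag(3), right = diag(3)) {
  out <- seq
  for (i in seq_len(length(seq))) {
    out$R[, , i] <- left %*% seq$R[, , i] %*% right
  }
  out
}

# canonical synthetic-head marker geometry as a named list
canonical_markers <- function(transform_R = diag(3), t_vec = c(0, 0, 0)) {
  g <- headkin:::.DEFAULT_MARKER_GEOMETRY
  out <- lapply(seq_len(nrow(g)), function(i) {
    as.numeric(transform_R %*% g[i, ] + t_vec)
  })
  names(out) <- rownames(g)
  out
}

# brute-force Karcher objective: sum of squared geodesic distances
karcher_objective <- function(Rm, rots) {
  sum(vapply(seq_len(dim(rots)[3]),
             function(i) rot_dist(Rm, rots[, , i])^2, 0))
}
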