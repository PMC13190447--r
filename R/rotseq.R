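#' Rotation sequences
#'
#' A \code{rotseq} is a time-stamped sequence of 3x3 rotation matrices in a
#' named reference frame: the carrier for both motion-capture reference
#' orientations and model predictions. Rotations are stored as a 3x3xN
#' array; times are milliseconds relative to the window start.
#'
#' @param R a 3x3xN array (or a single 3x3 matrix, or a list of matrices) of
#'   valid rotations.
#' @param t_ms numeric vector of timestamps in milliseconds, strictly
#'   increasing, one per rotation.
#' @param frame frame label, conventionally \code{"C"} (camera), \code{"G"}
#'   (global) or \code{"H"} (anatomical head); free-form labels such as
#'   \code{"C:F"} identify which camera.
#' @param rate nominal sampling rate in Hz.
#' @param check validate every rotation (default TRUE).
#' @return an object of class \code{rotseq}.
#' @export
rotseq <- function(R, t_ms, frame = "G", rate = NA_real_, check = TRUE) {
  if (is.list(R)) R <- simplify2array(R)
  if (is.matrix(R)) R <- array(R, c(3, 3, 1))
  stopifnot(is.array(R), length(dim(R)) == 3L, all(dim(R)[1:2] == 3L))
  n <- dim(R)[3]
  t_ms <- as.numeric(t_ms)
  if (length(t_ms) != n) {
    stop("length(t_ms) must equal the number of rotations", call. = FALSE)
  }
  if (n > 1L && any(diff(t_ms) <= 0)) {
    stop("'t_ms' must be strictly increasing", call. = FALSE)
  }
  if (check) {
    for (i in seq_len(n)) .check_rotation(R[, , i], paste0("R[,,", i, "]"))
  }
  structure(list(R = R, t_ms = t_ms, frame = frame, rate = rate),
            class = "rotseq")
}

#' @export
length.rotseq <- function(x) dim(x$R)[3]

#' @export
print.rotseq <- function(x, ...) {
  n <- length(x)
  cat("Rotation sequence: ", n, " frame", if (n != 1) "s", ", frame '",
      x$frame, "'", sep = "")
  if (!is.na(x$rate)) cat(", ", x$rate, " Hz", sep = "")
  cat("\n  t_ms: ", paste(utils::head(signif(x$t_ms, 6), 8), collapse = ", "),
      if (n > 8) ", ...", "\n", sep = "")
  ang <- vapply(seq_len(n), function(i) rot_angle(x$R[, , i]), 0) * 180 / pi
  cat(sprintf("  rotation magnitude d(R,I): %.2f-%.2f deg\n",
              min(ang), max(ang)))
  invisible(x)
}

#' Subset a rotation sequence
#' @param x a \code{rotseq}.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.rotseq` <- function(x, i, ...) {
  i <- seq_len(length(x))[i]
  rotseq(x$R[, , i, drop = FALSE], x$t_ms[i], frame = x$frame,
         rate = x$rate, check = FALSE)
}

#' Euler-angle view of a sequence (display only)
#'
#' @param x a \code{rotseq}.
#' @param row.names,optional,... passed on / ignored (S3 contract).
#' @return data.frame with t_ms, yaw, pitch, roll (degrees) and a
#'   gimbal-lock flag.
#' @export
as.data.frame.rotseq <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x)
  out <- data.frame(t_ms = x$t_ms, yaw = numeric(n), pitch = numeric(n),
                    roll = numeric(n), gimbal_lock = logical(n))
  for (i in seq_len(n)) {
    e <- euler_from_rotation(x$R[, , i])
    out$yaw[i] <- e[["yaw"]]; out$pitch[i] <- e[["pitch"]]
    out$roll[i] <- e[["roll"]]
    out$gimbal_lock[i] <- attr(e, "gimbal_lock")
  }
  out
}

#' Read and write the rotation CSV dialect
#'
#' One row per frame with header
#' \code{frame,t_ms,r11,r12,r13,r21,r22,r23,r31,r32,r33}, row-major matrix
#' entries, '.' decimal separator.
#'
#' @param path file path.
#' @param rate nominal rate (Hz) to attach on read.
#' @param check validate rotations on read (default TRUE).
#' @return \code{read_rotation_csv}: a \code{rotseq}.
#' @export
read_rotation_csv <- function(path, rate = NA_real_, check = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "t_ms", paste0("r", c(11:13, 21:23, 31:33)))
  if (!all(need %in% names(d))) {
    stop("rotation CSV '", path, "' missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(d)
  R <- array(0, c(3, 3, n))
  cols <- as.matrix(d[, need[-(1:2)]])
  for (i in seq_len(n)) R[, , i] <- matrix(cols[i, ], 3, 3, byrow = TRUE)
  rotseq(R, d$t_ms, frame = as.character(d$frame[1]), rate = rate,
         check = check)
}

#' @rdname read_rotation_csv
#' @param x a \code{rotseq} to write.
#' @export
write_rotation_csv <- function(x, path) {
  stopifnot(inherits(x, "rotseq"))
  n <- length(x)
  m <- t(vapply(seq_len(n), function(i) as.vector(t(x$R[, , i])),
                numeric(9)))
  d <- data.frame(frame = x$frame, t_ms = x$t_ms)
  d[paste0("r", c(11:13, 21:23, 31:33))] <- as.data.frame(m)
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
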