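# Trace binarization and behavioral kinematics.

#' Binarize a raw calcium trace
#'
#' The raw trace is zero-phase low-pass filtered (2nd-order Butterworth),
#' z-scored over the whole session, and a frame is called active when the
#' normalized amplitude exceeds `z_threshold` standard deviations while the
#' filtered trace is rising (positive first-order derivative). This keeps the
#' rising phase of each transient, the epoch most tightly coupled to spiking.
#'
#' @param raw numeric fluorescence vector (one cell).
#' @param frame_rate_hz sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param z_threshold activity threshold in SD units.
#' @return list with `filtered`, `zscored`, `binary` (integer 0/1).
#' @export
binarize_trace <- function(raw, frame_rate_hz = 30, cutoff_hz = 2,
                           z_threshold = 2) {
  if (length(raw) < 2L) stop("trace needs at least 2 frames")
  if (anyNA(raw) || any(!is.finite(raw))) stop("trace contains NA/Inf")
  if (sd(raw) == 0) stop("zero-variance trace (dead cell); refusing to binarize")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (cutoff_hz >= frame_rate_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency")
  bf <- signal::butter(2, cutoff_hz / (frame_rate_hz / 2), type = "low")
  filtered <- as.numeric(signal::filtfilt(bf, raw))
  zscored <- (filtered - mean(filtered)) / sd(filtered)
  rising <- c(FALSE, diff(filtered) > 0)
  binary <- as.integer(zscored > z_threshold & rising)
  list(filtered = filtered, zscored = zscored, binary = binary)
}

#' Binarize all traces of a session
#'
#' @param session a `session` object (see [simulate_session()] or
#'   [read_session()]).
#' @param ... passed to [binarize_trace()].
#' @return the session with `filtered`, `zscored` and `binary` matrices added
#'   (cells x frames).
#' @export
binarize_session <- function(session, ...) {
  fr <- session$metadata$frame_rate_hz
  out <- lapply(seq_len(nrow(session$traces)), function(k)
    binarize_trace(session$traces[k, ], frame_rate_hz = fr, ...))
  session$filtered <- do.call(rbind, lapply(out, `[[`, "filtered"))
  session$zscored <- do.call(rbind, lapply(out, `[[`, "zscored"))
  session$binary <- do.call(rbind, lapply(out, `[[`, "binary"))
  dimnames(session$binary) <- dimnames(session$traces)
  session
}

# Centered Gaussian smoothing of a vector, kernel renormalized at the edges.
gaussian_smooth_vec <- function(x, sigma_frames) {
  if (sigma_frames <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma_frames))
  k <- exp(-((-half):half)^2 / (2 * sigma_frames^2))
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num / den)[(half + 1):(half + n)]
}

#' Derive kinematic variables from a pose track
#'
#' Velocity is the frame-to-frame displacement rate, smoothed with a short
#' Gaussian (sigma = 33 ms by default) to suppress tracking jitter; a wider
#' 30-frame boxcar version (`velocity_smooth`) is also stored and is the one
#' used for velocity binning. Acceleration is the per-frame first difference
#' of the boxcar-smoothed velocity divided by the frame interval (cm/s^2).
#' Head direction is derived from the head-to-nose axis, measured clockwise
#' from the +y axis.
#'
#' @param track data frame with columns `t, head_x, head_y, nose_x, nose_y`.
#' @param frame_rate_hz sampling rate in Hz.
#' @param smooth_sigma_s Gaussian sigma (s) for velocity smoothing.
#' @param smooth_window_frames boxcar width (frames) for `velocity_smooth`.
#' @return the track with `heading`, `velocity`, `velocity_smooth` and
#'   `acceleration` columns, as a `behavior_track`.
#' @export
compute_kinematics <- function(track, frame_rate_hz = 30,
                               smooth_sigma_s = 0.033,
                               smooth_window_frames = 30) {
  n <- nrow(track)
  if (n < 3L) stop("need at least 3 frames")
  if (any(diff(track$t) <= 0)) stop("timestamps must be strictly increasing")
  dt <- diff(track$t)
  d <- sqrt(diff(track$head_x)^2 + diff(track$head_y)^2)
  v <- d / dt
  v <- c(v[1], v)  # align to frame centers, first frame copies the second
  v <- gaussian_smooth_vec(v, smooth_sigma_s * frame_rate_hz)
  w <- max(1L, round(smooth_window_frames))
  box <- rep(1 / w, w)
  num <- stats::filter(v, box, sides = 2)
  den <- stats::filter(rep(1, n), box, sides = 2)
  # renormalize the boxcar near the edges instead of dropping frames
  vs <- as.numeric(num / den)
  miss <- is.na(vs)
  if (any(miss)) {
    cs <- cumsum(v)
    for (i in which(miss)) {
      lo <- max(1L, i - w %/% 2); hi <- min(n, i + w %/% 2)
      vs[i] <- (cs[hi] - if (lo > 1L) cs[lo - 1L] else 0) / (hi - lo + 1L)
    }
  }
  acc <- c(0, diff(vs)) * frame_rate_hz
  track$heading <- compute_head_direction(cbind(track$head_x, track$head_y),
                                          cbind(track$nose_x, track$nose_y))
  track$velocity <- v
  track$velocity_smooth <- vs
  track$acceleration <- acc
  if (is.null(track$direction_label)) track$direction_label <- "none"
  if (!inherits(track, "behavior_track"))
    class(track) <- c("behavior_track", "data.frame")
  attr(track, "frame_rate_hz") <- frame_rate_hz
  track
}

#' Head direction from head and nose markers
#'
#' The heading is the angle between the vertical (+y) axis and the
#' head-to-nose line, measured clockwise and wrapped to `[0, 2*pi)`. Frames
#' where the two markers coincide propagate the last valid heading.
#'
#' @param head_xy,nose_xy n x 2 matrices of marker positions (cm).
#' @return heading in radians, `[0, 2*pi)`.
#' @export
compute_head_direction <- function(head_xy, nose_xy) {
  head_xy <- as.matrix(head_xy); nose_xy <- as.matrix(nose_xy)
  dx <- nose_xy[, 1] - head_xy[, 1]
  dy <- nose_xy[, 2] - head_xy[, 2]
  bad <- dx == 0 & dy == 0
  if (all(bad)) stop("head and nose markers coincide on every frame")
  theta <- wrap_angle(atan2(dx, dy))
  if (any(bad)) {
    idx <- cummax(ifelse(bad, 0L, seq_along(theta)))
    idx[idx == 0L] <- which(!bad)[1]  # leading invalid frames take first valid
    theta <- theta[idx]
  }
  theta
}

#' Align a behavior track to the calcium clock
#'
#' Positions and kinematics are linearly interpolated onto the calcium frame
#' timestamps. Heading is unwrapped, interpolated, and rewrapped so that
#' interpolation never crosses the circular discontinuity the long way.
#' Frames outside the behavior time range are flagged invalid.
#'
#' @param track a `behavior_track`.
#' @param calcium_timestamps numeric vector of target timestamps (s).
#' @return a `behavior_track` on the calcium clock with a logical `valid`
#'   column.
#' @export
align_behavior_to_calcium <- function(track, calcium_timestamps) {
  tb <- track$t
  tc <- calcium_timestamps
  if (max(tc) < min(tb) || min(tc) > max(tb))
    stop("behavior and calcium clocks do not overlap")
  interp <- function(y) approx(tb, y, xout = tc, rule = 2)$y
  unwrapped <- cumsum(c(track$heading[1],
                        ((diff(track$heading) + pi) %% (2 * pi)) - pi))
  out <- data.frame(
    t = tc,
    head_x = interp(track$head_x), head_y = interp(track$head_y),
    nose_x = interp(track$nose_x), nose_y = interp(track$nose_y),
    heading = wrap_angle(interp(unwrapped)),
    velocity = interp(track$velocity),
    velocity_smooth = interp(track$velocity_smooth),
    acceleration = interp(track$acceleration),
    stringsAsFactors = FALSE)
  # nearest-neighbor for the categorical label
  lab_idx <- pmin(pmax(round(approx(tb, seq_along(tb), xout = tc,
                                    rule = 2)$y), 1L), length(tb))
  out$direction_label <- track$direction_label[lab_idx]
  out$valid <- tc >= min(tb) & tc <= max(tb)
  class(out) <- c("behavior_track", "data.frame")
  attr(out, "arena") <- attr(track, "arena")
  attr(out, "frame_rate_hz") <- attr(track, "frame_rate_hz")
  out
}

#' Locomotion mask
#'
#' Frames with velocity below threshold are excluded from position and
#' direction tuning estimates; the comparison is inclusive (`>=`).
#'
#' @param velocity numeric velocity vector (cm/s).
#' @param threshold_cm_s exclusion threshold (cm/s).
#' @return logical vector, `TRUE` where the animal counts as running.
#' @export
running_mask <- function(velocity, threshold_cm_s = 5) {
  velocity >= threshold_cm_s
}
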