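# Synthetic sessions: trajectory, ground-truth tuned binary activity, and
# calcium traces with stored truth, so every downstream stage is testable
# against known parameters.

#' Describe a recording arena
#'
#' @param kind `"open_field"` or `"linear_track"`.
#' @param width_cm,height_cm open-field side lengths in cm (height is 0 for a
#'   linear track).
#' @param track_length_cm linear-track length in cm (ignored for open field).
#' @return an object of class `"arena_spec"`.
#' @examples
#' arena_spec("open_field", 45, 45)
#' arena_spec("linear_track", track_length_cm = 100)
#' @export
arena_spec <- function(kind = c("open_field", "linear_track"),
                       width_cm = 45, height_cm = 45, track_length_cm = 100) {
  kind <- match.arg(kind)
  if (kind == "open_field") {
    stopifnot_scalar_pos(width_cm, "width_cm")
    stopifnot_scalar_pos(height_cm, "height_cm")
    track_length_cm <- NA_real_
  } else {
    stopifnot_scalar_pos(track_length_cm, "track_length_cm")
    width_cm <- track_length_cm
    height_cm <- 0
  }
  structure(list(kind = kind, width_cm = width_cm, height_cm = height_cm,
                 track_length_cm = track_length_cm),
            class = "arena_spec")
}

#' Calcium transient kernel parameters
#'
#' Double-exponential transient shape emulating a fast genetically encoded
#' calcium indicator (GCaMP6f-like kinetics by default).
#'
#' @param rise_s,decay_s rise and decay time constants in seconds
#'   (`rise_s < decay_s`).
#' @param amplitude peak amplitude of a single transient (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @return an object of class `"calcium_kernel"`.
#' @export
calcium_kernel <- function(rise_s = 0.05, decay_s = 0.5, amplitude = 1,
                           noise_sd = 0.05) {
  stopifnot_scalar_pos(rise_s, "rise_s")
  stopifnot_scalar_pos(decay_s, "decay_s")
  stopifnot_scalar_pos(amplitude, "amplitude")
  if (rise_s >= decay_s) stop("rise_s must be smaller than decay_s")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(rise_s = rise_s, decay_s = decay_s, amplitude = amplitude,
                 noise_sd = noise_sd),
            class = "calcium_kernel")
}

#' Ground-truth tuning of a synthetic cell
#'
#' Defines the per-frame activation probability of a simulated neuron as
#' `p_baseline + (p_in_field - p_baseline) * f(state)`, with `f` a normalized
#' tuning function of the chosen behavioral variable.
#'
#' @param variable one of `"position2d"`, `"position1d"`, `"direction"`,
#'   `"velocity"`, `"acceleration"`, `"none"` (untuned control).
#' @param p_in_field activation probability per frame at the tuning peak.
#' @param p_baseline activation probability per frame far from the peak.
#' @param center_cm field center: length-2 (x, y) for `position2d`, scalar for
#'   `position1d`.
#' @param width_cm place-field width in cm, defined as twice the Gaussian
#'   sigma of the field.
#' @param preferred_rad preferred head direction in radians, in `[0, 2*pi)`.
#' @param concentration von Mises concentration of directional tuning.
#' @param slope,offset logistic parameters of monotone velocity/acceleration
#'   tuning: `f = plogis(slope * (value - offset))`.
#' @param direction_gate optionally restrict activation to `"left"` or
#'   `"right"` traversals on a linear track.
#' @return an object of class `"cell_tuning"`.
#' @export
cell_tuning <- function(variable = c("position2d", "position1d", "direction",
                                     "velocity", "acceleration", "none"),
                        p_in_field = 0.15, p_baseline = 0.005,
                        center_cm = NULL, width_cm = 7,
                        preferred_rad = 0, concentration = 4,
                        slope = 0.3, offset = 15,
                        direction_gate = NULL) {
  variable <- match.arg(variable)
  if (!(p_baseline >= 0 && p_baseline <= p_in_field && p_in_field <= 1))
    stop("need 0 <= p_baseline <= p_in_field <= 1")
  if (variable %in% c("position2d", "position1d") && is.null(center_cm))
    stop("place tuning needs 'center_cm'")
  if (!is.null(direction_gate))
    direction_gate <- match.arg(direction_gate, c("left", "right"))
  preferred_rad <- wrap_angle(preferred_rad)
  structure(list(variable = variable, p_in_field = p_in_field,
                 p_baseline = p_baseline, center_cm = center_cm,
                 width_cm = width_cm, preferred_rad = preferred_rad,
                 concentration = concentration, slope = slope, offset = offset,
                 direction_gate = direction_gate),
            class = "cell_tuning")
}

#' Simulate a behavioral trajectory
#'
#' Open-field paths follow a reflected Ornstein--Uhlenbeck speed process with
#' diffusing heading; linear-track paths alternate end-to-end runs separated
#' by brief end pauses. The returned track carries pose markers (head and
#' nose), derived kinematics, and per-frame run-direction labels so that
#' direction-split analyses have a recoverable truth.
#'
#' @param arena an [arena_spec()].
#' @param duration_s session duration in seconds.
#' @param frame_rate_hz sampling rate in Hz.
#' @param motion_params list with elements `mean_speed_cm_s`, `speed_sd_cm_s`,
#'   `speed_tau_s`, `turn_sd_rad` (heading diffusion, rad/sqrt(s)),
#'   `pause_s` (linear-track end pause). Missing entries take defaults.
#' @param seed integer seed; identical seeds give bit-identical tracks.
#' @return a `behavior_track` data frame (see [compute_kinematics()]) with
#'   columns `t, head_x, head_y, nose_x, nose_y, heading, velocity,
#'   velocity_smooth, acceleration, direction_label`.
#' @export
simulate_trajectory <- function(arena, duration_s = 900, frame_rate_hz = 30,
                                motion_params = list(), seed = 1) {
  stopifnot(inherits(arena, "arena_spec"))
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  mp <- modifyList(list(mean_speed_cm_s = 10, speed_sd_cm_s = 3,
                        speed_tau_s = 1, turn_sd_rad = 1.6, pause_s = 1.5),
                   motion_params)
  set.seed(seed)
  n <- round(duration_s * frame_rate_hz)
  dt <- 1 / frame_rate_hz
  tt <- (seq_len(n) - 1) * dt

  if (arena$kind == "open_field") {
    W <- arena$width_cm; H <- arena$height_cm
    x <- numeric(n); y <- numeric(n); theta <- numeric(n); v <- numeric(n)
    x[1] <- W / 2; y[1] <- H / 2
    theta[1] <- runif(1, 0, 2 * pi)
    v[1] <- max(mp$mean_speed_cm_s, 0)
    if (mp$mean_speed_cm_s > 0 || mp$speed_sd_cm_s > 0) {
      ou_a <- dt / mp$speed_tau_s
      ou_s <- mp$speed_sd_cm_s * sqrt(2 * dt / mp$speed_tau_s)
      ev <- rnorm(n); eth <- rnorm(n)
      for (i in 2:n) {
        v[i] <- abs(v[i - 1] + ou_a * (mp$mean_speed_cm_s - v[i - 1]) +
                      ou_s * ev[i])
        theta[i] <- theta[i - 1] + mp$turn_sd_rad * sqrt(dt) * eth[i]
        # heading convention: clockwise from +y, displacement (sin, cos)
        xi <- x[i - 1] + v[i] * dt * sin(theta[i])
        yi <- y[i - 1] + v[i] * dt * cos(theta[i])
        if (xi < 0) { xi <- -xi; theta[i] <- -theta[i] }
        if (xi > W) { xi <- 2 * W - xi; theta[i] <- -theta[i] }
        if (yi < 0) { yi <- -yi; theta[i] <- pi - theta[i] }
        if (yi > H) { yi <- 2 * H - yi; theta[i] <- pi - theta[i] }
        x[i] <- min(max(xi, 0), W); y[i] <- min(max(yi, 0), H)
      }
    } else {
      x[] <- x[1]; y[] <- y[1]; theta[] <- theta[1]
    }
    theta <- wrap_angle(theta)
    dir_label <- rep("none", n)
  } else {
    L <- arena$track_length_cm
    x <- numeric(n); y <- rep(0, n); theta <- numeric(n)
    dir_label <- character(n)
    pos <- 0; run_dir <- 1L; pause_left <- 0L
    pause_frames <- max(1L, round(mp$pause_s * frame_rate_hz))
    if (mp$mean_speed_cm_s > 0 || mp$speed_sd_cm_s > 0) {
      ou_a <- dt / mp$speed_tau_s
      ou_s <- mp$speed_sd_cm_s * sqrt(2 * dt / mp$speed_tau_s)
      sp <- mp$mean_speed_cm_s
      ev <- rnorm(n)
      for (i in seq_len(n)) {
        if (pause_left > 0L) {
          pause_left <- pause_left - 1L
          dir_label[i] <- "none"
        } else {
          sp <- abs(sp + ou_a * (mp$mean_speed_cm_s - sp) + ou_s * ev[i])
          pos <- pos + run_dir * sp * dt
          if (pos >= L) { pos <- L; run_dir <- -1L; pause_left <- pause_frames }
          if (pos <= 0) { pos <- 0; run_dir <- 1L; pause_left <- pause_frames }
          dir_label[i] <- if (pause_left > 0L) "none" else
            if (run_dir > 0L) "right" else "left"
        }
        x[i] <- pos
        theta[i] <- if (run_dir > 0L) pi / 2 else 3 * pi / 2
      }
    } else {
      x[] <- 0; theta[] <- pi / 2; dir_label[] <- "none"
    }
  }

  nose_len <- 1.5  # cm from head centroid to nose tip
  track <- data.frame(
    t = tt, head_x = x, head_y = y,
    nose_x = x + nose_len * sin(theta), nose_y = y + nose_len * cos(theta),
    direction_label = dir_label, stringsAsFactors = FALSE)
  track <- compute_kinematics(track, frame_rate_hz)
  attr(track, "arena") <- arena
  attr(track, "frame_rate_hz") <- frame_rate_hz
  class(track) <- c("behavior_track", "data.frame")
  track
}

# Normalized tuning function f(state) in [0, 1] for one cell on one track.
tuning_function <- function(track, tuning) {
  f <- switch(tuning$variable,
    position2d = {
      sig <- tuning$width_cm / 2
      d2 <- (track$head_x - tuning$center_cm[1])^2 +
            (track$head_y - tuning$center_cm[2])^2
      exp(-d2 / (2 * sig^2))
    },
    position1d = {
      sig <- tuning$width_cm / 2
      exp(-(track$head_x - tuning$center_cm[1])^2 / (2 * sig^2))
    },
    direction = {
      exp(tuning$concentration *
            (cos(track$heading - tuning$preferred_rad) - 1))
    },
    velocity = stats::plogis(tuning$slope * (track$velocity - tuning$offset)),
    acceleration = stats::plogis(tuning$slope *
                                   (track$acceleration - tuning$offset)),
    none = rep(0, nrow(track)))
  if (!is.null(tuning$direction_gate))
    f <- f * as.numeric(track$direction_label == tuning$direction_gate)
  f
}

#' Generate ground-truth binary activity for one cell
#'
#' Draws per-frame independent Bernoulli activity with rate
#' `p_baseline + (p_in_field - p_baseline) * f(state)` and returns both the
#' draw and the true per-frame rate, so downstream recovery can be checked
#' against exact binomial intervals.
#'
#' @param track a `behavior_track` from [simulate_trajectory()].
#' @param tuning a [cell_tuning()].
#' @param seed integer seed.
#' @return list with `binary` (0/1 vector) and `rate` (true per-frame rate).
#' @export
generate_binary_activity <- function(track, tuning, seed = 1) {
  stopifnot(inherits(tuning, "cell_tuning"), nrow(track) > 0)
  rate <- tuning$p_baseline +
    (tuning$p_in_field - tuning$p_baseline) * tuning_function(track, tuning)
  if (any(rate < 0 | rate > 1)) stop("composed rate outside [0, 1]")
  set.seed(seed)
  list(binary = rbinom(length(rate), 1L, rate), rate = rate)
}

#' Synthesize a raw fluorescence trace from binary activity
#'
#' Each 0-to-1 transition of the binary vector injects one double-exponential
#' transient (peak-normalized to `amplitude`); transients sum linearly and
#' Gaussian noise is added.
#'
#' @param binary 0/1 activity vector.
#' @param kernel a [calcium_kernel()].
#' @param frame_rate_hz sampling rate in Hz.
#' @param seed integer seed (noise only).
#' @return list with `trace` (fluorescence vector) and `onsets` (ground-truth
#'   onset frame indices).
#' @export
synthesize_calcium <- function(binary, kernel, frame_rate_hz = 30, seed = 1) {
  stopifnot(inherits(kernel, "calcium_kernel"))
  n <- length(binary)
  onsets <- which(diff(c(0L, binary)) == 1L)
  klen <- min(n, ceiling(8 * kernel$decay_s * frame_rate_hz))
  kt <- (seq_len(klen) - 1) / frame_rate_hz
  h <- exp(-kt / kernel$decay_s) - exp(-kt / kernel$rise_s)
  h <- h / max(h) * kernel$amplitude
  trace <- numeric(n + klen)
  for (o in onsets) trace[o:(o + klen - 1L)] <- trace[o:(o + klen - 1L)] + h
  trace <- trace[seq_len(n)]
  if (kernel$noise_sd > 0) {
    set.seed(seed)
    trace <- trace + rnorm(n, 0, kernel$noise_sd)
  }
  list(trace = trace, onsets = onsets)
}

#' Simulate a full synthetic session
#'
#' Bundles a trajectory with a population of cells whose tuning is known,
#' producing raw calcium traces, ground-truth binary activity and per-frame
#' rates in a single session object consumable by the whole pipeline.
#'
#' @param arena an [arena_spec()].
#' @param tunings list of [cell_tuning()] objects, one per cell.
#' @param duration_s,frame_rate_hz session length and rate.
#' @param kernel a [calcium_kernel()] shared by all cells.
#' @param motion_params passed to [simulate_trajectory()].
#' @param seed integer seed controlling trajectory, activity, and noise.
#' @return a `session` object: list with `metadata`, `behavior`, `traces`
#'   (cells x frames matrix), `truth` (list of per-cell binary/rate/onsets,
#'   plus the tunings).
#' @export
simulate_session <- function(arena, tunings, duration_s = 900,
                             frame_rate_hz = 30,
                             kernel = calcium_kernel(),
                             motion_params = list(), seed = 1) {
  track <- simulate_trajectory(arena, duration_s, frame_rate_hz,
                               motion_params, seed = seed)
  n_cells <- length(tunings)
  n <- nrow(track)
  traces <- matrix(0, n_cells, n)
  truth_binary <- matrix(0L, n_cells, n)
  truth_rate <- matrix(0, n_cells, n)
  onsets <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    act <- generate_binary_activity(track, tunings[[k]], seed = seed + 1000 + k)
    cal <- synthesize_calcium(act$binary, kernel, frame_rate_hz,
                              seed = seed + 2000 + k)
    traces[k, ] <- cal$trace
    truth_binary[k, ] <- act$binary
    truth_rate[k, ] <- act$rate
    onsets[[k]] <- cal$onsets
  }
  rownames(traces) <- sprintf("cell_%03d", seq_len(n_cells))
  structure(list(
    metadata = list(arena = arena, frame_rate_hz = frame_rate_hz,
                    duration_s = duration_s, seed = seed,
                    n_cells = n_cells),
    behavior = track,
    traces = traces,
    timestamps = track$t,
    truth = list(binary = truth_binary, rate = truth_rate, onsets = onsets,
                 tunings = tunings)),
    class = "session")
}

#' Convenience constructors for synthetic populations
#'
#' `make_place_cells()` scatters Gaussian place fields uniformly inside the
#' arena (with an edge margin); `make_untuned_cells()` returns baseline-only
#' controls at a given activity level.
#'
#' @param n number of cells.
#' @param arena an [arena_spec()].
#' @param width_cm,p_in_field,p_baseline passed to [cell_tuning()].
#' @param margin_cm minimum distance of field centers from the walls.
#' @param seed integer seed for field placement.
#' @return list of [cell_tuning()] objects.
#' @export
make_place_cells <- function(n, arena, width_cm = 7, p_in_field = 0.15,
                             p_baseline = 0.005, margin_cm = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    if (arena$kind == "open_field") {
      ctr <- c(runif(1, margin_cm, arena$width_cm - margin_cm),
               runif(1, margin_cm, arena$height_cm - margin_cm))
      cell_tuning("position2d", p_in_field, p_baseline,
                  center_cm = ctr, width_cm = width_cm)
    } else {
      cell_tuning("position1d", p_in_field, p_baseline,
                  center_cm = runif(1, margin_cm,
                                    arena$track_length_cm - margin_cm),
                  width_cm = width_cm)
    }
  })
}

#' @rdname make_place_cells
#' @param p_active per-frame activity probability of untuned cells.
#' @export
make_untuned_cells <- function(n, p_active = 0.015) {
  lapply(seq_len(n), function(k)
    cell_tuning("none", p_in_field = p_active, p_baseline = p_active))
}
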