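# Binned behavioral states and probabilistic tuning maps.

#' Binning specification for a behavioral variable
#'
#' Defaults follow the standard analysis grid: open-field position 17 x 17
#' bins spanning the arena (bin count held fixed, bin size scaled to the
#' arena side); linear-track position 34 bins; head direction 40 circular
#' bins of 9 degrees; velocity 20 bins on [2.5, 30] cm/s; acceleration 20
#' bins on [-2, 2] cm/s^2. Bins are half-open `[left, right)` with the last
#' bin closed; values outside the range are flagged invalid, not clipped.
#'
#' @param variable one of `"position2d"`, `"position1d"`, `"direction"`,
#'   `"velocity"`, `"acceleration"`.
#' @param arena an [arena_spec()]; required for positional variables.
#' @param n_bins bins per dimension (scalar, or length-2 for 2D); defaults
#'   per variable as above.
#' @param limits range per dimension (length-2 vector, or list of two for
#'   2D); defaults per variable.
#' @return an object of class `"binning_spec"` with fields `variable`,
#'   `edges` (list per dimension), `n_bins`, `circular`, `centers`.
#' @export
binning_spec <- function(variable = c("position2d", "position1d", "direction",
                                      "velocity", "acceleration"),
                         arena = NULL, n_bins = NULL, limits = NULL) {
  variable <- match.arg(variable)
  circular <- variable == "direction"
  if (variable %in% c("position2d", "position1d") && is.null(limits)) {
    if (is.null(arena)) stop("positional binning needs an 'arena'")
  }
  defaults <- switch(variable,
    position2d = list(n = c(17L, 17L),
                      lim = list(c(0, arena$width_cm), c(0, arena$height_cm))),
    position1d = list(n = 34L, lim = list(c(0, arena$track_length_cm))),
    direction = list(n = 40L, lim = list(c(0, 2 * pi))),
    velocity = list(n = 20L, lim = list(c(2.5, 30))),
    acceleration = list(n = 20L, lim = list(c(-2, 2))))
  if (is.null(n_bins)) n_bins <- defaults$n
  if (is.null(limits)) limits <- defaults$lim
  if (!is.list(limits)) limits <- list(limits)
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != length(limits))
    stop("n_bins and limits disagree on dimensionality")
  edges <- mapply(function(nb, lim) seq(lim[1], lim[2], length.out = nb + 1L),
                  n_bins, limits, SIMPLIFY = FALSE)
  for (e in edges) if (any(diff(e) <= 0)) stop("edges must strictly increase")
  centers <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  structure(list(variable = variable, edges = edges, n_bins = n_bins,
                 circular = circular, centers = centers),
            class = "binning_spec")
}

#' Total number of bins of a spec
#' @param spec a [binning_spec()].
#' @return integer, product over dimensions.
#' @export
n_states <- function(spec) prod(spec$n_bins)

bin_one_dim <- function(values, edges, circular) {
  if (circular) {
    rng <- edges[length(edges)] - edges[1]
    values <- edges[1] + (values - edges[1]) %% rng
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[values < edges[1] | values > edges[length(edges)]] <- NA_integer_
  idx
}

#' Assign each frame to a behavioral-state bin
#'
#' @param values numeric vector (1D variables) or n x 2 matrix/data frame
#'   (2D position) of per-frame values.
#' @param spec a [binning_spec()].
#' @param mask optional logical vector; frames with `FALSE` are flagged
#'   invalid (`NA` bin).
#' @return integer vector of linearized bin indices in `1..n_states(spec)`,
#'   `NA` for invalid or out-of-range frames.
#' @export
bin_states <- function(values, spec, mask = NULL) {
  stopifnot(inherits(spec, "binning_spec"))
  if (length(spec$n_bins) == 2L) {
    values <- as.matrix(values)
    ix <- bin_one_dim(values[, 1], spec$edges[[1]], FALSE)
    iy <- bin_one_dim(values[, 2], spec$edges[[2]], FALSE)
    bins <- ix + (iy - 1L) * spec$n_bins[1]
  } else {
    bins <- bin_one_dim(as.numeric(values), spec$edges[[1]], spec$circular)
  }
  if (!is.null(mask)) {
    if (length(mask) != length(bins)) stop("mask length mismatch")
    bins[!mask] <- NA_integer_
  }
  if (all(is.na(bins))) stop("no valid frames after masking")
  bins
}

#' Per-frame values of the binned variable, from a behavior track
#'
#' Convenience dispatcher mapping a [binning_spec()] variable to the matching
#' track columns (2D position and 1D position use the head centroid; velocity
#' uses the 30-frame smoothed velocity).
#'
#' @param track a `behavior_track`.
#' @param spec a [binning_spec()].
#' @return vector or matrix of per-frame values suitable for [bin_states()].
#' @export
state_values <- function(track, spec) {
  switch(spec$variable,
    position2d = cbind(track$head_x, track$head_y),
    position1d = track$head_x,
    direction = track$heading,
    velocity = track$velocity_smooth,
    acceleration = track$acceleration)
}

#' Estimate a probabilistic tuning map
#'
#' Over valid frames, estimates the occupancy `P(S_i)` (time in bin i /
#' total time), the joint `P(S_i & A)` (time active in bin i / total time)
#' and the conditional `P(A | S_i)` (time active in bin i / time in bin i)
#' as frame-count ratios. Unvisited bins carry `NA` conditionals and are
#' flagged, never silently zero.
#'
#' @param binary 0/1 activity vector for one cell.
#' @param bins per-frame bin index from [bin_states()] (`NA` = invalid).
#' @param spec the [binning_spec()] that produced `bins`.
#' @return an object of class `"tuning_map"`: list with `spec`, `occupancy`,
#'   `joint`, `conditional`, `frames_per_bin`, `M` (visited bins), `n_valid`,
#'   `p_active`.
#' @export
compute_tuning_map <- function(binary, bins, spec) {
  if (length(binary) != length(bins)) stop("binary/bins length mismatch")
  valid <- !is.na(bins)
  if (!any(valid)) stop("zero valid frames")
  b <- bins[valid]
  a <- binary[valid]
  nb <- n_states(spec)
  frames_per_bin <- tabulate(b, nbins = nb)
  active_per_bin <- tabulate(b[a == 1L], nbins = nb)
  n_valid <- sum(frames_per_bin)
  occupancy <- frames_per_bin / n_valid
  joint <- active_per_bin / n_valid
  conditional <- ifelse(frames_per_bin > 0, active_per_bin / frames_per_bin,
                        NA_real_)
  structure(list(spec = spec, occupancy = occupancy, joint = joint,
                 conditional = conditional, frames_per_bin = frames_per_bin,
                 M = sum(frames_per_bin > 0), n_valid = n_valid,
                 p_active = mean(a)),
            class = "tuning_map")
}

# Truncated Gaussian kernel on bin offsets.
gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  list(k = k, half = half)
}

smooth_vec_1d <- function(x, sigma, circular) {
  n <- length(x)
  kk <- gauss_kernel(sigma)
  vis <- as.numeric(!is.na(x))
  x0 <- ifelse(is.na(x), 0, x)
  out <- numeric(n); den <- numeric(n)
  offs <- (-kk$half):kk$half
  for (j in seq_along(offs)) {
    src <- seq_len(n) + offs[j]
    if (circular) {
      src <- ((src - 1L) %% n) + 1L
      out <- out + kk$k[j] * x0[src]
      den <- den + kk$k[j] * vis[src]
    } else {
      ok <- src >= 1L & src <= n
      out[ok] <- out[ok] + kk$k[j] * x0[src[ok]]
      den[ok] <- den[ok] + kk$k[j] * vis[src[ok]]
    }
  }
  res <- out / den
  res[vis == 0] <- NA_real_
  res
}

#' Smooth a tuning map
#'
#' Visitation-normalized Gaussian smoothing of the conditional activity map
#' (occupancy and joint maps stay raw; smoothed maps feed stability
#' correlations and display, raw maps feed mutual information). Circular
#' variables are smoothed with a wrapped kernel; unvisited bins are excluded
#' from the kernel mass and remain `NA`.
#'
#' @param map a [compute_tuning_map()] result, or a bare numeric
#'   vector/matrix laid out per `spec`.
#' @param sigma_bins Gaussian sigma in bins.
#' @param spec required when `map` is a bare vector.
#' @return the smoothed conditional map (vector in spec layout); for a
#'   `tuning_map` input, the map object with a `smoothed` field added.
#' @export
smooth_map <- function(map, sigma_bins = 3, spec = NULL) {
  if (sigma_bins <= 0) stop("sigma_bins must be > 0")
  is_map <- inherits(map, "tuning_map")
  if (is_map) { spec <- map$spec; x <- map$conditional }
  else x <- as.numeric(map)
  if (is.null(spec)) stop("need a binning_spec for a bare vector")
  if (length(spec$n_bins) == 1L) {
    sm <- smooth_vec_1d(x, sigma_bins, spec$circular)
  } else {
    nx <- spec$n_bins[1]; ny <- spec$n_bins[2]
    m <- matrix(x, nx, ny)
    vis <- !is.na(m)
    m0 <- ifelse(vis, m, 0)
    kk <- gauss_kernel(sigma_bins)
    conv2 <- function(mat) {
      tmp <- apply(mat, 2, function(col) {
        as.numeric(stats::filter(c(rep(0, kk$half), col, rep(0, kk$half)),
                                 kk$k, sides = 2))[(kk$half + 1):(kk$half + nx)]
      })
      t(apply(tmp, 1, function(row) {
        as.numeric(stats::filter(c(rep(0, kk$half), row, rep(0, kk$half)),
                                 kk$k, sides = 2))[(kk$half + 1):(kk$half + ny)]
      }))
    }
    num <- conv2(m0)
    den <- conv2(matrix(as.numeric(vis), nx, ny))
    sm <- num / den
    sm[!vis] <- NA_real_
    sm <- as.numeric(sm)
  }
  if (is_map) { map$smoothed <- sm; map } else sm
}

#' Lay a tuning-map vector out as a 2D matrix
#' @param x vector in spec layout (e.g. `map$conditional`).
#' @param spec the 2D [binning_spec()].
#' @return `n_bins[1] x n_bins[2]` matrix.
#' @export
map_as_matrix <- function(x, spec) {
  if (length(spec$n_bins) != 2L) stop("spec is not two-dimensional")
  matrix(x, spec$n_bins[1], spec$n_bins[2])
}
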