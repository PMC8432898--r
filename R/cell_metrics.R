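# Per-cell activity statistics, split-half stability, spatial dispersion.

#' Activity, activity index and bursting index
#'
#' `p_active` is the fraction of active frames; the bursting index is the
#' probability of staying active, `P(A_t | A_{t-1})`; the activity index is
#' the probability of becoming active from an inactive state,
#' `P(A_t | I_{t-1})`. Indices are estimated by transition counting and are
#' `NA` (flagged missing, not zero) when the conditioning state never occurs.
#'
#' @param binary 0/1 activity vector.
#' @return list with `p_active`, `activity_index`, `bursting_index`.
#' @export
activity_stats <- function(binary) {
  n <- length(binary)
  if (n < 2L) stop("need at least 2 frames")
  prev <- binary[-n]; cur <- binary[-1]
  n_act <- sum(prev == 1L); n_inact <- sum(prev == 0L)
  list(p_active = mean(binary),
       activity_index = if (n_inact > 0) sum(cur == 1L & prev == 0L) / n_inact
                        else NA_real_,
       bursting_index = if (n_act > 0) sum(cur == 1L & prev == 1L) / n_act
                        else NA_real_)
}

#' Split-half within-session stability
#'
#' The session is split at the frame where the cumulative count of binarized
#' events (0-to-1 transitions) reaches half the session total, so both halves
#' hold the same amount of activity. Tuning maps are computed per half,
#' Gaussian-smoothed, and Pearson-correlated over the bins visited in both
#' halves. A correlation above `stable_threshold` counts as a stable field.
#'
#' @param binary 0/1 activity vector.
#' @param bins per-frame bin index from [bin_states()].
#' @param spec the matching [binning_spec()].
#' @param sigma_bins smoothing sigma in bins.
#' @param stable_threshold stability criterion on the correlation.
#' @return list with `correlation`, `stable`, `split_frame`, `n_events`.
#' @export
split_half_stability <- function(binary, bins, spec, sigma_bins = 3,
                                 stable_threshold = 0.5) {
  events <- diff(c(0L, binary)) == 1L
  n_events <- sum(events)
  if (n_events < 2L) stop("need at least 2 binarized events to split")
  split_frame <- which(cumsum(events) >= n_events / 2)[1]
  idx1 <- seq_len(split_frame)
  idx2 <- (split_frame + 1L):length(binary)
  if (!any(!is.na(bins[idx1])) || !any(!is.na(bins[idx2])))
    stop("one half has zero valid frames")
  m1 <- smooth_map(compute_tuning_map(binary[idx1], bins[idx1], spec),
                   sigma_bins)
  m2 <- smooth_map(compute_tuning_map(binary[idx2], bins[idx2], spec),
                   sigma_bins)
  both <- !is.na(m1$smoothed) & !is.na(m2$smoothed)
  if (sum(both) < 3L) stop("fewer than 3 bins visited in both halves")
  r <- suppressWarnings(cor(m1$smoothed[both], m2$smoothed[both]))
  if (is.na(r)) r <- 0  # constant map in a half carries no spatial signal
  list(correlation = r, stable = r > stable_threshold,
       split_frame = split_frame, n_events = n_events,
       map_first = m1, map_second = m2)
}

#' Mean spatial dispersion of activity
#'
#' Mean Euclidean distance between each active-frame position and the
#' centroid of all active-frame positions (activity-weighted). Narrow, single
#' fields give small dispersion; diffuse or multi-field activity gives large
#' dispersion. Translation- and rotation-invariant by construction.
#'
#' @param binary 0/1 activity vector.
#' @param positions n x 2 matrix of positions (cm).
#' @param mask optional logical mask (e.g. locomotion frames).
#' @return dispersion in cm.
#' @export
mean_dispersion <- function(binary, positions, mask = NULL) {
  positions <- as.matrix(positions)
  keep <- binary == 1L
  if (!is.null(mask)) keep <- keep & mask
  if (!any(keep)) stop("no active frames under the mask")
  px <- positions[keep, 1]; py <- positions[keep, 2]
  cx <- mean(px); cy <- mean(py)
  mean(sqrt((px - cx)^2 + (py - cy)^2))
}

#' Per-cell metrics table for a population
#'
#' @param binary_mat cells x frames 0/1 matrix.
#' @param bins per-frame bin index.
#' @param spec the matching [binning_spec()].
#' @param positions n x 2 positions for dispersion (optional).
#' @param mask optional locomotion mask for dispersion.
#' @return data frame with one row per cell: `cell`, `p_active`,
#'   `activity_index`, `bursting_index`, `stability`, `stable`,
#'   `dispersion_cm`.
#' @export
cell_metrics <- function(binary_mat, bins, spec, positions = NULL,
                         mask = NULL) {
  rows <- lapply(seq_len(nrow(binary_mat)), function(k) {
    b <- binary_mat[k, ]
    st <- activity_stats(b)
    stab <- tryCatch(split_half_stability(b, bins, spec),
                     error = function(e) list(correlation = NA_real_,
                                              stable = NA))
    disp <- if (!is.null(positions))
      tryCatch(mean_dispersion(b, positions, mask),
               error = function(e) NA_real_) else NA_real_
    data.frame(cell = k, p_active = st$p_active,
               activity_index = st$activity_index,
               bursting_index = st$bursting_index,
               stability = stab$correlation, stable = stab$stable,
               dispersion_cm = disp)
  })
  do.call(rbind, rows)
}
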