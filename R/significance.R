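# Mutual information, circular-permutation nulls, and modulation verdicts.

# MI (bits) from per-bin occupancy/joint probability vectors. Terms with a
# zero joint probability contribute 0 by convention.
mi_from_probs <- function(occupancy, joint) {
  pa <- sum(joint)
  mi <- 0
  for (j in 1:2) {
    pj <- if (j == 1) joint else occupancy - joint
    pja <- if (j == 1) pa else 1 - pa
    ok <- pj > 0 & occupancy > 0
    if (pja > 0 && any(ok))
      mi <- mi + sum(pj[ok] * log2(pj[ok] / (occupancy[ok] * pja)))
  }
  mi
}

# MI from integer counts: frames per bin and active frames per bin.
mi_from_counts <- function(frames_per_bin, active_per_bin) {
  n <- sum(frames_per_bin)
  mi_from_probs(frames_per_bin / n, active_per_bin / n)
}

#' Mutual information of a tuning map
#'
#' Plug-in mutual information (bits) between the binary activity variable
#' (active/inactive) and the binned behavioral state, computed from the raw
#' (unsmoothed) occupancy and joint probabilities:
#' \deqn{MI = \sum_{i=1}^{M}\sum_{j\in\{1,2\}} P(S_i \cap A_j)\,
#'   \log_2 \frac{P(S_i \cap A_j)}{P(S_i) P(A_j)}}
#'
#' @param map a [compute_tuning_map()] result.
#' @return mutual information in bits (nonnegative).
#' @export
mutual_information <- function(map) {
  stopifnot(inherits(map, "tuning_map"))
  mi_from_probs(map$occupancy, map$joint)
}

#' Circular permutations of a binary activity vector
#'
#' Each surrogate rotates the whole activity time series by an independent
#' uniform shift of at least `min_shift_frames` frames (and at most
#' `T - min_shift_frames`), destroying the coupling to behavior while
#' preserving the temporal structure of transients.
#'
#' @param binary 0/1 activity vector.
#' @param n_shuffles number of surrogates.
#' @param min_shift_frames minimum rotation in frames (default 900,
#'   i.e. 30 s at 30 Hz).
#' @param seed integer seed.
#' @return `n_shuffles x T` integer matrix of rotated vectors.
#' @export
circular_shuffle <- function(binary, n_shuffles, min_shift_frames = 900,
                             seed = 1) {
  n <- length(binary)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (n <= 2 * min_shift_frames)
    stop("trace too short for the requested minimum shift")
  set.seed(seed)
  shifts <- sample.int(n - 2L * min_shift_frames, n_shuffles,
                       replace = TRUE) + min_shift_frames - 1L
  out <- matrix(0L, n_shuffles, n)
  for (s in seq_len(n_shuffles))
    out[s, ] <- rotate_vec(binary, shifts[s])
  attr(out, "shifts") <- shifts
  out
}

# Rotate x right by k frames (x[t] -> x[t+k], wrapped).
rotate_vec <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# Joint active-frame counts per bin for many circular shifts at once.
# bins: full-length bin index (NA = invalid); active_idx: frames where the
# unshifted cell is active. Returns an nb x n_shifts count matrix.
shifted_joint_counts <- function(bins, active_idx, shifts, nb) {
  n <- length(bins)
  ns <- length(shifts)
  if (length(active_idx) == 0L) return(matrix(0L, nb, ns))
  idx <- outer(active_idx - 1L, shifts, `+`) %% n + 1L  # n_active x ns
  bmat <- bins[idx]
  col <- rep(seq_len(ns) - 1L, each = length(active_idx))
  keep <- !is.na(bmat)
  counts <- tabulate(bmat[keep] + col[keep] * nb, nbins = nb * ns)
  matrix(counts, nb, ns)
}

#' Per-bin significance of a tuning map
#'
#' For each behavioral-state bin, compares the observed conditional activity
#' probability against the distribution obtained from `n_permutations`
#' circular permutations of the activity trace. The p-value is the fraction
#' of surrogate conditional values greater than or equal to the observed one,
#' with a plus-one correction so p is never 0. Bins with `p < alpha` make up
#' the significant field mask.
#'
#' @param binary 0/1 activity vector.
#' @param bins per-frame bin index from [bin_states()].
#' @param spec the matching [binning_spec()].
#' @param n_permutations number of circular permutations.
#' @param alpha per-bin significance level.
#' @param min_shift_frames minimum circular shift.
#' @param seed integer seed.
#' @return list with `p_values` (per bin, `NA` unvisited), `significant`
#'   (logical mask), `n_permutations`, `alpha`.
#' @export
per_bin_significance <- function(binary, bins, spec, n_permutations = 1000,
                                 alpha = 0.01, min_shift_frames = 900,
                                 seed = 1) {
  map <- compute_tuning_map(binary, bins, spec)
  n <- length(binary)
  set.seed(seed)
  shifts <- sample.int(n - 2L * min_shift_frames, n_permutations,
                       replace = TRUE) + min_shift_frames - 1L
  active_idx <- which(binary == 1L)
  nb <- n_states(spec)
  jc <- shifted_joint_counts(bins, active_idx, shifts, nb)
  cond_shuf <- jc / pmax(map$frames_per_bin, 1L)
  cond_obs <- map$conditional
  p <- rep(NA_real_, nb)
  vis <- map$frames_per_bin > 0
  ge <- rowSums(cond_shuf >= matrix(cond_obs, nb, n_permutations))
  p[vis] <- (ge[vis] + 1) / (n_permutations + 1)
  sig <- rep(FALSE, nb)
  sig[vis] <- ge[vis] / n_permutations < alpha
  list(p_values = p, significant = sig,
       n_permutations = n_permutations, alpha = alpha)
}

#' Mutual-information significance for one cell
#'
#' Computes the observed MI, a bootstrap distribution (frames resampled with
#' replacement, sample size `boot_frac` of the valid frames) and a
#' circular-shuffle null distribution. The cell is deemed significantly
#' modulated when the fraction of shuffled MI values greater than or equal
#' to the observed MI falls below `alpha` (so with 30 shuffles the verdict
#' requires the observed MI to beat every surrogate); the reported `p_value`
#' additionally carries a plus-one correction so it is never exactly 0. The
#' ranking score is the difference between mean bootstrap MI and mean
#' shuffled MI.
#'
#' @param binary 0/1 activity vector (full session).
#' @param bins per-frame bin index (`NA` = invalid frames).
#' @param spec the matching [binning_spec()].
#' @param n_boot,boot_frac bootstrap count and fraction of data per sample.
#' @param n_shuffles circular-shuffle count for the null.
#' @param alpha significance level.
#' @param min_shift_frames minimum circular shift in frames.
#' @param seed integer seed.
#' @return an object of class `"mi_result"`: list with `mi`, `mi_bootstrap`,
#'   `mi_shuffled`, `p_value`, `significant`, `rank_score`, `mi_per_event`,
#'   `n_events`, `p_active`.
#' @export
mi_significance <- function(binary, bins, spec, n_boot = 30, boot_frac = 0.5,
                            n_shuffles = 30, alpha = 0.01,
                            min_shift_frames = 900, seed = 1) {
  map <- compute_tuning_map(binary, bins, spec)
  mi <- mutual_information(map)
  valid_idx <- which(!is.na(bins))
  n_samp <- round(boot_frac * length(valid_idx))
  if (n_samp < 2) stop("too few valid frames for bootstrap")
  set.seed(seed)
  mi_boot <- vapply(seq_len(n_boot), function(b) {
    take <- sample(valid_idx, n_samp, replace = TRUE)
    nb <- n_states(spec)
    mi_from_counts(tabulate(bins[take], nbins = nb),
                   tabulate(bins[take][binary[take] == 1L], nbins = nb))
  }, numeric(1))
  n <- length(binary)
  shifts <- sample.int(n - 2L * min_shift_frames, n_shuffles,
                       replace = TRUE) + min_shift_frames - 1L
  active_idx <- which(binary == 1L)
  nbins_tab <- n_states(spec)
  jc <- shifted_joint_counts(bins, active_idx, shifts, nbins_tab)
  occ <- tabulate(bins[valid_idx], nbins = nbins_tab)
  mi_shuf <- vapply(seq_len(n_shuffles), function(s)
    mi_from_counts(occ, jc[, s]), numeric(1))
  r <- sum(mi_shuf >= mi)
  p <- (r + 1) / (n_shuffles + 1)
  n_events <- sum(diff(c(0L, binary)) == 1L)
  structure(list(mi = mi, mi_bootstrap = mi_boot, mi_shuffled = mi_shuf,
                 p_value = p, significant = r / n_shuffles < alpha,
                 rank_score = mean(mi_boot) - mean(mi_shuf),
                 mi_per_event = if (n_events > 0) mi / n_events else NA_real_,
                 n_events = n_events, p_active = map$p_active,
                 alpha = alpha),
            class = "mi_result")
}

#' Mutual information per binarized event
#'
#' @param mi mutual information in bits.
#' @param binary 0/1 activity vector; events are 0-to-1 transitions.
#' @return bits per binarized event.
#' @export
mi_per_event <- function(mi, binary) {
  n_events <- sum(diff(c(0L, binary)) == 1L)
  if (n_events == 0) stop("no binarized events in the session")
  mi / n_events
}

#' Direction-split mutual information on a linear track
#'
#' Computes spatial MI separately on left-run and right-run frames, tests
#' each against its own circular-shuffle null, and tests the left-right MI
#' difference with a bootstrap (frames resampled within each direction). The
#' cell is classed `"left"` or `"right"` when only that direction (or a
#' significant difference favoring it) is significant, `"bidirectional"`
#' when both directions are significant without a significant difference,
#' and `"untuned"` otherwise.
#'
#' @param binary 0/1 activity vector.
#' @param position1d per-frame track position (cm).
#' @param direction_label per-frame `"left"`/`"right"`/`"none"` labels.
#' @param spec a `position1d` [binning_spec()].
#' @param run_mask optional logical mask of locomotion frames.
#' @param n_boot,n_shuffles,alpha,min_shift_frames,seed as in
#'   [mi_significance()].
#' @return list with `mi_left`, `mi_right`, `delta_mi`, `p_left`, `p_right`,
#'   `p_delta`, `class`.
#' @export
directional_mi_split <- function(binary, position1d, direction_label, spec,
                                 run_mask = NULL, n_boot = 30,
                                 n_shuffles = 30, alpha = 0.01,
                                 min_shift_frames = 900, seed = 1) {
  if (!any(direction_label == "left") || !any(direction_label == "right"))
    stop("need frames in both traversal directions")
  keep <- if (is.null(run_mask)) rep(TRUE, length(binary)) else run_mask
  side_res <- lapply(c("left", "right"), function(side) {
    bins <- bin_states(position1d, spec,
                       mask = keep & direction_label == side)
    mi_significance(binary, bins, spec, n_boot = n_boot,
                    n_shuffles = n_shuffles, alpha = alpha,
                    min_shift_frames = min_shift_frames, seed = seed)
  })
  names(side_res) <- c("left", "right")
  delta_boot <- side_res$left$mi_bootstrap - side_res$right$mi_bootstrap
  qs <- quantile(delta_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  delta_sig <- qs[1] > 0 || qs[2] < 0
  sl <- side_res$left$significant; sr <- side_res$right$significant
  delta <- side_res$left$mi - side_res$right$mi
  cls <- if (sl && sr) {
    if (!delta_sig) "bidirectional" else if (delta > 0) "left" else "right"
  } else if (sl) "left" else if (sr) "right" else "untuned"
  list(mi_left = side_res$left$mi, mi_right = side_res$right$mi,
       delta_mi = delta, p_left = side_res$left$p_value,
       p_right = side_res$right$p_value,
       p_delta = if (delta_sig) 0 else 1, class = cls,
       left = side_res$left, right = side_res$right)
}

#' Score a whole population for modulation by one variable
#'
#' Runs [mi_significance()] (and optionally [per_bin_significance()]) for
#' every cell and returns a tidy per-cell table ordered by ranking score.
#'
#' @param binary_mat cells x frames 0/1 matrix.
#' @param bins per-frame bin index shared by all cells.
#' @param spec the matching [binning_spec()].
#' @param per_bin also compute the per-bin field mask and require at least
#'   one significant bin in the `modulated` verdict (conjunction).
#' @param ... passed to [mi_significance()].
#' @param seed integer seed; cell k uses `seed + k`.
#' @return data frame with one row per cell: `cell`, `mi`, `mi_per_event`,
#'   `p_value`, `significant`, `rank_score`, `p_active`, `modulated`.
#' @export
population_mi <- function(binary_mat, bins, spec, per_bin = FALSE, ...,
                          seed = 1) {
  n_cells <- nrow(binary_mat)
  rows <- lapply(seq_len(n_cells), function(k) {
    r <- mi_significance(binary_mat[k, ], bins, spec, ..., seed = seed + k)
    mod <- r$significant
    if (per_bin) {
      pb <- per_bin_significance(binary_mat[k, ], bins, spec,
                                 seed = seed + k)
      mod <- mod && any(pb$significant)
    }
    data.frame(cell = k, mi = r$mi, mi_per_event = r$mi_per_event,
               p_value = r$p_value, significant = r$significant,
               rank_score = r$rank_score, p_active = r$p_active,
               modulated = mod)
  })
  out <- do.call(rbind, rows)
  out[order(-out$rank_score), , drop = FALSE]
}
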