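# Cross-session cell matching and tuning-map stability over days.

#' Match cells across two sessions by footprint proximity
#'
#' Candidate pairs must have centroid distance below `max_dist_um` and
#' spatial-footprint correlation above `min_corr`; among candidates, a greedy
#' mutual-nearest-neighbor assignment (closest distance first) yields a
#' one-to-one matching. Footprints are assumed pre-aligned to a common
#' coordinate frame (identity alignment for synthetic data).
#'
#' @param centroids_a,centroids_b n x 2 matrices of cell centroids (um).
#' @param footprints_a,footprints_b optional lists of footprint weight
#'   matrices (identical dimensions across sessions); when omitted the
#'   correlation criterion is skipped.
#' @param max_dist_um maximum centroid distance (um).
#' @param min_corr minimum footprint correlation.
#' @return data frame with columns `cell_a`, `cell_b`, `dist_um`, `fp_corr`.
#' @export
match_cells <- function(centroids_a, centroids_b,
                        footprints_a = NULL, footprints_b = NULL,
                        max_dist_um = 12, min_corr = 0.65) {
  centroids_a <- as.matrix(centroids_a); centroids_b <- as.matrix(centroids_b)
  na <- nrow(centroids_a); nb <- nrow(centroids_b)
  if (na == 0L || nb == 0L) stop("empty session")
  d <- sqrt(outer(centroids_a[, 1], centroids_b[, 1], `-`)^2 +
              outer(centroids_a[, 2], centroids_b[, 2], `-`)^2)
  cand <- which(d < max_dist_um, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      dist_um = numeric(), fp_corr = numeric()))
  fp_corr <- rep(NA_real_, nrow(cand))
  if (!is.null(footprints_a) && !is.null(footprints_b)) {
    fp_corr <- vapply(seq_len(nrow(cand)), function(i)
      suppressWarnings(cor(as.numeric(footprints_a[[cand[i, 1]]]),
                           as.numeric(footprints_b[[cand[i, 2]]]))),
      numeric(1))
    keep <- !is.na(fp_corr) & fp_corr > min_corr
    cand <- cand[keep, , drop = FALSE]
    fp_corr <- fp_corr[keep]
  }
  ord <- order(d[cand])
  used_a <- logical(na); used_b <- logical(nb)
  rows <- list()
  for (i in ord) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      cell_a = ia, cell_b = ib, dist_um = d[ia, ib], fp_corr = fp_corr[i])
  }
  if (length(rows) == 0L)
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      dist_um = numeric(), fp_corr = numeric()))
  do.call(rbind, rows)
}

#' Cross-day tuning-map correlation with identity-shuffled null
#'
#' Pearson-correlates the smoothed tuning maps of matched cell pairs across
#' two sessions (pairwise-complete bins), and builds a null by permuting the
#' day-B cell identities among matched pairs (`n_shuffles` permutations).
#' Pairs with correlation above `stable_threshold` count as stable.
#'
#' @param maps_a,maps_b lists of [compute_tuning_map()] results (or
#'   pre-smoothed numeric vectors) on an identical [binning_spec()], indexed
#'   by cell.
#' @param pairs data frame with `cell_a`, `cell_b` (from [match_cells()]).
#' @param n_shuffles identity permutations for the null.
#' @param sigma_bins smoothing sigma when maps are unsmoothed `tuning_map`s.
#' @param stable_threshold stability criterion on the pair correlation.
#' @param seed integer seed.
#' @return list with `correlations` (per pair), `mean_correlation`,
#'   `fraction_stable`, `shuffle_means` (per permutation), `pairs`.
#' @export
cross_day_correlation <- function(maps_a, maps_b, pairs, n_shuffles = 30,
                                  sigma_bins = 3, stable_threshold = 0.3,
                                  seed = 1) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no matched pairs")
  getsm <- function(m) {
    if (inherits(m, "tuning_map")) {
      if (is.null(m$smoothed)) m <- smooth_map(m, sigma_bins)
      m$smoothed
    } else as.numeric(m)
  }
  sa <- lapply(maps_a, getsm); sb <- lapply(maps_b, getsm)
  pair_cor <- function(ia, ib) {
    x <- sa[[ia]]; y <- sb[[ib]]
    both <- !is.na(x) & !is.na(y)
    if (sum(both) < 3L) return(NA_real_)
    suppressWarnings(cor(x[both], y[both]))
  }
  rho <- mapply(pair_cor, pairs$cell_a, pairs$cell_b)
  set.seed(seed)
  shuffle_means <- vapply(seq_len(n_shuffles), function(s) {
    perm <- sample(pairs$cell_b)
    mean(mapply(pair_cor, pairs$cell_a, perm), na.rm = TRUE)
  }, numeric(1))
  list(correlations = rho,
       mean_correlation = mean(rho, na.rm = TRUE),
       fraction_stable = mean(rho > stable_threshold, na.rm = TRUE),
       shuffle_means = shuffle_means, pairs = pairs,
       stable_threshold = stable_threshold)
}
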