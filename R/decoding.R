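# Naive-Bayes maximum a posteriori reconstruction of behavioral state from
# binarized population activity.

#' Train a naive-Bayes decoder
#'
#' Estimates per-cell tuning curves `P(A_k | S_i)` and activity marginals
#' `P(A_k)` from the training frames, and attaches a uniform prior over the
#' bins visited during training. No prior assumption is made about location:
#' every visited bin receives equal prior probability.
#'
#' @param binary_mat cells x frames 0/1 matrix.
#' @param bins per-frame bin index (`NA` = invalid; typically already masked
#'   to locomotion frames).
#' @param spec the matching [binning_spec()].
#' @param train_mask logical vector selecting training frames.
#' @return an object of class `"decoder_model"`: `tuning` (cells x bins),
#'   `marginal` (per cell), `prior` (per bin, uniform over visited bins),
#'   `visited`, `spec`, `n_cells`.
#' @export
train_decoder <- function(binary_mat, bins, spec, train_mask) {
  stopifnot(ncol(binary_mat) == length(bins),
            length(train_mask) == length(bins))
  use <- train_mask & !is.na(bins)
  if (!any(use)) stop("no valid training frames")
  b <- bins[use]
  nb <- n_states(spec)
  occ_counts <- tabulate(b, nbins = nb)
  visited <- occ_counts > 0
  n_cells <- nrow(binary_mat)
  tuning <- matrix(NA_real_, n_cells, nb)
  marginal <- numeric(n_cells)
  for (k in seq_len(n_cells)) {
    a <- binary_mat[k, use]
    marginal[k] <- mean(a)
    act <- tabulate(b[a == 1L], nbins = nb)
    tuning[k, visited] <- act[visited] / occ_counts[visited]
  }
  prior <- ifelse(visited, 1 / sum(visited), 0)
  structure(list(tuning = tuning, marginal = marginal, prior = prior,
                 visited = visited, spec = spec, n_cells = n_cells,
                 occ_counts = occ_counts),
            class = "decoder_model")
}

#' Decode behavioral state per frame
#'
#' For each test frame, accumulates over the cells active in that frame the
#' log evidence `log(1 + P(A_k|S) P(S) / P(A_k))`, exponentiates, and
#' normalizes to a posterior over bins. Cells that were never active during
#' training carry no evidence and are skipped, as are inactive cells (the
#' binarized-activity reading of the independence product). Frames with no
#' active contributing cell fall back to the prior and are flagged.
#'
#' @param model a [train_decoder()] result.
#' @param binary_mat cells x frames 0/1 matrix (same cell order as training).
#' @param test_mask logical vector selecting frames to decode.
#' @return an object of class `"decoding_result"`: `posterior` (frames x
#'   bins, rows summing to 1), `map_bin` (argmax bin per frame, lowest-index
#'   tie-break), `frames` (decoded frame indices), `no_evidence` (logical).
#' @export
decode_frames <- function(model, binary_mat, test_mask) {
  stopifnot(inherits(model, "decoder_model"),
            nrow(binary_mat) == model$n_cells)
  frames <- which(test_mask)
  nb <- length(model$prior)
  usable <- model$marginal > 0
  logw <- matrix(0, model$n_cells, nb)
  vis <- model$visited
  for (k in which(usable)) {
    logw[k, vis] <- log(1 + model$tuning[k, vis] * model$prior[vis] /
                          model$marginal[k])
  }
  act <- binary_mat[usable, frames, drop = FALSE]
  logpost <- t(act) %*% logw[usable, , drop = FALSE]  # frames x bins
  no_evidence <- colSums(act) == 0
  logpost[, !vis] <- -Inf
  logpost[no_evidence, vis] <- 0  # falls back to the (uniform) prior
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  map_bin <- max.col(post, ties.method = "first")
  structure(list(posterior = post, map_bin = map_bin, frames = frames,
                 no_evidence = no_evidence, spec = model$spec),
            class = "decoding_result")
}

#' Temporal filtering of decoded posteriors
#'
#' Sliding-window mean of the log-posteriors (centered window of
#' `window_s * frame_rate_hz` frames rounded up to odd), renormalized per
#' frame, suppressing erratic frame-to-frame jumps of the decoded position.
#' `window_s = 0` is the identity.
#'
#' @param result a [decode_frames()] result (or bare posterior matrix).
#' @param window_s window length in seconds.
#' @param frame_rate_hz sampling rate in Hz.
#' @return the result with `posterior` and `map_bin` replaced (or the
#'   filtered matrix for a bare input).
#' @export
temporal_filter_posteriors <- function(result, window_s, frame_rate_hz = 30) {
  if (window_s < 0) stop("window_s must be >= 0")
  bare <- !inherits(result, "decoding_result")
  post <- if (bare) result else result$posterior
  w <- round(window_s * frame_rate_hz)
  if (w %% 2 == 0) w <- w + 1L
  if (window_s == 0 || w <= 1L) return(result)
  if (w > nrow(post)) stop("window longer than the decoded segment")
  lp <- log(pmax(post, 1e-300))
  half <- (w - 1L) %/% 2L
  n <- nrow(post)
  sm <- apply(lp, 2, function(col) {
    cs <- cumsum(col)
    lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
    (cs[hi] - cs[lo] + col[lo]) / (hi - lo + 1L)
  })
  sm <- sm - apply(sm, 1, max)
  out <- exp(sm)
  out <- out / rowSums(out)
  if (bare) return(out)
  result$posterior <- out
  result$map_bin <- max.col(out, ties.method = "first")
  if (!is.null(result$no_evidence)) {
    # a frame stays evidence-free only if its whole window was
    ne <- result$no_evidence
    cs <- cumsum(!ne)
    lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
    result$no_evidence <- (cs[hi] - cs[lo] + !ne[lo]) == 0L
  }
  result
}

#' Evaluate decoding against the actual trajectory
#'
#' Decoding error is the distance between decoded and actual bin centers:
#' absolute difference on a track, Euclidean distance in an open field.
#' Agreement is the fraction of frames whose exact bin was decoded. Frames
#' flagged as carrying no evidence (no active cell, posterior equal to the
#' prior) have no decoded estimate and are excluded by default; with
#' temporal filtering such frames inherit evidence from their window and
#' re-enter the evaluation.
#'
#' @param result a [decode_frames()] result.
#' @param actual_bins per-frame true bin index on the same clock as the full
#'   session (indexed by `result$frames`).
#' @param include_no_evidence also score flagged evidence-free frames (their
#'   decoded bin is the tie-break argmax of the prior).
#' @return list with `errors` (cm per frame), `mean_error`, `agreement`,
#'   `n_frames`.
#' @export
evaluate_decoding <- function(result, actual_bins,
                              include_no_evidence = FALSE) {
  act <- actual_bins[result$frames]
  keep <- !is.na(act)
  if (!include_no_evidence && !is.null(result$no_evidence))
    keep <- keep & !result$no_evidence
  if (!any(keep)) stop("no frames with decoded estimates to evaluate")
  dec <- result$map_bin[keep]; act <- act[keep]
  spec <- result$spec
  if (length(spec$n_bins) == 2L) {
    nx <- spec$n_bins[1]
    cx <- spec$centers[[1]]; cy <- spec$centers[[2]]
    dix <- (dec - 1L) %% nx + 1L; diy <- (dec - 1L) %/% nx + 1L
    aix <- (act - 1L) %% nx + 1L; aiy <- (act - 1L) %/% nx + 1L
    errors <- sqrt((cx[dix] - cx[aix])^2 + (cy[diy] - cy[aiy])^2)
  } else {
    ctr <- spec$centers[[1]]
    errors <- abs(ctr[dec] - ctr[act])
  }
  list(errors = errors, mean_error = mean(errors),
       agreement = mean(dec == act), n_frames = length(errors))
}

#' Decoding score
#'
#' Chance-normalized improvement of the decoder over its shuffled-tuning
#' control: `(mean shuffled error - mean actual error) / environment length`.
#' Dimensionless, hence invariant to the length unit.
#'
#' @param mean_error,shuffled_mean_error mean decoding errors (cm).
#' @param length_cm track length, or arena side for an open field.
#' @return the decoding score.
#' @export
decoding_score <- function(mean_error, shuffled_mean_error, length_cm) {
  stopifnot_scalar_pos(length_cm, "length_cm")
  (shuffled_mean_error - mean_error) / length_cm
}

#' Alternating-block train/test split
#'
#' Assigns alternating blocks (10 s by default) to training and testing so
#' both halves sample the whole session; a contiguous first-half/second-half
#' split is available via `style = "contiguous"`.
#'
#' @param n_frames session length in frames.
#' @param frame_rate_hz sampling rate.
#' @param block_s block length in seconds.
#' @param style `"blocks"` or `"contiguous"`.
#' @return list of logical vectors `train` and `test` (disjoint, covering).
#' @export
train_test_split <- function(n_frames, frame_rate_hz = 30, block_s = 10,
                             style = c("blocks", "contiguous")) {
  style <- match.arg(style)
  if (style == "contiguous") {
    half <- n_frames %/% 2L
    train <- c(rep(TRUE, half), rep(FALSE, n_frames - half))
  } else {
    block <- max(1L, round(block_s * frame_rate_hz))
    train <- ((seq_len(n_frames) - 1L) %/% block) %% 2L == 0L
  }
  list(train = train, test = !train)
}

#' Bootstrap population decoding
#'
#' Draws `n_boot` bootstrap samples of `cells_per_sample` cells (with
#' replacement) from the population passing the activity filter
#' `P(A) > cell_filter_pa_min`, trains on half the frames and decodes the
#' other half, optionally replacing each training activity vector by one
#' circular surrogate (shuffled-tuning control). Locomotion masking is
#' assumed already encoded in `bins` (invalid frames are `NA`).
#'
#' @param binary_mat cells x frames 0/1 matrix.
#' @param bins per-frame bin index.
#' @param spec the matching [binning_spec()].
#' @param actual_bins per-frame true bin index used for scoring (defaults to
#'   `bins`).
#' @param cells_per_sample cells per bootstrap sample (paper panels use 40,
#'   60, 80 or 100).
#' @param n_boot number of bootstrap samples.
#' @param shuffle_control replace training activity by circular surrogates.
#' @param cell_filter_pa_min minimum P(A) for a cell to enter the pool.
#' @param window_s temporal filtering window (0 = off).
#' @param frame_rate_hz sampling rate.
#' @param block_s train/test block length.
#' @param min_shift_frames minimum circular shift for the control.
#' @param seed integer seed.
#' @return data frame with one row per bootstrap sample: `sample_id`,
#'   `n_cells`, `mean_error_cm`, `agreement`, `shuffled`.
#' @export
bootstrap_decode <- function(binary_mat, bins, spec, actual_bins = bins,
                             cells_per_sample = 60, n_boot = 30,
                             shuffle_control = FALSE,
                             cell_filter_pa_min = 0.001, window_s = 0,
                             frame_rate_hz = 30, block_s = 10,
                             min_shift_frames = 900, seed = 1) {
  pa <- rowMeans(binary_mat)
  pool <- which(pa > cell_filter_pa_min)
  if (length(pool) == 0L) stop("no cells pass the activity filter")
  n_frames <- ncol(binary_mat)
  split <- train_test_split(n_frames, frame_rate_hz, block_s)
  set.seed(seed)
  rows <- lapply(seq_len(n_boot), function(s) {
    cells <- sample(pool, cells_per_sample, replace = TRUE)
    sub <- binary_mat[cells, , drop = FALSE]
    train_sub <- sub
    if (shuffle_control) {
      shifts <- sample.int(n_frames - 2L * min_shift_frames,
                           length(cells), replace = TRUE) +
        min_shift_frames - 1L
      for (k in seq_along(cells))
        train_sub[k, ] <- rotate_vec(sub[k, ], shifts[k])
    }
    model <- train_decoder(train_sub, bins, spec, split$train)
    res <- decode_frames(model, sub, split$test & !is.na(bins))
    if (window_s > 0)
      res <- temporal_filter_posteriors(res, window_s, frame_rate_hz)
    ev <- evaluate_decoding(res, actual_bins)
    data.frame(sample_id = s, n_cells = cells_per_sample,
               mean_error_cm = ev$mean_error, agreement = ev$agreement,
               shuffled = shuffle_control)
  })
  do.call(rbind, rows)
}
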