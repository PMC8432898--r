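# Naive-Bayes decoder: training, posteriors, filtering, evaluation.

# Small deterministic setup: 3 cells, 4 bins.
toy_setup <- function() {
  spec <- binning_spec("position1d", lt_arena(4), n_bins = 4,
                       limits = c(0, 4))
  bins <- rep(1:4, each = 25)
  B <- rbind(as.integer(bins == 1L),
             as.integer(bins %in% c(1L, 2L)),
             rep(c(1L, 0L), 50))
  list(spec = spec, bins = bins, B = B)
}

test_that("training tallies tuning curves and marginals exactly", {
  s <- toy_setup()
  m <- train_decoder(s$B, s$bins, s$spec, rep(TRUE, 100))
  expect_equal(m$tuning[1, ], c(1, 0, 0, 0))
  expect_equal(m$tuning[2, ], c(1, 1, 0, 0))
  expect_equal(m$marginal, c(0.25, 0.5, 0.5))
  expect_equal(m$prior, rep(0.25, 4))
  # random small session against a brute-force tally
  set.seed(5)
  bins <- sample(1:4, 300, replace = TRUE)
  B <- matrix(rbinom(600, 1, 0.3), 2)
  tm <- rep(c(TRUE, FALSE), 150)
  mod <- train_decoder(B, bins, s$spec, tm)
  for (k in 1:2) for (i in 1:4) {
    expect_equal(mod$tuning[k, i],
                 sum(B[k, tm] == 1 & bins[tm] == i) / sum(bins[tm] == i))
  }
})

test_that("posteriors follow the printed log-sum form and normalize", {
  s <- toy_setup()
  m <- train_decoder(s$B, s$bins, s$spec, rep(TRUE, 100))
  res <- decode_frames(m, s$B, rep(TRUE, 100))
  expect_row_stochastic(res$posterior)
  # hand-computed oracle: per frame, prod over active cells of
  # (1 + P(A_k|S) P(S) / P(A_k)), renormalized
  for (f in c(1, 30, 60, 99)) {
    active <- which(s$B[, f] == 1L)
    w <- rep(1, 4)
    for (k in active) w <- w * (1 + m$tuning[k, ] * m$prior / m$marginal[k])
    if (length(active) > 0) {
      expect_equal(res$posterior[f, ], w / sum(w), tolerance = 1e-12)
    }
  }
  # an indicator cell firing alone pins the posterior on its bin
  expect_equal(res$map_bin[1], 1L)
  # no active cell: posterior is the uniform prior, frame flagged
  idle <- decode_frames(m, matrix(0L, 3, 5), rep(TRUE, 5))
  expect_true(all(idle$no_evidence))
  expect_equal(idle$posterior[1, ], rep(0.25, 4))
  expect_equal(idle$map_bin, rep(1L, 5))  # lowest-index tie-break
})

test_that("uniform tuning decodes to the first bin by tie-break", {
  spec <- binning_spec("position1d", lt_arena(4), n_bins = 4,
                       limits = c(0, 4))
  bins <- rep(1:4, each = 10)
  B <- matrix(1L, 2, 40)  # always active everywhere: flat tuning
  m <- train_decoder(B, bins, spec, rep(TRUE, 40))
  res <- decode_frames(m, B, rep(TRUE, 40))
  expect_true(all(abs(res$posterior - 0.25) < 1e-12))
  expect_true(all(res$map_bin == 1L))
})

test_that("temporal filtering is an identity at window <= 1 frame and a
           fixed point on constant posteriors", {
  s <- toy_setup()
  m <- train_decoder(s$B, s$bins, s$spec, rep(TRUE, 100))
  res <- decode_frames(m, s$B, rep(TRUE, 100))
  same <- temporal_filter_posteriors(res, 0, 30)
  expect_identical(same$posterior, res$posterior)
  one <- temporal_filter_posteriors(res, 1 / 30, 30)
  expect_equal(one$posterior, res$posterior, tolerance = 1e-12)
  cst <- res; cst$posterior <- matrix(0.25, 100, 4)
  flt <- temporal_filter_posteriors(cst, 0.5, 30)
  expect_true(all(abs(flt$posterior - 0.25) < 1e-12))
  expect_row_stochastic(flt$posterior)
  expect_error(temporal_filter_posteriors(res, 100, 30), "window")
})

test_that("temporal filtering reduces erratic decoded jumps", {
  set.seed(9)
  a <- lt_arena()
  spec <- binning_spec("position1d", a)
  tr <- simulate_trajectory(a, 600, 30, seed = 71)
  tuns <- make_place_cells(40, a, seed = 72)
  B <- do.call(rbind, lapply(seq_along(tuns), function(k)
    generate_binary_activity(tr, tuns[[k]], seed = 73 + k)$binary))
  run <- running_mask(tr$velocity)
  bins <- bin_states(tr$head_x, spec, mask = run)
  sp <- train_test_split(length(bins))
  m <- train_decoder(B, bins, spec, sp$train & !is.na(bins))
  res <- decode_frames(m, B, sp$test & !is.na(bins))
  flt <- temporal_filter_posteriors(res, 0.5, 30)
  jumps <- function(r) sum(abs(diff(r$map_bin)) > 3)
  expect_lt(jumps(flt), jumps(res))
  expect_row_stochastic(flt$posterior)
})

test_that("decoding errors use bin-center geometry", {
  s <- toy_setup()
  m <- train_decoder(s$B, s$bins, s$spec, rep(TRUE, 100))
  res <- decode_frames(m, s$B, rep(TRUE, 100))
  res$map_bin <- s$bins[res$frames]  # force perfect decoding
  res$no_evidence[] <- FALSE
  ev <- evaluate_decoding(res, s$bins)
  expect_equal(ev$mean_error, 0)
  expect_equal(ev$agreement, 1)
  # 2D: decoded (0,0)-bin vs actual 3 bins right, 4 bins up on 1-cm bins
  spec2 <- binning_spec("position2d", arena_spec("open_field", 17, 17))
  fake <- structure(list(map_bin = 1L, frames = 1L, no_evidence = FALSE,
                         spec = spec2), class = "decoding_result")
  actual <- 4L + 4L * 17L  # bin (4, 5): +3 in x, +4 in y
  ev2 <- evaluate_decoding(fake, actual)
  expect_equal(ev2$mean_error, 5)
})

test_that("decoding score is the chance-normalized error difference", {
  expect_equal(decoding_score(10, 33.3, 100), 0.233)
  expect_equal(decoding_score(20, 20, 100), 0)
  # unit invariance: cm and m give the same score
  expect_equal(decoding_score(10, 30, 100), decoding_score(0.1, 0.3, 1))
})

test_that("a noiseless tiling population decodes perfectly", {
  a <- lt_arena()
  spec <- binning_spec("position1d", a)
  tr <- simulate_trajectory(a, 900, 30, seed = 81)
  bins <- bin_states(tr$head_x, spec)
  B <- do.call(rbind, lapply(1:34, function(k) as.integer(bins == k)))
  sp <- train_test_split(length(bins))
  m <- train_decoder(B, bins, spec, sp$train)
  res <- decode_frames(m, B, sp$test)
  ev <- evaluate_decoding(res, bins)
  expect_equal(ev$mean_error, 0)
  expect_equal(ev$agreement, 1)
})

test_that("bootstrap decoding beats its shuffled control and scales with
           population size", {
  a <- lt_arena()
  spec <- binning_spec("position1d", a)
  ses_tuns <- make_place_cells(60, a, seed = 91)
  tr <- simulate_trajectory(a, 600, 30, seed = 92)
  B <- do.call(rbind, lapply(seq_along(ses_tuns), function(k)
    generate_binary_activity(tr, ses_tuns[[k]], seed = 93 + k)$binary))
  run <- running_mask(tr$velocity)
  bins <- bin_states(tr$head_x, spec, mask = run)
  act <- bootstrap_decode(B, bins, spec, cells_per_sample = 60, n_boot = 6,
                          min_shift_frames = 600, seed = 94)
  shf <- bootstrap_decode(B, bins, spec, cells_per_sample = 60, n_boot = 6,
                          shuffle_control = TRUE, min_shift_frames = 600,
                          seed = 95)
  expect_true(all(act$mean_error_cm < shf$mean_error_cm))
  # with the track temporal filter, median error decreases monotonically as
  # the bootstrap sample grows
  med <- vapply(c(8, 40, 100), function(nc)
    median(bootstrap_decode(B, bins, spec, cells_per_sample = nc,
                            n_boot = 10, window_s = 0.5,
                            min_shift_frames = 600,
                            seed = 96)$mean_error_cm), numeric(1))
  expect_true(all(diff(med) < 0))
  # degenerate bootstrap: the whole population once, no replacement noise
  expect_error(bootstrap_decode(B * 0L, bins, spec), "activity filter")
})
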