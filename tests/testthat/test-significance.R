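# Mutual information, permutation nulls, modulation verdicts.

test_that("mutual information matches the brute-force double sum", {
  set.seed(12)
  spec6 <- binning_spec("position1d", lt_arena(), n_bins = 6,
                       limits = c(0, 6))
  for (rep in 1:50) {
    tab <- random_joint_table(6)
    map <- map_from_probs(tab$occupancy, tab$joint, spec6)
    expect_equal(mutual_information(map),
                 mi_bruteforce(tab$occupancy, tab$joint),
                 tolerance = 1e-12)
  }
})

test_that("analytic MI cases: independence gives 0, a fair indicator 1 bit", {
  spec2 <- binning_spec("position1d", lt_arena(), n_bins = 2,
                        limits = c(0, 2))
  # exact independence: joint = occupancy * marginal
  occ <- c(0.3, 0.7); pa <- 0.2
  ind <- map_from_probs(occ, occ * pa, spec2)
  expect_equal(mutual_information(ind), 0, tolerance = 1e-12)
  # two equal-occupancy bins, active iff bin 1: H(A) = 1, H(A|S) = 0
  det <- map_from_probs(c(0.5, 0.5), c(0.5, 0), spec2)
  expect_equal(mutual_information(det), 1, tolerance = 1e-12)
})

test_that("MI is nonnegative and bounded by log2(M) on random maps", {
  set.seed(13)
  for (nb in c(2, 5, 17)) {
    spec <- binning_spec("position1d", lt_arena(), n_bins = nb,
                         limits = c(0, nb))
    for (rep in 1:20) {
      tab <- random_joint_table(nb)
      mi <- mutual_information(map_from_probs(tab$occupancy, tab$joint, spec))
      expect_gte(mi, 0)
      expect_lte(mi, log2(nb) + 1e-12)
    }
  }
})

test_that("circular surrogates conserve activity and destroy tuning", {
  set.seed(3)
  b <- rbinom(5000, 1, 0.05)
  sh <- circular_shuffle(b, 25, min_shift_frames = 100, seed = 4)
  expect_equal(dim(sh), c(25L, 5000L))
  expect_true(all(rowSums(sh) == sum(b)))
  expect_identical(septune:::rotate_vec(b, 0L), b)
  expect_identical(septune:::rotate_vec(septune:::rotate_vec(b, 137L), 5000L - 137L), b)
  expect_error(circular_shuffle(b, 0, 100), "n_shuffles")
  expect_error(circular_shuffle(b[1:50], 5, 100), "short")
  # a strongly tuned place cell beats at least 99% of 300 surrogates
  tr <- short_track(21, 900)
  run <- running_mask(tr$velocity)
  spec <- binning_spec("position2d", of_arena())
  bins <- bin_states(cbind(tr$head_x, tr$head_y), spec, mask = run)
  act <- generate_binary_activity(
    tr, cell_tuning("position2d", center_cm = c(20, 25), width_cm = 7,
                    p_in_field = 0.2), seed = 5)
  r <- mi_significance(act$binary, bins, spec, n_shuffles = 300, seed = 6)
  expect_gte(mean(r$mi > r$mi_shuffled), 0.99)
})

test_that("per-bin test flags exactly the bin holding the activity", {
  set.seed(7)
  spec <- binning_spec("position1d", lt_arena(), n_bins = 8,
                       limits = c(0, 8))
  bins <- sample(1:8, 6000, replace = TRUE)
  binary <- as.integer(bins == 3L & runif(6000) < 0.4)
  res <- per_bin_significance(binary, bins, spec, n_permutations = 300,
                              min_shift_frames = 500, seed = 8)
  expect_true(res$significant[3])
  expect_true(all(!res$significant[-3]))
  expect_true(all(res$p_values > 0, na.rm = TRUE))
})

test_that("MI verdict: invariant cells are null, tuned cells significant", {
  spec <- binning_spec("position1d", lt_arena(), n_bins = 4,
                       limits = c(0, 4))
  bins <- rep(1:4, 2500)
  # all-active vector is identical under any rotation: rank score 0
  allon <- rep(1L, 10000)
  r0 <- mi_significance(allon, bins, spec, seed = 2)
  expect_equal(r0$rank_score, 0, tolerance = 1e-12)
  expect_false(r0$significant)
  # strong synthetic place cell at session scale
  tr <- simulate_trajectory(lt_arena(), 900, 30, seed = 31)
  run <- running_mask(tr$velocity)
  lspec <- binning_spec("position1d", lt_arena())
  lbins <- bin_states(tr$head_x, lspec, mask = run)
  act <- generate_binary_activity(
    tr, cell_tuning("position1d", center_cm = 40, width_cm = 7,
                    p_in_field = 0.2, p_baseline = 0.005), seed = 32)
  r1 <- mi_significance(act$binary, lbins, lspec, seed = 33)
  expect_true(r1$significant)
  expect_gt(r1$rank_score, 0)
  # bootstrap consistency: mean bootstrap MI near the full-data MI
  se <- sd(r1$mi_bootstrap)
  expect_lt(abs(mean(r1$mi_bootstrap) - r1$mi), 3 * se)
})

test_that("MI per binarized event scales inversely with event count", {
  expect_equal(mi_per_event(0.05, rep(c(1L, 0L), 500)), 1e-4)
  b1 <- c(rep(c(1L, 0L, 0L, 0L), 125), rep(0L, 500))
  b2 <- rep(c(1L, 0L, 0L, 0L), 250)
  expect_equal(mi_per_event(0.05, b1), 2 * mi_per_event(0.05, b2))
  expect_error(mi_per_event(0.05, rep(0L, 100)), "no binarized events")
})

test_that("direction-split MI classifies gated and agnostic cells", {
  a <- lt_arena()
  tr <- simulate_trajectory(a, 900, 30, seed = 41)
  run <- running_mask(tr$velocity)
  spec <- binning_spec("position1d", a)
  left_cell <- generate_binary_activity(
    tr, cell_tuning("position1d", center_cm = 50, width_cm = 7,
                    p_in_field = 0.25, p_baseline = 0.003,
                    direction_gate = "left"), seed = 42)
  res <- directional_mi_split(left_cell$binary, tr$head_x,
                              tr$direction_label, spec, run_mask = run,
                              seed = 43)
  expect_equal(res$class, "left")
  expect_gt(res$mi_left, res$mi_right)
  # swapping the labels swaps the classification
  swapped <- c(left = "right", right = "left",
               none = "none")[tr$direction_label]
  res_sw <- directional_mi_split(left_cell$binary, tr$head_x, swapped, spec,
                                 run_mask = run, seed = 43)
  expect_equal(res_sw$class, "right")
  # a direction-agnostic place cell shows a small, nonsignificant difference
  both <- generate_binary_activity(
    tr, cell_tuning("position1d", center_cm = 50, width_cm = 7,
                    p_in_field = 0.25, p_baseline = 0.003), seed = 44)
  res_b <- directional_mi_split(both$binary, tr$head_x, tr$direction_label,
                                spec, run_mask = run, seed = 45)
  expect_equal(res_b$class, "bidirectional")
})

test_that("permutation p-values are roughly uniform under the null", {
  # Kolmogorov distance of null p-values from U(0,1); coarse bound because
  # the p grid is discrete at n_shuffles = 60
  tr <- short_track(51, 300)
  spec <- binning_spec("position2d", of_arena())
  bins <- bin_states(cbind(tr$head_x, tr$head_y), spec)
  set.seed(52)
  ps <- vapply(1:60, function(k)
    mi_significance(rbinom(nrow(tr), 1, 0.02), bins, spec, n_shuffles = 60,
                    min_shift_frames = 300, seed = 100 + k)$p_value,
    numeric(1))
  grid <- seq(0.05, 0.95, by = 0.05)
  ks <- max(abs(vapply(grid, function(g) mean(ps <= g), numeric(1)) - grid))
  expect_lt(ks, 0.2)
  expect_true(all(ps > 0))
})

test_that("population scoring orders cells by rank score", {
  tr <- short_track(61, 300)
  spec <- binning_spec("position2d", of_arena())
  run <- running_mask(tr$velocity)
  bins <- bin_states(cbind(tr$head_x, tr$head_y), spec, mask = run)
  B <- rbind(
    generate_binary_activity(tr, cell_tuning("position2d",
      center_cm = c(15, 15), width_cm = 7, p_in_field = 0.3), seed = 1)$binary,
    rbinom(nrow(tr), 1, 0.02))
  tab <- population_mi(B, bins, spec, min_shift_frames = 2000, seed = 3)
  expect_equal(tab$cell[1], 1)
  expect_true(tab$rank_score[1] > tab$rank_score[2])
  expect_named(tab, c("cell", "mi", "mi_per_event", "p_value", "significant",
                      "rank_score", "p_active", "modulated"))
})
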