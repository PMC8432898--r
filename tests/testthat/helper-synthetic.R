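# Shared synthetic fixtures, built in code at test time.

# Short open-field session fixture: one trajectory reused across tests that
# only need realistic behavior, not a specific cell.
of_arena <- function() arena_spec("open_field", 45, 45)
lt_arena <- function(L = 100) arena_spec("linear_track", track_length_cm = L)

short_track <- function(seed = 101, duration_s = 120,
                        arena = of_arena()) {
  simulate_trajectory(arena, duration_s, 30, seed = seed)
}

# Independent brute-force MI oracle: explicit double sum over states and the
# two activity levels, no shared code with mi_from_probs.
mi_bruteforce <- function(occupancy, joint) {
  pa <- sum(joint)
  pj <- rbind(joint, occupancy - joint)      # rows: active, inactive
  pmarg <- c(pa, 1 - pa)
  total <- 0
  for (i in seq_along(occupancy)) {
    for (j in 1:2) {
      if (pj[j, i] > 0 && occupancy[i] > 0 && pmarg[j] > 0)
        total <- total + pj[j, i] *
          log2(pj[j, i] / (occupancy[i] * pmarg[j]))
    }
  }
  unname(total)
}

# Random valid (occupancy, joint) pair over nb bins.
random_joint_table <- function(nb) {
  occ <- runif(nb); occ <- occ / sum(occ)
  joint <- occ * runif(nb)
  list(occupancy = occ, joint = joint)
}

# Build a tuning_map object directly from probability vectors (exact tables,
# bypassing frame counting) for analytic MI cases.
map_from_probs <- function(occupancy, joint, spec) {
  structure(list(spec = spec, occupancy = occupancy, joint = joint,
                 conditional = ifelse(occupancy > 0, joint / occupancy,
                                      NA_real_),
                 frames_per_bin = round(occupancy * 1e6),
                 M = sum(occupancy > 0), n_valid = 1e6,
                 p_active = sum(joint)),
            class = "tuning_map")
}

expect_row_stochastic <- function(post, tol = 1e-9) {
  expect_true(all(abs(rowSums(post) - 1) < tol))
}
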