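test_that("geometry generator honours its size and determinism contracts", {
  brain <- generate_geometry(600, 64, seed = 1)
  expect_equal(dim(brain$atlas_coords), c(600, 3))
  expect_equal(dim(brain$electrode_coords), c(64, 3))
  expect_equal(length(brain$electrode_to_region), 64)
  expect_true(all(brain$electrode_to_region %in% 1:600))
  # bit-identical repetition
  brain2 <- generate_geometry(600, 64, seed = 1)
  expect_identical(brain$electrode_coords, brain2$electrode_coords)
  expect_identical(brain$atlas_coords, brain2$atlas_coords)
  # all pairwise electrode distances positive
  expect_gt(min(dist(brain$electrode_coords)), 0)
  expect_error(generate_geometry(50, 60, seed = 1),
               class = "memfc_error_invalid")
  expect_error(generate_geometry(8, 4, seed = 1),
               class = "memfc_error_invalid")
})

test_that("electrode patches sit at ~10 mm grid pitch", {
  brain <- generate_geometry(50, 20, seed = 7)
  D <- as.matrix(dist(brain$electrode_coords))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_equal(median(nn), 10, tolerance = 0.15)
})

test_that("structural connectome decays with distance and obeys limits", {
  brain <- small_brain(seed = 2)
  con <- generate_structural_connectome(brain, decay_mm = 20, density = 0.5,
                                        max_count = 200, seed = 3)
  expect_true(all(con$counts >= 0))
  expect_equal(con$counts, t(con$counts))
  expect_true(all(diag(con$counts) == 0))
  D <- distance_matrix(con$centroids)
  du <- upper_tri_vec(D); cu <- upper_tri_vec(con$counts)
  expect_lt(cor(du[cu > 0], cu[cu > 0], method = "spearman"), 0)
  # density 1 with huge decay length connects everything
  con_full <- generate_structural_connectome(brain, decay_mm = 1e9, density = 1,
                                             max_count = 50, seed = 4)
  expect_true(all(upper_tri_vec(con_full$counts) > 0))
  # near-zero density leaves the matrix near-empty
  con_empty <- generate_structural_connectome(brain, decay_mm = 30,
                                              density = 1e-9, max_count = 50,
                                              seed = 5)
  expect_equal(sum(con_empty$counts), 0)
  expect_error(generate_structural_connectome(brain, decay_mm = -1),
               class = "memfc_error_invalid")
  expect_error(generate_structural_connectome(brain, density = 0),
               class = "memfc_error_invalid")
})

test_that("planted ground truth tracks structure and hits the target rate", {
  brain <- small_brain(seed = 6)
  con <- generate_structural_connectome(brain, seed = 7)
  reg <- brain$electrode_to_region
  mem <- derive_ground_truth_mem(con, reg, coupling_scale = 0.5,
                                 target_rate = 0.5, noise_sd = 0.01, seed = 8,
                                 calib_rounds = 15)
  expect_identical(mem$convention, "zero_one")
  # planted-coupling recoverability by construction
  L <- con$normalized[reg, reg]; diag(L) <- 0
  expect_gt(cor(upper_tri_vec(mem$J), upper_tri_vec(L)), 0.9)
  # unconnected pair carries only the noise term
  zero_pair <- which(L == 0 & upper.tri(L), arr.ind = TRUE)[1, ]
  expect_lt(abs(mem$J[zero_pair[1], zero_pair[2]]), 5 * 0.01)
  # activation close to target under the model
  st <- sample_states(mem, 10000, "metropolis", seed = 9, burn_in = 500,
                      thin = 3)
  expect_equal(mean(st$states), 0.5, tolerance = 0.05)
  # coupling_scale 0 plants an independent-unit model up to noise
  mem0 <- derive_ground_truth_mem(con, reg, coupling_scale = 0,
                                  target_rate = 0.3, noise_sd = 0, seed = 10)
  expect_equal(max(abs(mem0$J)), 0)
})

test_that("exact state sampling matches enumerated probabilities", {
  m <- random_mem(3, seed = 16)
  st <- sample_states(m, 5e4, "exact", seed = 17)
  d <- exact_distribution(m)
  key <- colSums(st$states * 2^(0:2)) + 1
  emp <- tabulate(key, 8) / ncol(st$states)
  se <- sqrt(d$p * (1 - d$p) / 5e4)
  expect_true(all(abs(emp - d$p) < 3.5 * se + 1e-9))
  # single free unit is a fair coin
  m1 <- mem_params(0, matrix(0, 1, 1))
  s1 <- sample_states(m1, 2e4, "exact", seed = 18)
  expect_equal(mean(s1$states), 0.5, tolerance = 0.02)
  expect_error(sample_states(mem_params(numeric(21), matrix(0, 21, 21)), 10,
                             "exact"),
               class = "memfc_error_capability")
})

test_that("synthesized recordings carry band power where states are on", {
  # single channel always-on in alpha: alpha power dominates theta
  st <- matrix(1L, 1, 60)
  rec <- synthesize_recording(st, band = c(8, 13), fs = 100, state_dt = 0.25,
                              noise = list(reference_amp = 0,
                                           local_shared_amp = 0,
                                           pink_amp = 0), seed = 19)
  bp <- wavelet_band_power(rec, default_bands()[1:2, ], window_s = 10)
  expect_gt(mean(bp$alpha$power), 10 * mean(bp$theta$power))
  # all-off states with zero noise: near-silent channels (off_level only)
  rec0 <- synthesize_recording(matrix(0L, 2, 60), band = c(8, 13), fs = 100,
                               state_dt = 0.25,
                               noise = list(reference_amp = 0,
                                            local_shared_amp = 0,
                                            pink_amp = 0), seed = 20)
  expect_lt(sd(rec0$signal), 0.25)
  expect_error(synthesize_recording(st, band = c(8, 30), fs = 50),
               class = "memfc_error_invalid")
})

test_that("planted states survive the forward model and state reconstruction", {
  set.seed(21)
  N <- 6; Tst <- 1200; state_dt <- 0.25; fs <- 100
  st <- matrix(rbinom(N * Tst, 1, 0.5), N, Tst)
  rec <- synthesize_recording(st, band = c(8, 13), fs = fs,
                              state_dt = state_dt, seed = 22)
  bp <- wavelet_band_power(rec,
                           tibble::tibble(band = "alpha", low = 8, high = 13),
                           window_s = 100)
  rst <- binarize_power(bp[[1]], threshold = 0, downsample = 10)
  kept_t <- seq(10, ncol(bp[[1]]$power), by = 10) / fs
  idx <- pmin(ceiling(kept_t / state_dt), Tst)
  agreement <- mean(rst$states == st[, idx])
  expect_gt(agreement, 0.8)
})
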