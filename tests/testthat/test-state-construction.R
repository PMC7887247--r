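test_that("montages behave as re-referencing schemes should", {
  set.seed(1)
  fs <- 200; S <- 1500; N <- 8
  coords <- cbind(seq_len(N) * 10, 0, 0)
  common <- sin(2 * pi * 7 * seq_len(S) / fs)
  rec <- recording(matrix(rep(common, each = N), N, S) +
                     1e-8 * matrix(rnorm(N * S), N, S), fs, coords = coords)
  # identical common signal -> global regression leaves ~nothing
  rg <- apply_montage(rec, "global")
  expect_lt(max(abs(rg$signal)), 1e-6)
  expect_identical(rg$montage, "global_mean_regressed")
  # referential montage is the identity
  rr <- apply_montage(rec, "referential")
  expect_identical(rr$signal, rec$signal)
  # global regression is idempotent
  set.seed(2)
  recn <- recording(matrix(rnorm(N * S), N, S) +
                      matrix(rep(common, each = N), N, S), fs, coords = coords)
  g1 <- apply_montage(recn, "global")
  g2 <- apply_montage(g1, "global")
  expect_equal(g1$signal, g2$signal, tolerance = 1e-8)
})

test_that("local montage isolates a channel's private signal", {
  set.seed(3)
  fs <- 200; S <- 2000
  coords <- cbind(c(0, 10, 20, 10, 10, 40, 50, 60),
                  c(0, 0, 0, 10, -10, 0, 0, 0), 0)
  X <- matrix(rnorm(8 * S), 8, S)
  tone <- sin(2 * pi * 11 * seq_len(S) / fs)
  X[3, ] <- 0.5 * (X[1, ] + X[2, ] + X[4, ] + X[5, ]) + tone
  rl <- apply_montage(recording(X, fs, coords = coords), "local")
  expect_gt(cor(rl$signal[3, ], tone), 0.99)
  expect_error(apply_montage(recording(X[1:3, ], fs, coords = coords[1:3, ]),
                             "local"),
               class = "memfc_error_invalid")
})

test_that("wavelet band power localizes oscillations in the right band", {
  fs <- 200
  x <- sin(2 * pi * 10 * seq_len(fs * 120) / fs)
  bp <- wavelet_band_power(recording(matrix(x, 1), fs),
                           default_bands()[1:4, ], window_s = 100)
  pw <- vapply(bp, function(b) mean(b$power), numeric(1))
  expect_gt(pw["alpha"], 10 * pw["theta"])
  expect_gt(pw["alpha"], 10 * pw["beta"])
  # zero signal -> zero power (plus numerically negligible leakage)
  bp0 <- wavelet_band_power(recording(matrix(0 * x + 1e-30, 1), fs),
                            default_bands()[1:2, ], window_s = 100)
  expect_lt(max(bp0$theta$power), 1e-40)
  # band above Nyquist rejected
  expect_error(wavelet_band_power(recording(matrix(x, 1), fs), default_bands()),
               class = "memfc_error_invalid")
})

test_that("white-noise band power grows with band width", {
  set.seed(4)
  fs <- 400
  x <- rnorm(fs * 150)
  bp <- wavelet_band_power(recording(matrix(x, 1), fs), default_bands(),
                           window_s = 100)
  pw <- vapply(bp, function(b) mean(b$power), numeric(1))
  widths <- default_bands()$high - default_bands()$low
  expect_true(all(diff(pw) > 0))
  expect_gt(cor(log(pw), log(widths)), 0.9)
})

test_that("binarization thresholds z-scored series at the right rates", {
  set.seed(5)
  mk_bp <- function(P, fs = 100) structure(
    list(power = P, band = "test", low = 8, high = 13, fs = fs, window_s = 100,
         labels = paste0("ch", seq_len(nrow(P))), montage = "referential"),
    class = "band_power")
  P <- matrix(abs(rnorm(2 * 20000, 5, 1)), 2)   # gaussian fluctuations
  st0 <- binarize_power(mk_bp(P), threshold = 0, downsample = 1)
  expect_equal(mean(st0$states), 0.5, tolerance = 0.02)
  st1 <- binarize_power(mk_bp(P), threshold = 1, downsample = 1)
  expect_equal(mean(st1$states), pnorm(-1), tolerance = 0.02)
  # downsampling: T = floor(T_pre / factor)
  st10 <- binarize_power(mk_bp(P[, 1:1000, drop = FALSE]), downsample = 10)
  expect_equal(ncol(st10$states), 100)
  # affine invariance: offset and rescale leave states unchanged
  sta <- binarize_power(mk_bp(P), threshold = 0, downsample = 5)
  stb <- binarize_power(mk_bp(3.7 * P + 11), threshold = 0, downsample = 5)
  expect_identical(sta$states, stb$states)
  # constant channel errors with the channel named
  Pc <- P; Pc[2, ] <- 2
  expect_error(binarize_power(mk_bp(Pc)), "ch2")
})

test_that("one electrode per occupied region is selected, the closest", {
  centroids <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  coords <- rbind(c(3, 0, 0), c(7, 0, 0), c(101, 0, 0))
  sel <- select_roi_electrodes(coords, centroids, c(1, 1, 2))
  expect_equal(sel, c(1, 3))
  # one electrode per region: all returned
  sel2 <- select_roi_electrodes(centroids + 1, centroids, 1:3)
  expect_equal(sel2, 1:3)
  # synthetic brain: count equals occupied regions
  brain <- small_brain(seed = 6)
  s <- select_roi_electrodes(brain$electrode_coords, brain$atlas_coords,
                             brain$electrode_to_region)
  expect_equal(length(s), length(unique(brain$electrode_to_region)))
})

test_that("moments are exact hand counts and consistent for independence", {
  st <- matrix(c(1, 1, 0, 1), 2, 2)    # rows: (1,0), (1,1)
  mom <- compute_moments(st)
  expect_equal(mom$activation, c(0.5, 1))
  expect_equal(mom$coactivation[1, 2], 0.5)
  expect_equal(diag(mom$coactivation), mom$activation)
  # all-ones
  expect_true(all(compute_moments(matrix(1L, 3, 5))$coactivation == 1))
  # independent channels factorize approximately
  set.seed(7)
  Si <- matrix(rbinom(2 * 50000, 1, 0.4), 2)
  mi <- compute_moments(Si)
  expect_equal(mi$coactivation[1, 2], mi$activation[1] * mi$activation[2],
               tolerance = 0.01)
})

test_that("the state pipeline is deterministic for identical recordings", {
  set.seed(8)
  rec <- recording(matrix(rnorm(3 * 30000), 3), 100,
                   coords = cbind(1:3 * 10, 0, 0))
  run <- function() {
    bp <- wavelet_band_power(rec, default_bands()[1:2, ], window_s = 100)
    binarize_power(bp[[1]], threshold = 0)$states
  }
  expect_identical(run(), run())
})
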