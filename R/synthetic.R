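#' Synthetic brain geometry: atlas centroids plus clustered electrodes
#'
#' Atlas region centroids are drawn uniformly in a 140 x 120 x 100 mm box (the
#' scale of a human cranial vault). Electrodes mimic subdural grid/strip
#' coverage: 1-3 rectangular patches of grid points at 10 mm pitch with small
#' jitter, placed at random positions and orientations inside the box. Each
#' electrode is assigned to its nearest atlas region.
#'
#' @param n_atlas number of atlas regions (>= 10).
#' @param n_electrodes number of electrodes (<= n_atlas).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param pitch_mm inter-contact spacing (default 10).
#' @param jitter_mm coordinate jitter s.d. (default 0.5).
#' @return an object of class `synthetic_brain` with `atlas_coords` (M x 3),
#'   `electrode_coords` (N x 3), `electrode_to_region` (length N) and `seed`.
#' @export
generate_geometry <- function(n_atlas, n_electrodes, seed = 1,
                              pitch_mm = 10, jitter_mm = 0.5) {
  if (n_electrodes > n_atlas)
    abort_invalid("n_electrodes must not exceed n_atlas")
  if (n_atlas < 10) abort_invalid("n_atlas must be >= 10")
  set.seed(seed)
  box <- c(140, 120, 100)
  atlas <- cbind(runif(n_atlas, 0, box[1]), runif(n_atlas, 0, box[2]),
                 runif(n_atlas, 0, box[3]))

  n_patches <- if (n_electrodes <= 20) 1L else if (n_electrodes <= 48) 2L else 3L
  sizes <- diff(round(seq(0, n_electrodes, length.out = n_patches + 1)))
  elec <- matrix(0, 0, 3)
  for (m in sizes) {
    r <- max(1L, floor(sqrt(m)))
    cc <- ceiling(m / r)
    g <- as.matrix(expand.grid(x = (seq_len(r) - (r + 1) / 2) * pitch_mm,
                               y = (seq_len(cc) - (cc + 1) / 2) * pitch_mm))
    g <- cbind(g, 0)[seq_len(m), , drop = FALSE]
    rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    centre <- c(runif(1, 30, box[1] - 30), runif(1, 30, box[2] - 30),
                runif(1, 25, box[3] - 25))
    p <- g %*% t(rot) + matrix(centre, m, 3, byrow = TRUE)
    elec <- rbind(elec, p)
  }
  elec <- elec + matrix(rnorm(length(elec), 0, jitter_mm), nrow(elec), 3)
  dimnames(elec) <- NULL

  D <- as.matrix(dist(rbind(elec, atlas)))[seq_len(n_electrodes),
                                           n_electrodes + seq_len(n_atlas)]
  assignment <- apply(D, 1, which.min)

  structure(list(atlas_coords = atlas, electrode_coords = elec,
                 electrode_to_region = as.integer(assignment), seed = seed),
            class = "synthetic_brain")
}

#' @export
print.synthetic_brain <- function(x, ...) {
  cat(sprintf("<synthetic_brain> %d atlas regions, %d electrodes over %d occupied regions (seed %d)\n",
              nrow(x$atlas_coords), nrow(x$electrode_coords),
              length(unique(x$electrode_to_region)), x$seed))
  invisible(x)
}

#' Synthetic structural connectome with distance-decaying streamline counts
#'
#' Edge existence probability and mean streamline count both decay
#' exponentially with inter-centroid distance, reflecting the scarcity of
#' long-range fibers; counts have Poisson dispersion around the
#' distance-decayed mean.
#'
#' @param brain a [generate_geometry()] result.
#' @param decay_mm exponential decay length in mm (> 0).
#' @param density edge probability at zero distance, in (0, 1].
#' @param max_count mean streamline count at zero distance.
#' @param seed integer seed.
#' @return a [connectome()] over the atlas centroids.
#' @export
generate_structural_connectome <- function(brain, decay_mm = 30, density = 0.3,
                                           max_count = 1000, seed = 1) {
  stopifnot(inherits(brain, "synthetic_brain"))
  if (decay_mm <= 0) abort_invalid("decay_mm must be positive")
  if (density <= 0 || density > 1) abort_invalid("density must be in (0, 1]")
  set.seed(seed)
  cent <- brain$atlas_coords
  M <- nrow(cent)
  D <- distance_matrix(cent)
  du <- D[upper.tri(D)]
  decayed <- exp(-du / decay_mm)
  exist <- rbinom(length(du), 1, pmin(1, density * decayed))
  cnt <- exist * (1 + rpois(length(du), max_count * decayed))
  counts <- matrix(0, M, M)
  counts[upper.tri(counts)] <- cnt
  counts <- counts + t(counts)
  connectome(counts, cent)
}

#' Plant a ground-truth pairwise model that tracks structural connectivity
#'
#' Builds interaction weights proportional to the log-normalized streamline
#' counts between the regions the electrodes occupy (scaled to unit maximum)
#' plus a small symmetric noise term, then calibrates the base activations h
#' by short Metropolis sampling so that the model's mean activation rate is
#' close to `target_rate`. The planted coupling is the ground truth every
#' recovery test compares against.
#'
#' The default `coupling_scale` of 0.5 keeps the planted network in the
#' paramagnetic regime: with the connection densities the generator produces,
#' scales around 1 and above cross a ferromagnetic transition where strongly
#' coupled units saturate near rate 1 and no choice of h can hold the target
#' activation rate.
#'
#' @param structure a [connectome()].
#' @param electrode_to_region integer map electrode -> atlas region.
#' @param coupling_scale strength of the structure-tracking interactions
#'   (>= 0; 0 plants an independent-unit model).
#' @param target_rate desired mean activation rate in (0, 1).
#' @param noise_sd s.d. of the symmetric Gaussian noise added to J.
#' @param seed integer seed.
#' @param calib_rounds,calib_samples,calib_damp calibration schedule for h:
#'   damped per-unit log-odds corrections estimated from short Metropolis
#'   runs.
#' @return a [mem_params()] in the zero-one convention.
#' @export
derive_ground_truth_mem <- function(structure, electrode_to_region,
                                    coupling_scale = 0.5, target_rate = 0.3,
                                    noise_sd = 0.02, seed = 1,
                                    calib_rounds = 25, calib_samples = 3000,
                                    calib_damp = 0.4) {
  stopifnot(inherits(structure, "connectome"))
  if (coupling_scale < 0) abort_invalid("coupling_scale must be >= 0")
  if (target_rate <= 0 || target_rate >= 1)
    abort_invalid("target_rate must be in (0, 1)")
  set.seed(seed)
  reg <- as.integer(electrode_to_region)
  N <- length(reg)
  L <- structure$normalized[reg, reg]
  diag(L) <- 0
  if (max(L) > 0) L <- L / max(L)
  noise <- matrix(rnorm(N * N, 0, noise_sd), N, N)
  noise <- (noise + t(noise)) / 2
  J <- coupling_scale * L + noise
  diag(J) <- 0

  # calibrate h: start from the logistic mean-field guess, then apply damped
  # per-unit log-odds corrections estimated from short Metropolis runs
  # (undamped corrections oscillate in coupled networks)
  h <- rep(log(target_rate / (1 - target_rate)), N) - rowSums(J) * target_rate
  mem <- mem_params(h, J, convention = "zero_one")
  for (r in seq_len(calib_rounds)) {
    st <- metropolis_sample(mem, n_keep = calib_samples, burn_in = 300, thin = 2,
                            seed = derive_seed(seed, 100 + r))
    rate <- rowMeans(st$states)
    rate <- pmin(pmax(rate, 1 / (2 * calib_samples)), 1 - 1 / (2 * calib_samples))
    adj <- calib_damp * (log(target_rate / (1 - target_rate)) -
                           log(rate / (1 - rate)))
    mem$h <- mem$h + pmin(pmax(adj, -2), 2)
  }
  attr(mem, "planted") <- list(coupling_scale = coupling_scale,
                               target_rate = target_rate, noise_sd = noise_sd,
                               seed = seed)
  mem
}

#' Sample binary states from a pairwise model
#'
#' `method = "exact"` enumerates the Boltzmann distribution (N <= 20) and
#' draws i.i.d. states by inverse-CDF sampling; `method = "metropolis"`
#' delegates to [metropolis_sample()]. Both are deterministic given `seed` and
#' return states in the zero-one convention.
#'
#' @param mem a [mem_params()] object.
#' @param T number of samples.
#' @param method `"exact"` or `"metropolis"`.
#' @param seed integer seed.
#' @param ... passed to [metropolis_sample()] (`burn_in`, `thin`).
#' @return a [binary_states()] object (N x T).
#' @export
sample_states <- function(mem, T, method = c("exact", "metropolis"), seed = 1,
                          ...) {
  method <- match.arg(method)
  m <- convert_convention(mem, "zero_one")
  if (method == "metropolis")
    return(metropolis_sample(m, n_keep = T, seed = seed, ...))
  if (n_units(m) > 20)
    abort_capability("exact sampling requires N <= 20; use method = 'metropolis'")
  dist <- exact_distribution(m)
  set.seed(seed)
  idx <- sample.int(length(dist$p), T, replace = TRUE, prob = dist$p)
  binary_states(t(dist$states[idx, , drop = FALSE]), band = "model",
                threshold = NA_real_, downsample = 1L)
}

# pink (1/f) noise by spectral shaping of white noise
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # mirrored frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE) / n)
  x / sd(x)
}

#' Synthesize a band-limited recording from planted binary states
#'
#' A forward test harness (not a physiological model): each channel carries a
#' band-limited oscillatory carrier whose envelope is modulated by that
#' channel's planted state (relative amplitude 1 when 'on', `off_level` when
#' 'off', smoothed over `smooth_s` to avoid spectral splatter), plus 1/f pink
#' noise, plus a single shared reference signal added to all channels
#' (emulating reference contamination), plus distance-weighted shared local
#' sources (emulating volume conduction). The carrier mixes a
#' random-phase sinusoid at the band's geometric-mean frequency with
#' band-limited Gaussian noise (`carrier_noise_frac`): a purely stochastic
#' narrowband carrier has a heavily fluctuating (Rayleigh-like) envelope that
#' masks the planted modulation within each state, so the carrier is kept
#' mostly coherent for robust band-power separation.
#'
#' @param states a [binary_states()] object or binary N x T matrix.
#' @param band numeric `(low, high)` carrier band in Hz.
#' @param fs sampling rate, must be >= 4 x high.
#' @param state_dt duration of one state sample in seconds (>= 1/fs).
#' @param noise list with `reference_amp`, `local_shared_amp`, `pink_amp`
#'   (amplitudes relative to the unit 'on' carrier).
#' @param seed integer seed.
#' @param coords optional N x 3 electrode coordinates; defaults to a 10 mm
#'   grid layout. Stored on the returned recording.
#' @param off_level relative 'off' amplitude (default 0.2).
#' @param smooth_s envelope smoothing window in seconds (default 0.05).
#' @param carrier_noise_frac fraction of band-limited noise mixed into the
#'   carrier, in `[0, 1]` (default 0.25).
#' @return a [recording()] of duration `T_states * state_dt`.
#' @export
synthesize_recording <- function(states, band = c(8, 13), fs = 200,
                                 state_dt = 0.25,
                                 noise = list(reference_amp = 0.15,
                                              local_shared_amp = 0.15,
                                              pink_amp = 0.15),
                                 seed = 1, coords = NULL, off_level = 0.2,
                                 smooth_s = 0.05, carrier_noise_frac = 0.25) {
  S <- states_matrix(states)
  N <- nrow(S); Tst <- ncol(S)
  if (fs < 4 * band[2]) abort_invalid("fs must be at least 4x the band's upper edge")
  if (state_dt < 1 / fs) abort_invalid("state_dt must be >= 1/fs")
  if (is.null(coords)) {
    ncol_g <- 8
    coords <- cbind(((seq_len(N) - 1) %% ncol_g) * 10,
                    ((seq_len(N) - 1) %/% ncol_g) * 10, 0)
  }
  set.seed(seed)
  spp <- round(state_dt * fs)          # samples per state
  Sn <- Tst * spp
  sig <- matrix(0, N, Sn)
  smooth_w <- max(1L, round(smooth_s * fs))
  f0 <- sqrt(band[1] * band[2])
  w <- carrier_noise_frac
  for (i in seq_len(N)) {
    env <- rep(S[i, ], each = spp)
    env <- smooth_ma(env, smooth_w)
    amp <- off_level + (1 - off_level) * env
    tone <- sqrt(2) * sin(2 * pi * f0 * seq_len(Sn) / fs + runif(1, 0, 2 * pi))
    bn <- band_pass(rnorm(Sn), fs, band[1], band[2])
    carrier <- sqrt(1 - w^2) * tone + w * bn / sd(bn)
    sig[i, ] <- carrier * amp / sqrt(2)
    if (noise$pink_amp > 0)
      sig[i, ] <- sig[i, ] + noise$pink_amp * pink_noise(Sn)
  }
  if (noise$reference_amp > 0) {
    ref <- band_pass(rnorm(Sn), fs, band[1], band[2])
    ref <- noise$reference_amp * ref / sd(ref)
    sig <- sig + matrix(ref, N, Sn, byrow = TRUE)
  }
  if (noise$local_shared_amp > 0) {
    n_src <- max(1L, N %/% 10)
    src_at <- sample.int(N, n_src)
    D <- as.matrix(dist(coords))
    for (s in src_at) {
      source_sig <- band_pass(rnorm(Sn), fs, band[1], band[2])
      source_sig <- source_sig / sd(source_sig)
      wgt <- noise$local_shared_amp * exp(-D[s, ] / 15)
      sig <- sig + outer(wgt, source_sig)
    }
  }
  recording(sig, fs, coords = coords)
}
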