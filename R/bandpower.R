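#' Default frequency-band layout
#'
#' Conventional iEEG bands spanning 4-180 Hz: theta 4-8, alpha 8-13, beta
#' 13-30, gamma 30-80, high gamma 80-180 Hz. All analyses take the layout as
#' an argument, so alternative edges are a one-line change.
#'
#' @return a tibble with columns `band`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "beta", "gamma", "high_gamma"),
    low  = c(4, 8, 13, 30, 80),
    high = c(8, 13, 30, 80, 180)
  )
}

# Analytic Morlet continuous wavelet power of one channel, via FFT
# convolution. Amplitude-normalized (unit peak in the frequency domain), so a
# unit-amplitude sinusoid yields the same envelope magnitude at any frequency.
# Reflection padding controls edge effects.
morlet_power <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  scales <- omega0 / (2 * pi * freqs)           # seconds
  pad <- min(n, ceiling(3 * max(scales) * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  np <- length(xp)
  xh <- fft(xp)
  w <- 2 * pi * fs * c(seq(0, floor(np / 2)), seq(-ceiling(np / 2) + 1, -1)) / np
  pow <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    psi <- exp(-0.5 * (scales[k] * w - omega0)^2) * (w > 0)
    wt <- fft(xh * psi, inverse = TRUE) / np
    pow[k, ] <- Mod(wt[(pad + 1):(pad + n)])^2
  }
  pow
}

#' Band-limited wavelet power series
#'
#' Segments the recording into consecutive non-overlapping windows, computes
#' the continuous (analytic Morlet) wavelet power per segment on a
#' log-spaced frequency grid, averages power across the frequencies inside
#' each band, and concatenates segments back into one series per band.
#'
#' @param rec a [recording()].
#' @param bands tibble with `band`, `low`, `high` columns (Hz);
#'   see [default_bands()].
#' @param window_s segment length in seconds (default 100).
#' @param n_voices wavelet frequencies per octave on the global grid.
#' @param omega0 Morlet centre-frequency parameter.
#' @return a list of `band_power` objects (one per band), each holding an
#'   N x T' power matrix at the native sampling rate.
#' @export
wavelet_band_power <- function(rec, bands = default_bands(), window_s = 100,
                               n_voices = 6, omega0 = 6) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (any(bands$high > fs / 2))
    abort_invalid("band edge above Nyquist frequency")
  if (ncol(rec$signal) < window_s * fs)
    abort_invalid("recording shorter than one analysis window")

  fmin <- min(bands$low); fmax <- max(bands$high)
  n_freq <- max(2, ceiling(log2(fmax / fmin) * n_voices) + 1)
  grid <- exp(seq(log(fmin), log(fmax), length.out = n_freq))
  band_freqs <- lapply(seq_len(nrow(bands)), function(b) {
    lo <- bands$low[b]; hi <- bands$high[b]
    f <- grid[grid >= lo & (grid < hi | (b == nrow(bands) & grid <= hi))]
    if (length(f) == 0) f <- sqrt(lo * hi)
    f
  })
  freqs <- sort(unique(unlist(band_freqs)))

  n <- nrow(rec$signal); S <- ncol(rec$signal)
  wlen <- floor(window_s * fs)
  starts <- seq(1, S - wlen + 1, by = wlen)
  rem_start <- max(starts) + wlen
  segs <- lapply(starts, function(s) s:(s + wlen - 1))
  if (S - rem_start + 1 >= 0.1 * wlen) segs <- c(segs, list(rem_start:S))

  out <- lapply(seq_len(n), function(i) {
    do.call(cbind, lapply(segs, function(idx)
      morlet_power(rec$signal[i, idx], fs, freqs, omega0)))
  })
  Tp <- ncol(out[[1]])

  res <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- which(freqs %in% band_freqs[[b]])
    pw <- matrix(0, n, Tp)
    for (i in seq_len(n))
      pw[i, ] <- colMeans(out[[i]][sel, , drop = FALSE])
    res[[b]] <- structure(
      list(power = pw, band = bands$band[b], low = bands$low[b],
           high = bands$high[b], fs = fs, window_s = window_s,
           labels = rec$labels, montage = rec$montage),
      class = "band_power")
  }
  names(res) <- bands$band
  res
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %s (%g-%g Hz): %d channels x %d samples @ %g Hz\n",
              x$band, x$low, x$high, nrow(x$power), ncol(x$power), x$fs))
  invisible(x)
}

#' Binary power-amplitude state matrix container
#'
#' @param states integer/logical N x T matrix with entries in \{0, 1\}.
#' @param band band name.
#' @param threshold binarization threshold (z-units).
#' @param downsample decimation factor applied after thresholding.
#' @param montage source montage tag.
#' @param labels channel names.
#' @return an object of class `binary_states`.
#' @export
binary_states <- function(states, band = "unknown", threshold = NA_real_,
                          downsample = 1L, montage = "referential",
                          labels = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) abort_invalid("states must be binary (0/1)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(states)))
  structure(list(states = states, band = band, threshold = threshold,
                 downsample = downsample, montage = montage, labels = labels),
            class = "binary_states")
}

#' @export
print.binary_states <- function(x, ...) {
  cat(sprintf(
    "<binary_states> band %s: %d channels x %d samples (threshold %s, downsample %d, montage %s)\n",
    x$band, nrow(x$states), ncol(x$states), format(x$threshold),
    x$downsample, x$montage))
  invisible(x)
}

#' @export
dim.binary_states <- function(x) dim(x$states)

#' Binarize a band-power series into power-amplitude states
#'
#' Per channel: high-pass filter the power series (zero-phase 4th-order
#' Butterworth) to strip ultra-slow power drift, z-score over the full series,
#' mark state 1 where the z-score strictly exceeds the threshold, then keep
#' every `downsample`-th sample to reduce temporal dependence. z-scoring makes
#' the states invariant to affine rescaling of power.
#'
#' @param bp a `band_power` object from [wavelet_band_power()].
#' @param hp_hz high-pass cutoff in Hz (default 0.5).
#' @param threshold z-score threshold (the analysis uses 0 or 1).
#' @param downsample decimation factor (default 10).
#' @return a [binary_states()] object with `T = floor(T_pre / downsample)`.
#' @export
binarize_power <- function(bp, hp_hz = 0.5, threshold = 0, downsample = 10) {
  stopifnot(inherits(bp, "band_power"))
  if (hp_hz >= bp$fs / 2) abort_invalid("hp_hz must be below the power-series Nyquist")
  P <- bp$power
  n <- nrow(P); Tp <- ncol(P)
  bf <- signal::butter(4, hp_hz / (bp$fs / 2), type = "high")
  keep <- seq(downsample, Tp, by = downsample)
  st <- matrix(0L, n, length(keep))
  for (i in seq_len(n)) {
    if (sd(P[i, ]) == 0)
      abort_invalid(sprintf("channel %s has zero variance", bp$labels[i]))
    # demean before filtering so an additive offset is removed exactly rather
    # than through filter edge transients (keeps binarization affine-invariant)
    xf <- signal::filtfilt(bf, P[i, ] - mean(P[i, ]))
    z <- (xf - mean(xf)) / sd(xf)
    st[i, ] <- as.integer(z[keep] > threshold)
  }
  binary_states(st, band = bp$band, threshold = threshold,
                downsample = as.integer(downsample), montage = bp$montage,
                labels = bp$labels)
}

#' Empirical activation and co-activation rates
#'
#' Computes the first- and second-order moments of the binary states: the
#' activation rate of each channel (fraction of samples 'on') and the
#' co-activation rate of each channel pair (fraction of samples both 'on').
#' These are the sufficient statistics the pairwise maximum entropy model is
#' fitted to. The diagonal of the co-activation matrix equals the activation
#' rates since states are 0/1.
#'
#' @param states a [binary_states()] object or a binary N x T matrix.
#' @return an object of class `moment_set` with fields `activation` (length N)
#'   and `coactivation` (N x N symmetric).
#' @export
compute_moments <- function(states) {
  S <- if (inherits(states, "binary_states")) states$states else as.matrix(states)
  Tn <- ncol(S)
  if (Tn < 1) abort_invalid("need at least one sample")
  C <- (S %*% t(S)) / Tn
  structure(list(activation = diag(C), coactivation = C, n_samples = Tn),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> %d channels, %d samples; mean activation %.3f\n",
              length(x$activation), x$n_samples, mean(x$activation)))
  invisible(x)
}
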