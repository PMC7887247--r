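#' Functional connectivity matrix container
#'
#' A symmetric N x N matrix of pairwise statistics, tagged with the estimator,
#' frequency band and montage it came from. The diagonal is fixed by the
#' method (1 for correlation-family estimators, 0 otherwise).
#'
#' @param values symmetric numeric matrix.
#' @param method estimator tag.
#' @param band band name.
#' @param montage montage tag.
#' @param diag_value method-defined diagonal.
#' @return an object of class `fc_matrix` (a matrix with attributes).
#' @export
fc_matrix <- function(values, method, band = NA_character_,
                      montage = NA_character_, diag_value = 0) {
  values <- as.matrix(values)
  if (!is_symmetric_num(values, tol = 1e-6) && !anyNA(values))
    abort_invalid("fc matrix must be symmetric")
  diag(values) <- diag_value
  structure(values, class = c("fc_matrix", "matrix", "array"),
            method = method, band = band, montage = montage)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %s, band %s, montage %s: %d x %d\n",
              attr(x, "method"), attr(x, "band"), attr(x, "montage"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Co-activation functional connectivity from binary states
#'
#' `mode = "rate"` returns the raw co-activation rates: the fraction of
#' samples in which both channels are 'on'. `mode = "pearson"` returns the
#' Pearson correlation of the binary series (the two readings of binarized
#' power-amplitude correlations; both are provided since they emphasise
#' different aspects: rates retain base-rate information, correlations remove
#' it).
#'
#' @param states a [binary_states()] object or binary N x T matrix.
#' @param mode `"rate"` or `"pearson"`.
#' @return an [fc_matrix()] (diagonal 0 for rates, 1 for correlations).
#' @export
coactivation_fc <- function(states, mode = c("rate", "pearson")) {
  mode <- match.arg(mode)
  S <- states_matrix(states)
  if (ncol(S) < 2) abort_invalid("need at least 2 samples")
  band <- if (inherits(states, "binary_states")) states$band else NA_character_
  mont <- if (inherits(states, "binary_states")) states$montage else NA_character_
  if (mode == "rate") {
    M <- (S %*% t(S)) / ncol(S)
    fc_matrix(M, method = "coactivation_rate", band = band, montage = mont,
              diag_value = 0)
  } else {
    const <- apply(S, 1, function(r) all(r == r[1]))
    if (any(const))
      warn(sprintf("constant channel(s) %s: correlation undefined (NA)",
                   paste(which(const), collapse = ", ")))
    M <- suppressWarnings(cor(t(S)))
    fc_matrix(M, method = "coactivation_pearson", band = band, montage = mont,
              diag_value = 1)
  }
}

#' Pearson correlation functional connectivity
#'
#' @param series numeric N x T matrix (channels in rows).
#' @param band,montage optional tags.
#' @return an [fc_matrix()] with unit diagonal.
#' @export
pearson_fc <- function(series, band = NA_character_, montage = NA_character_) {
  X <- as.matrix(series)
  const <- apply(X, 1, function(r) sd(r) == 0)
  if (any(const))
    warn(sprintf("constant channel(s) %s: correlation undefined (NA)",
                 paste(which(const), collapse = ", ")))
  fc_matrix(suppressWarnings(cor(t(X))), method = "pearson", band = band,
            montage = montage, diag_value = 1)
}

# residual-based partial correlation of one segment (channels in rows);
# per pair (i, j): correlate the residuals of X_i and X_j each regressed on
# all remaining channels. Ridge fallback on rank deficiency.
partial_corr_segment <- function(X, ridge_tol = 1e-10) {
  N <- nrow(X); Tn <- ncol(X)
  out <- diag(1, N)
  Xc <- t(X)                    # T x N
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      others <- setdiff(seq_len(N), c(i, j))
      Z <- cbind(1, Xc[, others, drop = FALSE])
      q <- qr(Z)
      if (q$rank < ncol(Z)) {
        G <- crossprod(Z)
        lambda <- 1e-6 * sum(diag(G)) / ncol(G)
        B <- solve(G + lambda * diag(ncol(G)), crossprod(Z, Xc[, c(i, j)]))
        R <- Xc[, c(i, j)] - Z %*% B
        message("partial correlation: rank-deficient regressors; ridge fallback used")
      } else {
        R <- qr.resid(q, Xc[, c(i, j)])
      }
      out[i, j] <- out[j, i] <- suppressWarnings(cor(R[, 1], R[, 2]))
    }
  }
  out
}

#' Partial correlation functional connectivity
#'
#' For every channel pair, the correlation of the residuals after regressing
#' each of the two series on all remaining channels — the regression-residual
#' reading of the partial correlation, which on well-conditioned data equals
#' the inverse-covariance formula `-p_ij / sqrt(p_ii p_jj)`. The series is
#' split into `segment_s`-long segments (hour-long by default), each segment
#' is decimated by `downsample` to reduce temporal dependence, and the final
#' matrix is the mean over segments. Segments with too few samples relative to
#' the channel count are skipped with a warning.
#'
#' @param series numeric N x T matrix.
#' @param fs sampling rate of `series` in Hz; `NULL` treats the whole series
#'   as a single segment.
#' @param downsample decimation factor (default 10).
#' @param segment_s segment length in seconds (default 3600).
#' @param band,montage optional tags.
#' @return an [fc_matrix()] with unit diagonal.
#' @export
partial_correlation_fc <- function(series, fs = NULL, downsample = 10,
                                   segment_s = 3600, band = NA_character_,
                                   montage = NA_character_) {
  X <- as.matrix(series)
  N <- nrow(X); S <- ncol(X)
  segs <- if (is.null(fs)) list(seq_len(S)) else {
    wlen <- floor(segment_s * fs)
    starts <- seq(1, S, by = wlen)
    lapply(starts, function(s) s:min(s + wlen - 1, S))
  }
  mats <- list()
  for (idx in segs) {
    keep <- idx[seq(downsample, length(idx), by = downsample)]
    if (length(keep) <= N + 2) {
      warn(sprintf("segment with %d downsampled samples <= N + 2; skipped", length(keep)))
      next
    }
    mats[[length(mats) + 1]] <- partial_corr_segment(X[, keep, drop = FALSE])
  }
  if (length(mats) == 0) abort_invalid("no segment long enough for partial correlation")
  M <- Reduce(`+`, mats) / length(mats)
  fc_matrix(M, method = "partial_correlation", band = band, montage = montage,
            diag_value = 1)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of the analytic signal `x + i H(x)`; its argument is the
#' instantaneous phase and its modulus the envelope.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1; hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1; hmul[2:((n + 1) / 2)] <- 2
  }
  fft(X * hmul, inverse = TRUE) / n
}

#' Zero-phase FIR band-pass filter
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @param order FIR order; default scales with `fs / low`.
#' @return filtered numeric vector.
#' @export
band_pass <- function(x, fs, low, high, order = NULL) {
  if (high >= fs / 2) abort_invalid("band edge above Nyquist frequency")
  if (is.null(order)) order <- min(512L, max(32L, 2L * ceiling(1.5 * fs / low)))
  flt <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(flt, x))
}

#' Phase-locking value of a pair of analytic signals
#'
#' `PLV = |E(exp(i theta))|` where theta is the instantaneous phase difference;
#' 1 for a perfectly constant phase lag, 0 for uniformly scattered phase
#' differences.
#'
#' @param z1,z2 complex analytic signals (or real signals, in which case the
#'   Hilbert transform is applied).
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(z1, z2) {
  if (is.numeric(z1)) z1 <- analytic_signal(z1)
  if (is.numeric(z2)) z2 <- analytic_signal(z2)
  theta <- Arg(z1) - Arg(z2)
  Mod(mean(exp(1i * theta)))
}

#' Phase-lag index of a pair of analytic signals
#'
#' `PLI = |E(sgn(Im(X)))|` with `X = Z1 * Conj(Z2)` the per-sample
#' cross-spectrum term. Insensitive to zero-lag (volume-conducted) coupling:
#' exactly zero-lag pairs have `Im(X) = 0`, which contributes `sgn(0) = 0`.
#'
#' @inheritParams plv
#' @return PLI in `[0, 1]`.
#' @export
pli <- function(z1, z2) {
  if (is.numeric(z1)) z1 <- analytic_signal(z1)
  if (is.numeric(z2)) z2 <- analytic_signal(z2)
  abs(mean(sign(Im(z1 * Conj(z2)))))
}

#' Weighted phase-lag index of a pair of analytic signals
#'
#' `WPLI = |E(Im(X))| / E(|Im(X)|)`, which downweights near-zero-lag samples
#' rather than counting signs. Equals 1 whenever the imaginary cross-spectrum
#' keeps a constant sign (any consistently positive or negative phase
#' difference). An identically zero imaginary cross-spectrum (pure zero-lag
#' coupling) is degenerate: the value 0 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams plv
#' @return WPLI in `[0, 1]`.
#' @export
wpli <- function(z1, z2) {
  if (is.numeric(z1)) z1 <- analytic_signal(z1)
  if (is.numeric(z2)) z2 <- analytic_signal(z2)
  im <- Im(z1 * Conj(z2))
  denom <- mean(abs(im))
  if (denom == 0) {
    warn("WPLI degenerate: imaginary cross-spectrum identically zero; returning 0")
    return(structure(0, degenerate = TRUE))
  }
  abs(mean(im)) / denom
}

#' Phase-synchrony functional connectivity matrix
#'
#' Band-passes every channel (zero-phase FIR at the band edges), takes the
#' analytic signal, and computes PLV, PLI or WPLI for every channel pair.
#' Expectations are taken per `segment_s`-long segment and averaged across
#' segments.
#'
#' @param rec a [recording()] or numeric N x S matrix.
#' @param band length-2 numeric `(low, high)` in Hz.
#' @param method `"plv"`, `"pli"` or `"wpli"`.
#' @param fs sampling rate; taken from the recording if omitted.
#' @param segment_s segment length in seconds (default 3600).
#' @param band_name optional band label.
#' @return an [fc_matrix()] with zero diagonal.
#' @export
phase_fc <- function(rec, band, method = c("plv", "pli", "wpli"), fs = NULL,
                     segment_s = 3600, band_name = NA_character_) {
  method <- match.arg(method)
  if (inherits(rec, "recording")) {
    X <- rec$signal; fs <- rec$fs
    mont <- rec$montage
  } else {
    X <- as.matrix(rec)
    if (is.null(fs)) abort_invalid("fs required for matrix input")
    mont <- NA_character_
  }
  N <- nrow(X); S <- ncol(X)
  Z <- matrix(0 + 0i, N, S)
  for (i in seq_len(N))
    Z[i, ] <- analytic_signal(band_pass(X[i, ], fs, band[1], band[2]))
  wlen <- floor(segment_s * fs)
  starts <- seq(1, max(1, S - wlen + 1), by = wlen)
  segs <- lapply(starts, function(s) s:min(s + wlen - 1, S))
  f <- switch(method, plv = plv, pli = pli, wpli = wpli)
  M <- matrix(0, N, N)
  for (idx in segs) {
    Mi <- matrix(0, N, N)
    for (i in seq_len(N - 1))
      for (j in (i + 1):N)
        Mi[i, j] <- Mi[j, i] <- as.numeric(suppressWarnings(
          f(Z[i, idx], Z[j, idx])))
    M <- M + Mi
  }
  M <- M / length(segs)
  fc_matrix(M, method = method, band = band_name, montage = mont, diag_value = 0)
}
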