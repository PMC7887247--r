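#' Deterministic per-stage seed derivation
#'
#' Fans a single user-facing seed out to independent stage seeds using a
#' Lehmer step, so that no stage shares a random stream with another and the
#' whole pipeline is a pure function of the top-level seed. Results stay
#' below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer master seed.
#' @param offset integer stage offset (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 7919 * (as.double(offset) + 1)
  as.integer(s %% 2147483647) + 1L
}

abort_invalid <- function(msg) abort(msg, class = "memfc_error_invalid")
abort_capability <- function(msg) abort(msg, class = "memfc_error_capability")

#' Upper-triangle vector of a square matrix
#'
#' @param m a square matrix.
#' @return the strictly-upper-triangle entries as a vector (column-major).
#' @export
upper_tri_vec <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort_invalid("matrix must be square")
  m[upper.tri(m)]
}

is_symmetric_num <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

#' Pearson (non-excess) kurtosis
#'
#' Fourth standardized moment m4 / m2^2; equals 3 for a normal distribution.
#'
#' @param x numeric vector.
#' @return kurtosis value.
#' @export
kurtosis_pearson <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) abort_invalid("kurtosis needs at least 2 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

# moving-average smoother with edge padding, used for envelope shaping
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  xp <- c(rep(x[1], width), x, rep(x[length(x)], width))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(width + 1):(width + length(x))])
}
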