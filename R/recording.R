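#' Multichannel recording container
#'
#' Holds a channels-by-samples signal matrix together with its sampling rate,
#' channel labels, 3D electrode coordinates and the montage it was derived
#' under. Intracranial EEG is a relative measure (every channel is a potential
#' difference against a reference), so the montage tag records which
#' re-referencing scheme produced the signal.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional character vector of channel names.
#' @param coords optional channels x 3 matrix of electrode positions (mm).
#' @param montage one of `"referential"`, `"global_mean_regressed"`,
#'   `"local_regressed"`.
#' @return an object of class `recording`.
#' @export
recording <- function(signal, fs, labels = NULL, coords = NULL,
                      montage = "referential") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || anyNA(signal) || any(!is.finite(signal)))
    abort_invalid("signal must be a finite numeric matrix with no NA/NaN")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    abort_invalid("fs must be a single positive number")
  n <- nrow(signal)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  if (length(labels) != n) abort_invalid("labels must match channel count")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      abort_invalid("coords must be an N x 3 matrix matching channels")
  }
  montage <- match.arg(montage,
                       c("referential", "global_mean_regressed", "local_regressed"))
  structure(list(signal = signal, fs = fs, labels = labels,
                 coords = coords, montage = montage),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), montage: %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, x$montage))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$signal)

#' Re-reference a recording
#'
#' Applies one of three montages. `referential` returns the input unchanged.
#' `global` regresses each channel on the across-channel mean signal (common
#' average reference by least squares) and keeps the residual, removing noise
#' shared by the reference electrode. `local` regresses each channel on its
#' `k_local` nearest channels (Euclidean electrode distance) by multiple
#' linear regression and keeps the residual, suppressing volume conduction and
#' locally shared sources.
#'
#' @param rec a [recording()].
#' @param montage `"referential"`, `"global"` or `"local"` (full tags also
#'   accepted).
#' @param k_local number of nearest neighbours for the local montage.
#' @return a new `recording` with updated signal and montage tag.
#' @export
apply_montage <- function(rec, montage = c("referential", "global", "local"),
                          k_local = 4) {
  stopifnot(inherits(rec, "recording"))
  montage <- switch(match.arg(montage,
                              c("referential", "global", "local",
                                "global_mean_regressed", "local_regressed")),
                    referential = "referential",
                    global = , global_mean_regressed = "global_mean_regressed",
                    local = , local_regressed = "local_regressed")
  if (montage == "referential") {
    rec$montage <- "referential"
    return(rec)
  }
  X <- rec$signal
  n <- nrow(X)
  if (montage == "global_mean_regressed") {
    g <- colMeans(X)
    gc <- g - mean(g)
    vg <- sum(gc^2)
    # guard a degenerate (numerically zero) mean signal: a float-noise
    # regressor would otherwise blow up the fitted coefficient
    v_ref <- mean(rowSums((X - rowMeans(X))^2))
    out <- t(apply(X, 1, function(ch) {
      chc <- ch - mean(ch)
      beta <- if (vg > 1e-14 * max(v_ref, .Machine$double.xmin))
        sum(chc * gc) / vg else 0
      chc - beta * gc
    }))
  } else {
    if (is.null(rec$coords)) abort_invalid("local montage requires electrode coords")
    if (n <= k_local) abort_invalid("local montage requires more channels than k_local")
    D <- as.matrix(dist(rec$coords))
    if (any(upper_tri_vec(D) == 0))
      warn("duplicate electrode coordinates; nearest-neighbour ties broken by channel order")
    out <- matrix(0, n, ncol(X))
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(k_local)]
      nb <- seq_len(n)[-i][nb]
      out[i, ] <- lm.fit(cbind(1, t(X[nb, , drop = FALSE])), X[i, ])$residuals
    }
  }
  dimnames(out) <- dimnames(X)
  rec$signal <- out
  rec$montage <- montage
  rec
}

#' Select one electrode per occupied region
#'
#' When several electrodes fall inside the same atlas region, keeps only the
#' electrode closest (Euclidean distance) to that region's centroid, so that
#' each occupied region contributes exactly one channel to the model.
#'
#' @param coords N x 3 electrode positions (mm).
#' @param roi_centroids M x 3 region centroids (mm).
#' @param roi_assignment integer vector of length N mapping each electrode to
#'   its region index (1-based into `roi_centroids`).
#' @return integer vector of selected electrode indices, ordered by region.
#' @export
select_roi_electrodes <- function(coords, roi_centroids, roi_assignment) {
  coords <- as.matrix(coords); roi_centroids <- as.matrix(roi_centroids)
  if (length(roi_assignment) != nrow(coords))
    abort_invalid("roi_assignment must have one entry per electrode")
  if (anyNA(roi_assignment)) abort_invalid("every electrode must be assigned a region")
  sel <- integer(0)
  for (r in sort(unique(roi_assignment))) {
    idx <- which(roi_assignment == r)
    d <- sqrt(rowSums((coords[idx, , drop = FALSE] -
                         matrix(roi_centroids[r, ], length(idx), 3, byrow = TRUE))^2))
    sel <- c(sel, idx[which.min(d)])
  }
  sel
}
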