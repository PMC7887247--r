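#' Structural connectome container
#'
#' Region centroids plus a symmetric matrix of streamline counts between
#' regions (tractography-derived white-matter connection weights). The
#' log-normalized form `log10(count + 1)` is attached on construction.
#'
#' @param counts M x M symmetric non-negative matrix of streamline counts,
#'   zero diagonal.
#' @param centroids M x 3 matrix of region centroid positions (mm).
#' @param region_ids optional character region labels.
#' @return an object of class `connectome`.
#' @export
connectome <- function(counts, centroids, region_ids = NULL) {
  counts <- as.matrix(counts)
  centroids <- as.matrix(centroids)
  if (nrow(counts) != ncol(counts)) abort_invalid("counts must be square")
  if (any(counts < 0)) abort_invalid("streamline counts must be non-negative")
  if (!is_symmetric_num(counts)) abort_invalid("counts must be symmetric")
  if (any(diag(counts) != 0)) abort_invalid("counts must have zero diagonal")
  if (nrow(centroids) != nrow(counts) || ncol(centroids) != 3)
    abort_invalid("centroids must be M x 3 matching counts")
  if (is.null(region_ids)) region_ids <- paste0("roi", seq_len(nrow(counts)))
  dimnames(counts) <- list(region_ids, region_ids)
  structure(list(region_ids = region_ids, centroids = centroids,
                 counts = counts, normalized = normalize_streamlines(counts)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(upper_tri_vec(x$counts) > 0)
  cat(sprintf("<connectome> %d regions, %d connected pairs (density %.3f)\n",
              nrow(x$counts), nz, nz / choose(nrow(x$counts), 2)))
  invisible(x)
}

#' Log-normalize streamline counts
#'
#' Elementwise `log10(count + 1)`, which compresses the heavy right tail of
#' streamline counts and improves cross-modality correlations.
#'
#' @param counts non-negative matrix (or vector).
#' @return matrix of the same shape.
#' @export
normalize_streamlines <- function(counts) {
  if (any(counts < 0)) abort_invalid("streamline counts must be non-negative")
  log10(counts + 1)
}

#' Euclidean distance matrix of centroids
#'
#' @param centroids M x 3 matrix (mm).
#' @return symmetric M x M matrix of pairwise distances (mm).
#' @export
distance_matrix <- function(centroids) {
  as.matrix(dist(as.matrix(centroids)))
}

#' Remove the weakest structural edges
#'
#' Sets to zero all nonzero edges whose weight is strictly below the given
#' percentile of the nonzero-weight distribution. Ties at the threshold are
#' kept. Used to probe whether structure-function coupling strengthens when
#' likely-false-positive weak streamline connections are discarded.
#'
#' @param sc_matrix symmetric weight matrix.
#' @param percentile percentage in `[0, 100)` of weakest nonzero edges to drop.
#' @return pruned symmetric matrix.
#' @export
prune_weak_edges <- function(sc_matrix, percentile) {
  if (percentile < 0 || percentile >= 100)
    abort_invalid("percentile must be in [0, 100)")
  m <- as.matrix(sc_matrix)
  nz <- m[m > 0]
  if (length(nz) == 0 || percentile == 0) return(m)
  thr <- quantile(nz, percentile / 100, names = FALSE)
  m[m > 0 & m < thr] <- 0
  m
}
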