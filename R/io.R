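#' Write / read a structural connectome as delimited text
#'
#' Writes `<prefix>_counts.tsv` (square matrix with a header row of region
#' ids) and `<prefix>_centroids.tsv` (`region_id`, `x`, `y`, `z`).
#'
#' @param con a [connectome()].
#' @param prefix file path prefix.
#' @return (write) the prefix, invisibly; (read) a [connectome()].
#' @export
write_connectome <- function(con, prefix) {
  stopifnot(inherits(con, "connectome"))
  cnt <- as.data.frame(con$counts)
  names(cnt) <- con$region_ids
  write.table(cnt, paste0(prefix, "_counts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cen <- data.frame(region_id = con$region_ids, x = con$centroids[, 1],
                    y = con$centroids[, 2], z = con$centroids[, 3])
  write.table(cen, paste0(prefix, "_centroids.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(prefix) {
  cnt <- as.matrix(read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE))
  cen <- read.table(paste0(prefix, "_centroids.tsv"), sep = "\t", header = TRUE)
  connectome(unname(cnt), as.matrix(cen[, c("x", "y", "z")]),
             region_ids = as.character(cen$region_id))
}

#' Write / read binary state matrices as delimited text plus JSON sidecar
#'
#' Writes `<prefix>_states.tsv` (integer matrix, channels in rows) and
#' `<prefix>_states.json` (band, threshold, downsample, montage, labels).
#'
#' @param st a [binary_states()] object.
#' @param prefix file path prefix.
#' @return (write) the prefix, invisibly; (read) a [binary_states()].
#' @export
write_states <- function(st, prefix) {
  stopifnot(inherits(st, "binary_states"))
  write.table(st$states, paste0(prefix, "_states.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- list(band = st$band, threshold = st$threshold,
               downsample = st$downsample, montage = st$montage,
               labels = st$labels)
  jsonlite::write_json(meta, paste0(prefix, "_states.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_states
#' @export
read_states <- function(prefix) {
  m <- as.matrix(read.table(paste0(prefix, "_states.tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(prefix, "_states.json"),
                              simplifyVector = TRUE)
  binary_states(unname(m), band = meta$band,
                threshold = if (is.null(meta$threshold)) NA_real_
                            else as.numeric(meta$threshold),
                downsample = as.integer(meta$downsample),
                montage = meta$montage, labels = meta$labels)
}

#' Write / read a recording as a raw binary array plus JSON sidecar
#'
#' The signal is stored as little-endian float64, column-major
#' (sample-by-sample for channel 1, then channel 2, ...), in `<prefix>.f64`;
#' the sidecar `<prefix>.json` records dimensions, sampling rate, labels,
#' coordinates and montage so the array is self-describing.
#'
#' @param rec a [recording()].
#' @param prefix file path prefix.
#' @return (write) the prefix, invisibly; (read) a [recording()].
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  con <- file(paste0(prefix, ".f64"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  meta <- list(n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
               fs = rec$fs, labels = rec$labels, montage = rec$montage,
               coords = if (is.null(rec$coords)) NULL else unname(rec$coords))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(prefix, ".f64"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  sig <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  coords <- if (!is.null(meta$coords)) as.matrix(meta$coords) else NULL
  recording(sig, meta$fs, labels = meta$labels, coords = coords,
            montage = meta$montage)
}

#' Write / read model parameters as JSON
#'
#' Serializes `h`, `J` (row-major), the spin convention and any fit
#' diagnostics.
#'
#' @param mem a [mem_params()] object.
#' @param path JSON file path.
#' @return (write) the path, invisibly; (read) a [mem_params()].
#' @export
write_mem <- function(mem, path) {
  stopifnot(inherits(mem, "mem_params"))
  d <- attr(mem, "diagnostics")
  obj <- list(n = length(mem$h), h = mem$h,
              J = as.vector(t(mem$J)), convention = mem$convention,
              diagnostics = d)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mem
#' @export
read_mem <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- matrix(obj$J, obj$n, obj$n, byrow = TRUE)
  out <- mem_params(obj$h, J, convention = obj$convention)
  if (!is.null(obj$diagnostics)) {
    attr(out, "diagnostics") <- obj$diagnostics
    class(out) <- c("mem_fit", class(out))
  }
  out
}

#' Write a functional connectivity matrix as delimited text plus JSON sidecar
#'
#' @param fc an [fc_matrix()].
#' @param prefix file path prefix.
#' @return the prefix, invisibly.
#' @export
write_fc <- function(fc, prefix) {
  write.table(unclass(fc), paste0(prefix, "_fc.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(method = attr(fc, "method"), band = attr(fc, "band"),
                            montage = attr(fc, "montage")),
                       paste0(prefix, "_fc.json"), auto_unbox = TRUE)
  invisible(prefix)
}
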