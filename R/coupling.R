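#' Structure-function correlation
#'
#' Pearson correlation between the strictly-upper-triangle entries of a
#' functional connectivity matrix and a (log-normalized) structural
#' connectivity matrix over the same region ordering. By default all region
#' pairs enter, including structurally unconnected ones; `use = "connected"`
#' restricts to pairs with nonzero structural weight (used in the weak-edge
#' pruning analysis).
#'
#' @param fc functional connectivity matrix ([fc_matrix()] or plain matrix).
#' @param sc structural weight matrix, same dimensions/ordering.
#' @param use `"all"` or `"connected"`.
#' @return Pearson correlation (NA with a warning if either vector is
#'   constant).
#' @export
structure_function_correlation <- function(fc, sc, use = c("all", "connected")) {
  use <- match.arg(use)
  x <- upper_tri_vec(as.matrix(fc))
  y <- upper_tri_vec(as.matrix(sc))
  if (length(x) != length(y)) abort_invalid("fc and sc dimensions differ")
  if (use == "connected") {
    keep <- y > 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    warn("structure-function correlation undefined (constant or too-short input)")
    return(NA_real_)
  }
  cor(x, y)
}

#' ROC curve and AUC for predicting structural edges from functional weights
#'
#' Sweeps a detection threshold over the functional weights of all region
#' pairs (upper triangle): a pair counts as a true positive when it is
#' structurally connected and its functional weight exceeds the threshold.
#' The area under the curve is computed by the trapezoid rule, with tied
#' weights grouped so that the AUC equals the rank statistic
#' `P(FC_connected > FC_unconnected) + 0.5 P(tie)`. AUC 1 is perfect
#' classification and 0.5 chance level.
#'
#' @param fc functional connectivity matrix (or a plain vector of pair
#'   weights).
#' @param sc_binary structural adjacency: logical/0-1 matrix, or a weight
#'   matrix (nonzero means connected); a plain vector when `fc` is a vector.
#' @return a list of class `roc` with `curve` (tibble: threshold, fpr, tpr)
#'   and `auc`.
#' @export
roc_auc <- function(fc, sc_binary) {
  if (is.matrix(fc) || inherits(fc, "fc_matrix")) {
    w <- upper_tri_vec(as.matrix(fc))
    lab <- upper_tri_vec(as.matrix(sc_binary)) > 0
  } else {
    w <- as.numeric(fc)
    lab <- as.numeric(sc_binary) > 0
  }
  if (length(w) != length(lab)) abort_invalid("fc and sc dimensions differ")
  P <- sum(lab); Ng <- sum(!lab)
  if (P == 0 || Ng == 0) abort_invalid("need both connected and unconnected pairs")
  o <- order(w, decreasing = TRUE)
  w <- w[o]; lab <- lab[o]
  # group tied weights so ties advance diagonally
  grp <- cumsum(c(TRUE, diff(w) != 0))
  tp <- tapply(lab, grp, sum)
  fp <- tapply(!lab, grp, sum)
  tpr <- cumsum(tp) / P
  fpr <- cumsum(fp) / Ng
  thr <- tapply(w, grp, max)
  curve <- tibble::tibble(threshold = c(Inf, as.numeric(thr)),
                          fpr = c(0, as.numeric(fpr)),
                          tpr = c(0, as.numeric(tpr)))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("<roc> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$curve) - 1))
  invisible(x)
}

#' One-sided permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)` — the add-one estimator,
#' which never returns 0 and is exact for exchangeable nulls.
#'
#' @param observed observed statistic.
#' @param null_values vector of null statistics.
#' @return p-value in `[1/(n+1), 1]`.
#' @export
permutation_test <- function(observed, null_values) {
  if (length(null_values) == 0) abort_invalid("null_values must be non-empty")
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Benjamini-Hochberg FDR correction
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values.
#' @export
fdr_correct <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    abort_invalid("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Cross-frequency similarity of connectivity matrices
#'
#' For every pair of bands, correlates the upper-triangle weight vectors and
#' fits an ordinary least-squares line (y on x). High similarity across bands
#' indicates a common (anatomical) scaffold behind the interactions inferred
#' at different frequencies.
#'
#' @param matrices_by_band named list of N x N matrices, one per band.
#' @return a tibble with one row per band pair: `band_x`, `band_y`, `r`,
#'   `slope`, `intercept`, `r_squared`, `p_value` (two-sided, for the slope).
#' @export
cross_frequency_similarity <- function(matrices_by_band) {
  bands <- names(matrices_by_band)
  if (length(bands) < 2) abort_invalid("need at least 2 bands")
  vecs <- lapply(matrices_by_band, function(m) upper_tri_vec(as.matrix(m)))
  purrr::map_dfr(utils::combn(seq_along(bands), 2, simplify = FALSE), function(ij) {
    x <- vecs[[ij[1]]]; y <- vecs[[ij[2]]]
    fit <- lm(y ~ x)
    s <- summary(fit)
    tibble::tibble(
      band_x = bands[ij[1]], band_y = bands[ij[2]],
      r = cor(x, y),
      slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
      r_squared = s$r.squared,
      p_value = s$coefficients[2, 4]
    )
  })
}

#' Stability of pairwise co-activation with recording duration
#'
#' Quantifies how much the co-activation matrix keeps changing as recording
#' duration grows: for each n, repeatedly draws two disjoint random sets of
#' hour-long state segments of sizes n and n-1, computes the co-activation
#' matrix of each set, and records the matrix-norm difference. A curve that
#' plateaus at small values indicates the correlation structure has become
#' effectively static.
#'
#' @param states_by_hour list of [binary_states()] (or binary matrices), one
#'   per hour-long segment, all with the same channels (>= 3 segments).
#' @param n_iter random draws per n (default 10000).
#' @param seed integer seed.
#' @param norm `"frobenius"` (default) or `"spectral"`.
#' @param mode co-activation mode passed to [coactivation_fc()].
#' @return a tibble of class `stability_curve` with columns `n_hours`,
#'   `mean_norm_diff`, `stderr`, `n_iter`.
#' @export
stability_curve <- function(states_by_hour, n_iter = 10000, seed = 1,
                            norm = c("frobenius", "spectral"), mode = "rate") {
  norm <- match.arg(norm)
  H <- length(states_by_hour)
  if (H < 3) abort_invalid("need at least 3 hour-long segments")
  mats <- lapply(states_by_hour, states_matrix)
  nmax <- floor((H + 1) / 2)
  set.seed(seed)
  rows <- list()
  for (n in 2:nmax) {
    if (2 * n - 1 > H) {
      message(sprintf("n = %d skipped: needs %d segments, have %d", n, 2 * n - 1, H))
      next
    }
    d <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      pick <- sample.int(H, 2 * n - 1)
      A <- coactivation_fc(do.call(cbind, mats[pick[seq_len(n)]]), mode = mode)
      B <- coactivation_fc(do.call(cbind, mats[pick[(n + 1):(2 * n - 1)]]), mode = mode)
      dm <- unclass(A) - unclass(B)
      d[it] <- if (norm == "frobenius") sqrt(sum(dm^2)) else base::norm(dm, "2")
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      n_hours = n, mean_norm_diff = mean(d),
      stderr = sd(d) / sqrt(n_iter), n_iter = n_iter)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_curve", class(out))
  attr(out, "norm") <- norm
  out
}

#' Compare distribution shapes of interaction weights and co-activation
#'
#' The pairwise model separates direct from indirect coupling, so its
#' interaction weights are expected to be heavy-tailed (few strong direct
#' links, many near zero) relative to co-activation values. Computes the
#' Pearson (non-excess, normal = 3) kurtosis of each matched weight vector and
#' a paired two-sided t-test across the pairs.
#'
#' @param J_list list of interaction-weight vectors or matrices (upper
#'   triangle is taken from matrices).
#' @param coact_list matched list of co-activation vectors/matrices.
#' @return a list with `table` (tibble: pair, kurtosis_J, kurtosis_coact),
#'   `statistic` and `p_value` from the paired t-test.
#' @export
distribution_shape_compare <- function(J_list, coact_list) {
  if (length(J_list) != length(coact_list))
    abort_invalid("J_list and coact_list lengths differ")
  if (length(J_list) < 2) abort_invalid("need at least 2 matched pairs")
  as_vec <- function(v) if (is.matrix(v)) upper_tri_vec(v) else as.numeric(v)
  kj <- vapply(J_list, function(v) kurtosis_pearson(as_vec(v)), numeric(1))
  kc <- vapply(coact_list, function(v) kurtosis_pearson(as_vec(v)), numeric(1))
  tt <- t.test(kj, kc, paired = TRUE)
  list(table = tibble::tibble(pair = seq_along(kj), kurtosis_J = kj,
                              kurtosis_coact = kc),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}
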