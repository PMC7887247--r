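#' Fitting configuration
#'
#' Settings shared by the two fitters. `learning_rate` is the initial gradient
#' step; both fitters adapt it (geometric growth while the moment error
#' shrinks, back-off on oscillation). `tol` is the convergence criterion: the
#' maximum absolute mismatch between empirical and model activation /
#' co-activation moments.
#'
#' @param learning_rate initial step size (> 0), default 0.05.
#' @param max_iter iteration cap, default 50000.
#' @param tol maximum absolute moment error at convergence, default 1e-4.
#' @param seed integer seed (used by stages that randomize).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(learning_rate = 0.05, max_iter = 50000, tol = 1e-4,
                       seed = 1L) {
  if (learning_rate <= 0) abort_invalid("learning_rate must be positive")
  if (tol <= 0) abort_invalid("tol must be positive")
  structure(list(learning_rate = learning_rate, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "fit_config")
}

states_matrix <- function(states) {
  S <- if (inherits(states, "binary_states")) states$states else as.matrix(states)
  if (!all(S %in% c(0L, 1L))) abort_invalid("states must be binary (0/1)")
  S
}

#' Fit the pairwise model by pseudo-likelihood maximization
#'
#' Maximizes the product over time and channels of each channel's conditional
#' (single-spin Boltzmann) probability given the others, avoiding the full
#' partition function. Fitting runs in the \{-1,+1\} convention (states are
#' mapped 0 to -1): parameters follow the gradient-ascent updates
#' `h_i <- h_i + eps (<s_i>_emp - <s_i>_model)` and likewise for `J_ij`, where
#' the model means take the tanh form `tanh(h_i + sum_j J_ij s_j(t))` averaged
#' over samples. The pseudo-likelihood estimator converges to the maximum
#' likelihood estimator as T grows. The J gradient is symmetrized each step,
#' which shares the fixed points of fitting rows independently and then
#' averaging `(J + t(J))/2`, but keeps J symmetric throughout. The result is
#' returned in the zero-one convention via [convert_convention()].
#'
#' @param states a [binary_states()] object or binary N x T matrix (T >= 2).
#' @param cfg a [fit_config()].
#' @return a `mem_fit` object (subclass of [mem_params()], zero-one
#'   convention) with fit diagnostics; see [glance.mem_fit()].
#' @export
fit_pseudolikelihood <- function(states, cfg = fit_config()) {
  S <- states_matrix(states)
  if (ncol(S) < 2) abort_invalid("need at least 2 samples")
  const_ch <- which(apply(S, 1, function(r) all(r == r[1])))
  if (length(const_ch) > 0)
    warn(sprintf("channel(s) %s constant across samples; empirical moments regularized",
                 paste(const_ch, collapse = ", ")))
  Spm <- t(S) * 2 - 1   # T x N in {-1, +1}
  res <- cpp_pl_fit(Spm, cfg$learning_rate, cfg$tol, cfg$max_iter)
  if (!res$converged)
    warn(sprintf("pseudo-likelihood fit did not converge: max moment error %.3g after %d iterations",
                 res$max_moment_error, res$iterations))
  fit <- mem_params(as.numeric(res$h), res$J, convention = "plus_minus")
  attr(fit, "diagnostics") <- list(
    method = "pseudolikelihood", iterations = res$iterations,
    max_moment_error = res$max_moment_error, converged = res$converged,
    learning_rate_final = res$learning_rate_final,
    n_samples = ncol(S), tol = cfg$tol)
  class(fit) <- c("mem_fit", class(fit))
  convert_convention(fit, "zero_one")
}

#' Fit the pairwise model by exact-gradient likelihood maximization
#'
#' Moment matching against the exactly enumerated Boltzmann distribution:
#' model moments are computed by summing over all 2^N states each iteration
#' and the parameters follow the (concave) likelihood gradient
#' `eps * (empirical - model)` moment mismatch until the maximum absolute
#' mismatch drops below `tol`. Exact but exponential in N, so restricted to
#' N <= 15; beyond that use [fit_pseudolikelihood()].
#'
#' @param states a [binary_states()] object, binary matrix, or a `moment_set`
#'   from [compute_moments()].
#' @param cfg a [fit_config()].
#' @return a `mem_fit` object in the zero-one convention.
#' @export
fit_exact_gradient <- function(states, cfg = fit_config()) {
  if (inherits(states, "moment_set")) {
    mom <- states
  } else {
    mom <- compute_moments(states_matrix(states))
  }
  N <- length(mom$activation)
  if (N > 15) abort_capability("fit_exact_gradient requires N <= 15")
  clip <- 1e-6
  emp_m <- pmin(pmax(mom$activation, clip), 1 - clip)
  emp_C <- pmin(pmax(mom$coactivation, clip), 1 - clip)
  diag(emp_C) <- emp_m

  Smat <- enumerate_states(N, "zero_one")
  h <- numeric(N)
  J <- matrix(0, N, N)
  eps <- cfg$learning_rate
  prev_err <- Inf
  err <- Inf
  it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    E <- -as.vector(Smat %*% h) - 0.5 * rowSums((Smat %*% J) * Smat)
    m <- max(-E)
    p <- exp(-E - m); p <- p / sum(p)
    model_m <- as.vector(crossprod(Smat, p))
    model_C <- crossprod(Smat, Smat * p)
    Gh <- emp_m - model_m
    GJ <- emp_C - model_C
    GJ <- (GJ + t(GJ)) / 2
    diag(GJ) <- 0
    err <- max(max(abs(Gh)), max(abs(GJ)))
    if (err < cfg$tol) break
    eps <- if (err > prev_err) max(eps * 0.7, cfg$learning_rate * 1e-3)
           else min(eps * 1.02, cfg$learning_rate * 40)
    prev_err <- err
    h <- h + eps * Gh
    J <- J + eps * GJ
  }
  if (err >= cfg$tol)
    warn(sprintf("exact-gradient fit did not converge: max moment error %.3g", err))
  fit <- mem_params(h, J, convention = "zero_one")
  attr(fit, "diagnostics") <- list(
    method = "exact_gradient", iterations = it, max_moment_error = err,
    converged = err < cfg$tol, learning_rate_final = eps,
    n_samples = mom$n_samples, tol = cfg$tol)
  class(fit) <- c("mem_fit", class(fit))
  fit
}

#' @export
print.mem_fit <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat(sprintf("<mem_fit> N = %d (%s, %s convention)\n", length(x$h),
              d$method, x$convention))
  cat(sprintf("  %d iterations, max moment error %.3g (%s)\n",
              d$iterations, d$max_moment_error,
              if (d$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a fitted pairwise model
#'
#' One row per parameter: all N base-activation terms `h[i]` and the N(N-1)/2
#' upper-triangle interaction terms `J[i,j]`.
#'
#' @param x a `mem_fit` (or `mem_params`) object.
#' @param ... unused.
#' @return a tibble with columns `term`, `type`, `i`, `j`, `estimate`.
#' @export
tidy.mem_params <- function(x, ...) {
  N <- length(x$h)
  ij <- which(upper.tri(x$J), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = sprintf("h[%d]", seq_len(N)), type = "h",
                   i = seq_len(N), j = NA_integer_, estimate = x$h),
    tibble::tibble(term = sprintf("J[%d,%d]", ij[, 1], ij[, 2]), type = "J",
                   i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   estimate = x$J[ij])
  )
}

#' One-row fit summary
#'
#' @param x a `mem_fit` object.
#' @param ... unused.
#' @return a tibble with the method, problem size, iteration count, final
#'   moment error and convergence flag.
#' @export
glance.mem_fit <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble::tibble(
    n_channels = length(x$h), method = d$method, convention = x$convention,
    n_samples = d$n_samples, iterations = d$iterations,
    max_moment_error = d$max_moment_error, tol = d$tol,
    converged = d$converged)
}
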