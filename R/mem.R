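#' Pairwise maximum entropy model parameters
#'
#' Container for the Ising-type model of binary power-amplitude states: `h[i]`
#' is the base activation tendency of channel i in isolation and `J[i, j]` the
#' pairwise functional interaction. The Boltzmann distribution over states
#' `P(V) = exp(-E(V)) / Z` with `E(V) = -sum_i h_i s_i - 1/2 sum_ij J_ij s_i s_j`
#' is the maximum-entropy distribution matching first and second moments.
#' Two equivalent spin conventions are supported: states in \{0,1\}
#' (`zero_one`) or \{-1,+1\} (`plus_minus`); [convert_convention()] maps
#' between them without changing any state probability.
#'
#' @param h numeric vector of length N.
#' @param J numeric N x N symmetric matrix with zero diagonal.
#' @param convention `"zero_one"` or `"plus_minus"`.
#' @return an object of class `mem_params`.
#' @export
mem_params <- function(h, J, convention = c("zero_one", "plus_minus")) {
  convention <- match.arg(convention)
  h <- as.numeric(h)
  J <- as.matrix(J)
  if (length(h) != nrow(J) || nrow(J) != ncol(J))
    abort_invalid("h and J dimensions must agree")
  if (any(!is.finite(h)) || any(!is.finite(J)))
    abort_invalid("parameters must be finite")
  if (!is_symmetric_num(J)) abort_invalid("J must be symmetric")
  if (max(abs(diag(J))) > 1e-12) abort_invalid("J must have zero diagonal")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  structure(list(h = h, J = J, convention = convention), class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat(sprintf("<mem_params> N = %d, convention = %s\n", length(x$h), x$convention))
  invisible(x)
}

n_units <- function(mem) length(mem$h)

#' State energy under the pairwise model
#'
#' `E(V) = -sum_i h_i s_i - 1/2 sum_{i,j} J_ij s_i s_j` (double sum over all
#' ordered pairs, halved). In the zero-one convention the silent (all-off)
#' state has energy exactly 0, which is what makes the silent-state
#' partition-function estimator possible.
#'
#' @param mem a [mem_params()] object.
#' @param state a state vector of length N, or a K x N matrix of states (one
#'   state per row), in the model's convention.
#' @return numeric energy (vector of length K for matrix input).
#' @export
energy <- function(mem, state) {
  stopifnot(inherits(mem, "mem_params"))
  S <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  if (ncol(S) != n_units(mem)) abort_invalid("state length must equal N")
  e <- -as.vector(S %*% mem$h) - 0.5 * rowSums((S %*% mem$J) * S)
  if (is.matrix(state)) e else e[[1]]
}

# all 2^N states as a (2^N) x N matrix; row k (0-based k-1) has bit i of k-1
# in column i (column 1 = least significant bit)
enumerate_states <- function(N, convention = "zero_one") {
  if (N > 20) abort_capability("exact enumeration limited to N <= 20")
  k <- 0:(2^N - 1)
  S <- matrix(0, 2^N, N)
  for (i in seq_len(N)) S[, i] <- bitwAnd(bitwShiftR(k, i - 1L), 1L)
  if (convention == "plus_minus") S <- 2 * S - 1
  S
}

#' Exact Boltzmann distribution by enumeration
#'
#' Enumerates all 2^N states and returns their exact probabilities
#' `P(V_k) = exp(-E(V_k)) / Z`. Feasible only for small systems (N <= 20);
#' used as the ground-truth oracle for samplers, fitters and the silent-state
#' partition-function identity.
#'
#' @param mem a [mem_params()] object with N <= 20.
#' @return a list with `states` (2^N x N matrix in the model's convention),
#'   `p` (probabilities summing to 1), `energies`, `Z` and `log_Z`.
#' @export
exact_distribution <- function(mem) {
  stopifnot(inherits(mem, "mem_params"))
  N <- n_units(mem)
  if (N > 20) abort_capability("exact_distribution requires N <= 20")
  S <- enumerate_states(N, mem$convention)
  E <- energy(mem, S)
  m <- max(-E)
  lse <- m + log(sum(exp(-E - m)))
  list(states = S, p = exp(-E - lse), energies = E, Z = exp(lse), log_Z = lse)
}

#' Convert model parameters between spin conventions
#'
#' The \{0,1\} and \{-1,+1\} parameterizations describe the same family of
#' distributions under the state bijection `s_pm = 2 s_01 - 1`. Substituting
#' into the energy gives `J = 4 J~` and `h_i = 2 h~_i - 2 sum_j J~_ij` (tilde
#' denotes plus-minus parameters); the constant energy offset cancels in the
#' normalization, so state probabilities are preserved exactly.
#'
#' @param mem a [mem_params()] object.
#' @param to target convention.
#' @return a `mem_params` object in the target convention.
#' @export
convert_convention <- function(mem, to = c("zero_one", "plus_minus")) {
  stopifnot(inherits(mem, "mem_params"))
  to <- match.arg(to)
  if (identical(mem$convention, to)) return(mem)
  if (to == "zero_one") {
    J <- 4 * mem$J
    h <- 2 * mem$h - 2 * rowSums(mem$J)
  } else {
    J <- mem$J / 4
    h <- mem$h / 2 + rowSums(mem$J) / 4
  }
  out <- mem_params(h, J, convention = to)
  attr(out, "diagnostics") <- attr(mem, "diagnostics")
  class(out) <- class(mem)
  out
}

#' Metropolis-Hastings sampler for the pairwise model
#'
#' Draws binary states with single-site flip proposals accepted with
#' probability `min(1, exp(-dE))`. One sweep makes N proposals at uniformly
#' random sites; the first `burn_in` sweeps are discarded and every `thin`-th
#' sweep thereafter is kept, reducing autocorrelation between retained
#' samples. Deterministic given `seed`.
#'
#' @param mem a [mem_params()] object (any convention; sampling happens in
#'   zero-one and states are returned as 0/1).
#' @param n_keep number of samples to keep.
#' @param burn_in sweeps discarded before retention (default 1000).
#' @param thin keep every `thin`-th sweep (default 10).
#' @param seed integer RNG seed.
#' @return a [binary_states()] object (N x n_keep).
#' @export
metropolis_sample <- function(mem, n_keep, burn_in = 1000, thin = 10, seed = 1) {
  stopifnot(inherits(mem, "mem_params"))
  if (n_keep < 1) abort_invalid("n_keep must be >= 1")
  m <- convert_convention(mem, "zero_one")
  set.seed(seed)
  draws <- cpp_metropolis(m$h, m$J, as.integer(n_keep),
                          as.integer(burn_in), as.integer(thin))
  binary_states(t(draws), band = "model", threshold = NA_real_,
                downsample = 1L, montage = "referential")
}

#' Empirical and model probabilities of observed states
#'
#' Tabulates every distinct observed state with its empirical frequency and
#' the model's (unnormalized-then-anchored) probability estimate. The
#' partition function is approximated from the silent state: in the zero-one
#' convention `E(all-off) = 0`, so `p(all-off) = 1/Z` and
#' `Z_hat = 1 / p_empirical(all-off)`; hence
#' `p_model(x) = exp(-E(x)) * p_empirical(all-off)`. Requires the silent state
#' to be observed at least once.
#'
#' @param mem a [mem_params()] object (converted to zero-one internally).
#' @param states a [binary_states()] object or binary N x T matrix.
#' @return a tibble of class `state_prob_table` with columns `state`
#'   (bit string), `n_on`, `count`, `p_empirical`, `p_model`, and attribute
#'   `z_hat`.
#' @export
estimate_state_probabilities <- function(mem, states) {
  stopifnot(inherits(mem, "mem_params"))
  m <- convert_convention(mem, "zero_one")
  S <- if (inherits(states, "binary_states")) states$states else as.matrix(states)
  if (nrow(S) != n_units(m)) abort_invalid("states and model dimensions differ")
  Tn <- ncol(S)
  keys <- apply(S, 2, paste0, collapse = "")
  tab <- table(keys)
  silent_key <- paste0(rep("0", nrow(S)), collapse = "")
  if (!silent_key %in% names(tab))
    abort("silent (all-off) state never observed; cannot anchor the partition function",
          class = "memfc_error_silent_state")
  p_silent <- as.numeric(tab[silent_key]) / Tn
  uniq <- names(tab)
  U <- t(vapply(strsplit(uniq, ""), function(ch) as.numeric(ch), numeric(nrow(S))))
  if (nrow(S) == 1) U <- matrix(as.numeric(unlist(strsplit(uniq, ""))), ncol = 1)
  E <- energy(m, U)
  out <- tibble::tibble(
    state = uniq,
    n_on = rowSums(U),
    count = as.integer(tab),
    p_empirical = as.integer(tab) / Tn,
    p_model = exp(-E) * p_silent
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$p_empirical))
  attr(out, "z_hat") <- 1 / p_silent
  attr(out, "n_samples") <- Tn
  class(out) <- c("state_prob_table", class(out))
  out
}

#' Modified Kullback-Leibler divergence
#'
#' `D(P, Q) = sum_x P(x) |log2(P(x) / Q(x))|`. The absolute value (unlike the
#' classical KL divergence) penalizes states whose probability the model
#' overestimates as well as underestimates, which matters because the
#' silent-state-anchored model probabilities are not normalized: without the
#' absolute value, overestimated states would spuriously lower the divergence.
#' Consequently D is not invariant to rescaling Q, by design.
#'
#' @param P empirical probabilities (> 0).
#' @param Q model probabilities / positive weights (> 0), same length.
#' @return non-negative scalar divergence in bits.
#' @export
modified_kl_divergence <- function(P, Q) {
  if (length(P) != length(Q)) abort_invalid("P and Q must have the same length")
  if (any(P <= 0) || any(Q <= 0)) abort_invalid("P and Q entries must be positive")
  sum(P * abs(log2(P / Q)))
}
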