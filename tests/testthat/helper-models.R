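# small planted models and fixtures shared across tests

random_mem <- function(N, seed, h_sd = 0.4, j_sd = 0.35, h_mean = -0.3) {
  set.seed(seed)
  J <- matrix(rnorm(N * N, 0, j_sd), N, N)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  mem_params(rnorm(N, h_mean, h_sd), J)
}

# brute-force Boltzmann probabilities, independent of exact_distribution():
# explicit loop over states and pair sums
oracle_boltzmann <- function(h, J, convention = "zero_one") {
  N <- length(h)
  vals <- if (convention == "zero_one") c(0, 1) else c(-1, 1)
  # expand.grid varies column 1 fastest, matching the package's state order
  states <- unname(as.matrix(expand.grid(rep(list(vals), N))))
  E <- apply(states, 1, function(s) {
    e <- -sum(h * s)
    for (i in seq_len(N)) for (j in seq_len(N))
      e <- e - 0.5 * J[i, j] * s[i] * s[j]
    e
  })
  w <- exp(-E)
  list(states = states, p = w / sum(w), E = E)
}

small_brain <- function(seed = 1, n_atlas = 120, n_electrodes = 16) {
  generate_geometry(n_atlas, n_electrodes, seed = seed)
}
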