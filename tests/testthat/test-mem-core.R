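test_that("energy matches direct substitution and silent-state identity", {
  m <- mem_params(c(0.5, -0.5), matrix(c(0, 1, 1, 0), 2, 2))
  expect_identical(energy(m, c(0, 0)), 0)
  expect_equal(energy(m, c(1, 1)), -1.0)
  # h = 0, J = 0: zero energy for every state
  m0 <- mem_params(numeric(3), matrix(0, 3, 3))
  expect_equal(energy(m0, matrix(rbinom(30, 1, .5), 10, 3)), rep(0, 10))
  expect_error(energy(m, c(1, 0, 1)), class = "memfc_error_invalid")
})

test_that("exact_distribution matches an independent enumeration oracle", {
  m <- random_mem(3, seed = 42)
  d <- exact_distribution(m)
  orc <- oracle_boltzmann(m$h, m$J)
  expect_equal(d$p, orc$p, tolerance = 1e-12)
  expect_equal(d$energies, orc$E, tolerance = 1e-12)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  # degenerate cases
  m1 <- mem_params(0, matrix(0, 1, 1))
  expect_equal(exact_distribution(m1)$p, c(0.5, 0.5))
  m2 <- mem_params(c(0, 0), matrix(0, 2, 2))
  expect_equal(exact_distribution(m2)$p, rep(0.25, 4))
  big <- mem_params(numeric(21), matrix(0, 21, 21))
  expect_error(exact_distribution(big), class = "memfc_error_capability")
})

test_that("normalization holds for random models across sizes", {
  for (N in c(2, 4, 7, 10)) {
    d <- exact_distribution(random_mem(N, seed = N))
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
  }
})

test_that("convention transforms preserve state probabilities exactly", {
  # the printed transform: J = 4 J~ elementwise
  m <- mem_params(c(0.1, -0.2), matrix(c(0, 0.25, 0.25, 0), 2, 2),
                  convention = "plus_minus")
  expect_equal(convert_convention(m, "zero_one")$J[1, 2], 1.0)

  m4 <- random_mem(4, seed = 9)
  pm <- convert_convention(m4, "plus_minus")
  # state bijection s_pm = 2 s_01 - 1 keeps enumeration order, so the
  # probability vectors must agree entry-by-entry
  expect_equal(exact_distribution(m4)$p, exact_distribution(pm)$p,
               tolerance = 1e-12)
  rt <- convert_convention(pm, "zero_one")
  expect_equal(rt$h, m4$h, tolerance = 1e-12)
  expect_equal(rt$J, m4$J, tolerance = 1e-12)
  expect_identical(convert_convention(m4, "zero_one"), m4)
})

test_that("metropolis sampler reproduces the exact distribution", {
  m <- random_mem(3, seed = 5)
  st <- metropolis_sample(m, n_keep = 30000, burn_in = 500, thin = 5, seed = 7)
  key <- colSums(st$states * 2^(0:2)) + 1
  emp <- tabulate(key, 8) / ncol(st$states)
  tv <- 0.5 * sum(abs(emp - exact_distribution(m)$p))
  expect_lt(tv, 0.02)
  # determinism
  st2 <- metropolis_sample(m, n_keep = 500, burn_in = 100, thin = 2, seed = 3)
  st3 <- metropolis_sample(m, n_keep = 500, burn_in = 100, thin = 2, seed = 3)
  expect_identical(st2$states, st3$states)
  # h = 0, J = 0: fair coin flips, chi-square uniformity not rejected
  m0 <- mem_params(numeric(3), matrix(0, 3, 3))
  st0 <- metropolis_sample(m0, n_keep = 20000, burn_in = 200, thin = 3, seed = 1)
  counts <- tabulate(colSums(st0$states * 2^(0:2)) + 1, 8)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("exact sampling converges to model moments at the root-T rate", {
  m <- random_mem(4, seed = 21)
  d <- exact_distribution(m)
  act_true <- as.vector(t(d$states) %*% d$p)
  # monotone on average over seeds, at roughly the root-T rate
  errs <- rowMeans(vapply(1:4, function(s) {
    vapply(c(1e3, 1e4, 1e5), function(Tn) {
      st <- sample_states(m, Tn, method = "exact", seed = 30 + s)
      max(abs(compute_moments(st)$activation - act_true))
    }, numeric(1))
  }, numeric(3)))
  expect_true(all(diff(errs) < 0))
  # O(T^{-1/2}): two-decade T increase should shrink error by ~10x
  expect_lt(errs[3], errs[1] / 3)
})

test_that("state-probability table anchors the partition function at the silent state", {
  # uniform model: every observed state gets p_model equal to the empirical
  # silent-state frequency
  m0 <- mem_params(numeric(3), matrix(0, 3, 3))
  st <- sample_states(m0, 4000, "exact", seed = 2)
  tab <- estimate_state_probabilities(m0, st)
  expect_true(all(abs(tab$p_model - tab$p_empirical[tab$state == "000"]) < 1e-12))
  # p_model(silent) always equals p_empirical(silent)
  m <- random_mem(4, seed = 3)
  st4 <- sample_states(m, 20000, "exact", seed = 4)
  tab4 <- estimate_state_probabilities(m, st4)
  silent <- tab4[tab4$state == "0000", ]
  expect_equal(silent$p_model, silent$p_empirical, tolerance = 1e-14)
  expect_equal(attr(tab4, "z_hat"), 1 / silent$p_empirical, tolerance = 1e-14)
  # rank agreement between model and empirical probabilities for a planted fit
  expect_gt(cor(tab4$p_model, tab4$p_empirical, method = "spearman"), 0.9)
  # silent state absent -> explicit error
  on <- matrix(1L, 3, 10)
  expect_error(estimate_state_probabilities(m0, on),
               class = "memfc_error_silent_state")
})

test_that("modified KL divergence penalizes over- and under-estimation", {
  expect_equal(modified_kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(modified_kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * abs(log2(2)) + 0.5 * abs(log2(2 / 3)),
               tolerance = 1e-12)
  expect_equal(modified_kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.79248,
               tolerance = 1e-4)
  # not scale-invariant in Q, by design (Q is unnormalized)
  d1 <- modified_kl_divergence(c(0.5, 0.5), c(0.3, 0.6))
  d2 <- modified_kl_divergence(c(0.5, 0.5), 2 * c(0.3, 0.6))
  expect_false(isTRUE(all.equal(d1, d2)))
  expect_error(modified_kl_divergence(c(0.5, 0.5), c(0, 1)),
               class = "memfc_error_invalid")
})
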