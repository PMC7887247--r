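test_that("structure-function correlation hits the exact limits", {
  set.seed(1)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_equal(structure_function_correlation(m, m), 1)
  expect_equal(structure_function_correlation(m, -m), -1)
  expect_warning(r <- structure_function_correlation(m * 0, m), "undefined")
  expect_true(is.na(r))
  # connected-only variant uses fewer pairs
  sc <- m; sc[1, 2] <- sc[2, 1] <- 0
  expect_equal(structure_function_correlation(m, sc, use = "connected"),
               cor(upper_tri_vec(m)[upper_tri_vec(sc) > 0],
                   upper_tri_vec(sc)[upper_tri_vec(sc) > 0]))
})

test_that("ROC AUC equals the rank-statistic hand counts", {
  # spec'd four-pair cases
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.7, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  # tie handling: a tied connected/unconnected pair contributes 1/2
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0))$auc, 0.5)
  set.seed(2)
  fcm <- matrix(runif(100), 10, 10); fcm <- (fcm + t(fcm)) / 2; diag(fcm) <- 0
  scm <- matrix(rbinom(100, 1, 0.3), 10, 10); scm <- 1 * (scm + t(scm) > 0)
  diag(scm) <- 0
  r <- roc_auc(fcm, scm)
  w <- upper_tri_vec(fcm); lab <- upper_tri_vec(scm) > 0
  rank_auc <- (sum(rank(w)[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_equal(r$auc, rank_auc, tolerance = 1e-12)
  # matrix input with perfect separation
  sep <- matrix(0, 4, 4)
  sep[upper.tri(sep)] <- c(10, 9, 8, 2, 1, 0.5)
  sep <- sep + t(sep)
  lab3 <- matrix(0, 4, 4); lab3[upper.tri(lab3)] <- c(1, 1, 1, 0, 0, 0)
  lab3 <- lab3 + t(lab3)
  expect_equal(roc_auc(sep, lab3)$auc, 1)
  # single-class labels are rejected
  expect_error(roc_auc(c(1, 2, 3), c(1, 1, 1)), class = "memfc_error_invalid")
})

test_that("AUC approaches chance for label-independent weights", {
  set.seed(3)
  n <- 40
  fcm <- matrix(rnorm(n^2), n, n); fcm <- (fcm + t(fcm)) / 2; diag(fcm) <- 0
  scm <- matrix(rbinom(n^2, 1, 0.5), n, n); scm <- 1 * ((scm + t(scm)) > 0)
  diag(scm) <- 0
  expect_equal(roc_auc(fcm, scm)$auc, 0.5, tolerance = 0.05)
})

test_that("permutation p-values follow the add-one formula and are monotone-invariant", {
  expect_equal(permutation_test(10, rep(1, 9999)), 1 / 10000)
  expect_equal(permutation_test(-10, rep(1, 99)), 1)
  nulls <- seq_len(101)
  expect_equal(permutation_test(51, nulls), (1 + 51) / 102)
  # invariance under joint strictly monotone transform
  set.seed(4)
  obs <- 1.3; nv <- rnorm(500)
  expect_equal(permutation_test(obs, nv),
               permutation_test(exp(obs), exp(nv)))
})

test_that("FDR correction reproduces Benjamini-Hochberg by hand", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_error(fdr_correct(c(0.5, 1.2)), class = "memfc_error_invalid")
})

test_that("cross-frequency similarity recovers planted linear relations", {
  set.seed(5)
  A <- matrix(runif(64), 8, 8); A <- (A + t(A)) / 2; diag(A) <- 0
  # identical matrices: lm warns about a perfect fit, which is the point here
  out <- suppressWarnings(cross_frequency_similarity(list(theta = A, gamma = A)))
  expect_equal(out$slope, 1, tolerance = 1e-10)
  expect_equal(out$intercept, 0, tolerance = 1e-10)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  # planted slope/intercept with small noise
  B <- 0.5 * A + 0.02
  B[upper.tri(B)] <- B[upper.tri(B)] + rnorm(sum(upper.tri(B)), 0, 0.005)
  B <- (B + t(B)) / 2; diag(B) <- 0
  out2 <- cross_frequency_similarity(list(theta = A, high_gamma = B))
  expect_equal(out2$slope, 0.5, tolerance = 0.05)
  expect_lt(abs(out2$intercept - 0.02), 0.01)
  # independent matrices: negligible R^2
  C <- matrix(runif(64), 8, 8); C <- (C + t(C)) / 2; diag(C) <- 0
  expect_lt(cross_frequency_similarity(list(a = A, b = C))$r_squared, 0.2)
  # all band pairs reported
  expect_equal(nrow(cross_frequency_similarity(list(a = A, b = B, c = C))), 3)
})

test_that("stability curves are zero for identical segments and shrink with n", {
  seg <- matrix(rbinom(4 * 50, 1, 0.4), 4, 50)
  same <- replicate(7, seg, simplify = FALSE)
  sc <- stability_curve(same, n_iter = 50, seed = 1)
  expect_true(all(sc$mean_norm_diff == 0))
  # stationary source: decreasing mean difference
  set.seed(6)
  m <- random_mem(4, seed = 60)
  segs <- lapply(1:9, function(k) sample_states(m, 400, "exact", seed = k)$states)
  curve <- stability_curve(segs, n_iter = 150, seed = 2)
  expect_equal(curve$n_hours, 2:5)
  expect_lt(curve$mean_norm_diff[4], curve$mean_norm_diff[1])
  # reproducible under the same seed
  curve2 <- stability_curve(segs, n_iter = 150, seed = 2)
  expect_equal(curve$mean_norm_diff, curve2$mean_norm_diff)
})

test_that("kurtosis comparison flags heavy-tailed interaction weights", {
  set.seed(7)
  g <- rnorm(50000)
  expect_equal(kurtosis_pearson(g), 3, tolerance = 0.15)
  # laplace via difference of exponentials: kurtosis 6
  lap <- rexp(50000) - rexp(50000)
  expect_equal(kurtosis_pearson(lap), 6, tolerance = 0.5)
  # agreement with the e1071 implementation (excess convention + 3)
  skip_if_not_installed("e1071")
  x <- rnorm(2000)^2
  expect_equal(kurtosis_pearson(x), e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
  # sparse heavy-tailed vs dense: paired test direction
  Js <- lapply(1:4, function(k) { v <- rnorm(200, 0, 0.02); v[1:8] <- 1; v })
  Cs <- lapply(1:4, function(k) runif(200, 0.2, 0.6))
  cmp <- distribution_shape_compare(Js, Cs)
  expect_true(all(cmp$table$kurtosis_J > cmp$table$kurtosis_coact))
  expect_lt(cmp$p_value, 0.05)
  expect_error(distribution_shape_compare(Js[1], Cs[1]),
               class = "memfc_error_invalid")
})
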