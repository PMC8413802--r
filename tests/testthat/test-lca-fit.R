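test_that("log-likelihood matches closed forms and the brute-force oracle", {
  y1 <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(lca_loglik(y1, 1, matrix(0.5)), 4 * log(0.5), tolerance = 1e-12)

  # a mixture with identical columns collapses to the single-class model
  set.seed(1)
  y <- matrix(rbinom(40, 1, 0.4), 20, 2)
  rho1 <- matrix(c(0.3, 0.7), 2, 1)
  expect_equal(lca_loglik(y, c(0.5, 0.5), cbind(rho1, rho1)),
               lca_loglik(y, 1, rho1), tolerance = 1e-10)

  # K = 2, J = 2 toy against direct summation over classes
  y2 <- as.matrix(expand.grid(0:1, 0:1))
  pi2 <- c(0.3, 0.7)
  rho2 <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2)
  expect_equal(lca_loglik(y2, pi2, rho2), loglik_brute(y2, pi2, rho2),
               tolerance = 1e-12)

  # label permutation leaves the likelihood unchanged
  expect_equal(lca_loglik(y2, pi2[2:1], rho2[, 2:1]),
               lca_loglik(y2, pi2, rho2), tolerance = 1e-12)
})

test_that("single-class fit is the closed-form solution", {
  set.seed(2)
  y <- matrix(rbinom(150, 1, c(0.2, 0.5, 0.8)), 50, 3, byrow = TRUE)
  f <- lca_fit(y, 1, seed = 1)
  expect_equal(f$pi, 1)
  expect_equal(as.vector(f$rho), colMeans(y), tolerance = 1e-4)
  expect_equal(f$loglik, loglik_brute(y, 1, matrix(colMeans(y), 3, 1)),
               tolerance = 1e-6)
})

test_that("perfectly separated blocks are recovered at the boundary", {
  y <- rbind(matrix(1L, 4, 3), matrix(0L, 4, 3))
  f <- lca_fit(y, 2, n_starts = 10, seed = 1)
  perm <- order(-f$pi * 0 + f$rho[1, ]) # column with high rho last
  expect_equal(sort(f$pi), c(0.5, 0.5), tolerance = 1e-6)
  hi <- which.max(f$rho[1, ]); lo <- which.min(f$rho[1, ])
  expect_true(all(f$rho[, hi] >= 1 - 2e-5))
  expect_true(all(f$rho[, lo] <= 2e-5))
  expect_true(all(pmax(f$posterior[, hi], f$posterior[, lo]) > 1 - 1e-6))
  expect_monotone_ll(f)
})

test_that("EM recovers a well-separated two-class structure", {
  d <- separated_2class(n = 600, j = 6, seed = 3)
  f <- lca_fit(d$y, 2, n_starts = 10, seed = 4)
  perm <- align_labels(f, cbind(rep(0.9, 6), rep(0.1, 6)))
  expect_lt(max(abs(f$rho[, perm] - cbind(rep(0.9, 6), rep(0.1, 6)))), 0.06)
  expect_lt(max(abs(f$pi[perm] - c(0.5, 0.5))), 0.05)
  expect_monotone_ll(f)
  expect_gte(f$n_starts_replicating_best, 2)
})

test_that("posteriors are normalized and consistent with assignments", {
  set.seed(6)
  y <- matrix(rbinom(400, 1, 0.4), 100, 4)
  f <- lca_fit(y, 2, n_starts = 5, seed = 2)
  expect_true(all(abs(rowSums(f$posterior) - 1) < 1e-8))
  expect_equal(f$assignment, apply(f$posterior, 1, which.max))
  expect_monotone_ll(f)
})

test_that("modal assignment takes the argmax and flags exact ties", {
  w1 <- modal_assignment(matrix(c(0.985, 0.006, 0.002, 0.004, 0.003), 1))
  expect_equal(as.integer(w1), 1L)
  w2 <- modal_assignment(matrix(c(0.5, 0.5), 1))
  expect_equal(as.integer(w2), 1L) # tie broken toward the lowest index
  expect_true(attr(w2, "tie"))
  w3 <- modal_assignment(diag(4))
  expect_equal(as.integer(w3), 1:4)
  expect_error(modal_assignment(matrix(c(0.7, 0.6), 1)), "sum")
})

test_that("label alignment finds the permutation and survives noise", {
  ref <- ref_params()$rho
  expect_equal(align_labels(ref, ref), 1:5)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  expect_equal(align_labels(ref[, perm], ref), order(perm))
  set.seed(10)
  noisy <- pmin(pmax(ref + runif(length(ref), -0.02, 0.02), 0), 1)
  expect_equal(align_labels(noisy, ref), 1:5)
  expect_error(align_labels(ref[, 1:4], ref), "dimensions")
})

test_that("permuting class labels keeps posterior/assignment consistency", {
  d <- separated_2class(n = 100, j = 4, seed = 5)
  f <- lca_fit(d$y, 2, n_starts = 5, seed = 5)
  g <- permute_classes(f, c(2L, 1L))
  expect_equal(g$pi, f$pi[2:1])
  expect_equal(g$posterior[, 1], f$posterior[, 2])
  expect_equal(g$assignment, apply(g$posterior, 1, which.max))
})

test_that("asking for more classes than response patterns warns", {
  y <- rbind(matrix(1L, 6, 2), matrix(0L, 6, 2)) # 2 distinct patterns
  expect_warning(lca_fit(y, 3, n_starts = 5, seed = 1), "distinct response patterns")
})

test_that("tidy/glance expose the fit on the published-table scales", {
  d <- separated_2class(n = 150, j = 4, seed = 7)
  f <- lca_fit(d$y, 2, n_starts = 5, seed = 7)
  td <- tidy(f)
  expect_equal(nrow(td), 8)
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  gl <- glance(f)
  expect_equal(gl$bic, -2 * f$loglik + f$n_params * log(f$n))
  expect_s3_class(autoplot(f), "ggplot")
})
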