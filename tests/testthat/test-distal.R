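test_that("classification error matrix matches hand computations", {
  expect_equal(unname(classification_error_matrix(diag(3)[c(1, 2, 3, 2), ])),
               diag(3))
  tau_u <- matrix(0.5, 4, 2)
  q <- classification_error_matrix(tau_u, assignment = c(1L, 1L, 2L, 2L))
  expect_equal(unname(q), matrix(0.5, 2, 2))
  tau <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8))
  q2 <- classification_error_matrix(tau)
  expect_equal(q2[1, ], c(1.7 / 1.9, 0.2 / 1.9), ignore_attr = TRUE)
  expect_equal(rowSums(q2), c(1, 1), ignore_attr = TRUE)
  expect_error(classification_error_matrix(cbind(rep(1, 3), rep(0, 3))),
               "zero posterior mass")
})

test_that("with one-hot posteriors the 3-step estimates are the naive summaries", {
  set.seed(41)
  n <- 300
  w <- sample(1:3, n, TRUE)
  tau <- diag(3)[w, ]
  q <- classification_error_matrix(tau, w)
  expect_equal(unname(q), diag(3))
  yc <- rnorm(n, mean = c(0, 1, 2)[w])
  dc <- distal_continuous(yc, w, q, pi_hat = tabulate(w, 3) / n)
  naive <- vapply(1:3, function(k) mean(yc[w == k]), numeric(1))
  expect_equal(dc$estimates$estimate, naive, tolerance = 1e-6)

  yb <- rbinom(n, 1, c(0.2, 0.5, 0.8)[w])
  db <- distal_categorical(yb, w, q, pi_hat = tabulate(w, 3) / n)
  naive_p <- vapply(1:3, function(k) mean(yb[w == k]), numeric(1))
  p1 <- db$estimates$prob[db$estimates$category == "1"]
  expect_equal(p1, naive_p, tolerance = 1e-6)
  # probability rows sum to one
  sums <- tapply(db$estimates$prob, db$estimates$class, sum)
  expect_equal(unname(as.vector(sums)), rep(1, 3), tolerance = 1e-10)
})

test_that("a single class yields the grand mean and no tests", {
  y <- rnorm(50, 3)
  d <- distal_continuous(y, rep(1L, 50), matrix(1, 1, 1), 1)
  expect_equal(d$estimates$estimate, mean(y))
  expect_equal(nrow(d$pairwise), 0L)
})

test_that("corrected continuous estimates recover generating class means", {
  # step-1 posteriors computed at the true published parameters: isolates
  # the step-3 correction from estimation noise in the measurement model
  rp <- ref_params()
  d <- simulate_lca_matrix(2000, rp$pi, rp$rho, seed = 51)
  rho_c <- pmin(pmax(rp$rho, 1e-12), 1 - 1e-12) # avoid 0 * log(0) in the dot products
  ld <- log(rp$pi)[col(matrix(0, 2000, 5))] +
    d$y %*% log(rho_c) + (1 - d$y) %*% log(1 - rho_c)
  tau <- exp(ld - apply(ld, 1, max))
  tau <- tau / rowSums(tau)
  w <- apply(tau, 1, which.max)
  q <- classification_error_matrix(tau, w)
  pi_hat <- colMeans(tau)

  mu_true <- c(1, 2, 0, -1, -2)
  set.seed(52)
  yc <- rnorm(2000, mu_true[d$class], 1)
  dc <- distal_continuous(yc, w, q, pi_hat)
  expect_lt(max(abs(dc$estimates$estimate - mu_true)), 0.15)
  expect_lt(dc$overall$p_value, 0.001)
  expect_true(all(dc$estimates$se > 0))
})

test_that("correction reduces attenuation relative to naive class means", {
  # moderate-separation two-class model; corrected means should sit closer
  # to the generating means than assigned-class averages in most runs
  rho <- cbind(rep(0.75, 6), rep(0.25, 6))
  mu_true <- c(1, -1)
  wins <- 0L
  for (s in 1:5) {
    d <- simulate_lca_matrix(800, c(0.5, 0.5), rho, seed = 60 + s)
    f <- lca_fit(d$y, 2, n_starts = 10, seed = 60 + s)
    perm <- align_labels(f, rho)
    f <- permute_classes(f, perm)
    set.seed(160 + s)
    yc <- rnorm(800, mu_true[d$class], 1)
    q <- classification_error_matrix(f$posterior, f$assignment)
    dc <- distal_continuous(yc, f$assignment, q, f$pi)
    naive <- vapply(1:2, function(k) mean(yc[f$assignment == k]), numeric(1))
    err_corr <- max(abs(dc$estimates$estimate - mu_true))
    err_naive <- max(abs(naive - mu_true))
    if (err_corr < err_naive) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("homogeneous categorical outcomes are not flagged", {
  set.seed(71)
  w <- sample(1:3, 200, TRUE)
  tau <- diag(3)[w, ]
  q <- classification_error_matrix(tau, w)
  y_const <- rep(1, 200)
  expect_warning(d0 <- distal_categorical(factor(y_const, levels = c(0, 1)),
                                          w, q, tabulate(w, 3) / 200),
                 "dropping")
  expect_equal(d0$overall$p_value, 1)

  yb <- rbinom(200, 1, 0.5) # same rate in every class
  db <- distal_categorical(yb, w, q, tabulate(w, 3) / 200)
  expect_false(any(db$pairwise$significant))
})

test_that("Bonferroni adjustment divides alpha by the number of pairs", {
  mk <- function(k) {
    pw <- tibble::as_tibble(t(utils::combn(k, 2)), .name_repair = ~ c("class_a", "class_b"))
    pw$p_value <- 0.008
    structure(list(type = "continuous", estimates = tibble::tibble(),
                   overall = tibble::tibble(), pairwise = pw,
                   alpha_adjusted = NA_real_, loglik = NA_real_,
                   unstable = FALSE), class = "lca_distal")
  }
  d5 <- pairwise_tests(mk(5), 0.05)
  expect_equal(d5$alpha_adjusted, 0.005)
  expect_false(any(d5$pairwise$significant)) # 0.008 is above 0.05/10
  d2 <- pairwise_tests(mk(2), 0.05)
  expect_equal(d2$alpha_adjusted, 0.05)
  expect_true(all(d2$pairwise$significant))
})

test_that("low step-1 entropy triggers the applicability warning", {
  w <- rep(1:2, each = 20)
  q <- diag(2)
  expect_warning(distal_continuous(rnorm(40), w, q, c(0.5, 0.5), entropy = 0.4),
                 "0.60")
  expect_silent(invisible(distal_continuous(rnorm(40), w, q, c(0.5, 0.5),
                                            entropy = 0.9)))
})
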