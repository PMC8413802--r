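test_that("dichotomization collapses yes codes to 1 and everything else to 0", {
  raw <- tibble::tibble(
    respondent_id = 1:5,
    EPII01 = c(1, 2, 0, 3, 9), # yes-me, yes-other, no, n/a, nondisclosed
    EPII02 = c(0, 0, 0, 0, 0)
  )
  bin <- dichotomize_epii(raw)
  expect_equal(bin$EPII01, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(bin$EPII02, rep(0L, 5))
  expect_equal(attr(bin, "n_nondisclosed"), 1L)
  expect_equal(bin$respondent_id, raw$respondent_id)
})

test_that("dichotomization is total and idempotent on random raw tables", {
  set.seed(42)
  for (rep in 1:5) {
    raw <- tibble::as_tibble(matrix(sample(c(0, 1, 2, 3, 9), 30 * 4, TRUE),
                                    30, 4, dimnames = list(NULL, sprintf("EPII%02d", 1:4))))
    bin <- dichotomize_epii(raw)
    vals <- as.matrix(bin[sprintf("EPII%02d", 1:4)])
    expect_true(all(vals %in% 0:1))
    expect_false(anyNA(vals))
    again <- dichotomize_epii(bin) # 0/1 are themselves valid codes
    expect_equal(as.matrix(again[sprintf("EPII%02d", 1:4)]), vals)
  }
})

test_that("invalid raw codes raise an error naming row and column", {
  raw <- tibble::tibble(EPII01 = c(1, 5), EPII02 = c(0, 0))
  expect_error(dichotomize_epii(raw), "row 2.*EPII01")
})

test_that("domain counts match catalog domain sizes and row sums", {
  ids <- sprintf("EPII%02d", 1:92)
  ones <- tibble::as_tibble(matrix(1L, 1, 92, dimnames = list(NULL, ids)))
  dc <- epii_domain_counts(ones)
  expect_equal(unlist(dc[1, c("work", "home", "social", "health", "positive")],
                      use.names = FALSE),
               c(12L, 19L, 18L, 24L, 19L))
  expect_equal(dc$adverse_total, 12 + 19 + 18 + 24)

  zeros <- tibble::as_tibble(matrix(0L, 1, 92, dimnames = list(NULL, ids)))
  expect_equal(unlist(epii_domain_counts(zeros)[1, c("work", "home", "social",
                                                     "health", "positive")],
                      use.names = FALSE), rep(0L, 5))

  two <- zeros
  two$EPII01 <- 1L # work item
  two$EPII74 <- 1L # positive item
  dc2 <- epii_domain_counts(two)
  expect_equal(unlist(dc2[1, c("work", "home", "social", "health", "positive")],
                      use.names = FALSE),
               c(1L, 0L, 0L, 0L, 1L))

  set.seed(7)
  rand <- tibble::as_tibble(matrix(rbinom(10 * 92, 1, 0.3), 10, 92,
                                   dimnames = list(NULL, ids)))
  dcr <- epii_domain_counts(rand)
  expect_equal(rowSums(dcr[c("work", "home", "social", "health", "positive")]),
               rowSums(rand))
})

test_that("columns without a catalog entry are rejected", {
  bad <- tibble::tibble(EPII93 = 1L)
  expect_error(epii_domain_counts(bad), "EPII93")
})

test_that("scale scoring sums items and mean-imputes nondisclosure", {
  phq_max <- tibble::as_tibble(matrix(3L, 1, 9, dimnames = list(NULL, sprintf("PHQ%02d", 1:9))))
  s <- score_scales(phq_max)
  expect_equal(s$phq9_total, 27)
  expect_true(s$phq9_ge15)

  pss0 <- tibble::as_tibble(matrix(0L, 1, 10, dimnames = list(NULL, sprintf("PSS%02d", 1:10))))
  expect_equal(score_scales(pss0)$pss_total, 0)

  # eight items = 2, one nondisclosed: imputed with the within-scale mean 2
  phq_imp <- tibble::as_tibble(matrix(2L, 1, 9, dimnames = list(NULL, sprintf("PHQ%02d", 1:9))))
  phq_imp$PHQ04 <- 9L
  s2 <- score_scales(phq_imp)
  expect_equal(s2$phq9_total, 18)
  expect_equal(s2$phq9_imputed_fraction, 1 / 9)

  # all nondisclosed: undefined score, missing flag
  phq_all9 <- tibble::as_tibble(matrix(9L, 1, 9, dimnames = list(NULL, sprintf("PHQ%02d", 1:9))))
  s3 <- score_scales(phq_all9)
  expect_true(is.na(s3$phq9_total))
  expect_true(is.na(s3$phq9_ge15))
})

test_that("scale scores are invariant to column order and identity without opt-outs", {
  set.seed(3)
  gad <- tibble::as_tibble(matrix(sample(0:3, 20 * 7, TRUE), 20, 7,
                                  dimnames = list(NULL, sprintf("GAD%02d", 1:7))))
  s1 <- score_scales(gad)
  s2 <- score_scales(gad[sample(names(gad))])
  expect_equal(s1$gad7_total, s2$gad7_total)
  expect_equal(s1$gad7_total, rowSums(gad)) # no opt-outs: plain sum
  expect_equal(s1$gad7_imputed_fraction, rep(0, 20))
})

test_that("screening flags sit at the published cutoffs and are monotone", {
  sc <- tibble::tibble(phq9_total = c(14, 15, 27), gad7_total = c(21, 3, NA),
                       pcptsd_total = c(2, 3, 5))
  fl <- screen_flags(sc)
  expect_equal(fl$phq9_ge15, c(FALSE, TRUE, TRUE))
  expect_equal(fl$gad7_ge15, c(TRUE, FALSE, NA))
  expect_equal(fl$pcptsd_ge3, c(FALSE, TRUE, TRUE))
  # monotone in the total
  tot <- 0:27
  fl2 <- screen_flags(tibble::tibble(phq9_total = tot))
  expect_true(all(diff(fl2$phq9_ge15) >= 0))
})

test_that("Cronbach's alpha matches hand-evaluated and limiting cases", {
  x <- rnorm(20)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)

  # 3 items, pairwise covariance 0.5, unit variances: alpha = 0.75 exactly
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  y <- MASS::mvrnorm(50, mu = rep(0, 3), Sigma = sigma, empirical = TRUE)
  expect_equal(cronbach_alpha(y), 0.75, tolerance = 1e-10)

  set.seed(8)
  z <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(cronbach_alpha(z)), 0.1) # independent items: alpha near 0

  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)), "at least 2 items")
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "zero variance")
})
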