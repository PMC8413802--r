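# shared fixtures: small generators and independent oracles

# brute-force mixture log-likelihood: direct summation over classes per
# respondent, no log-space tricks — the independent oracle for lca_loglik
loglik_brute <- function(y, pi, rho) {
  sum(apply(y, 1L, function(row) {
    log(sum(vapply(seq_along(pi), function(k) {
      pi[k] * prod(ifelse(row == 1, rho[, k], 1 - rho[, k]))
    }, numeric(1))))
  }))
}

# published generator parameters (weights renormalized, 38 x 5 profile)
ref_params <- function() {
  pr <- epii_class_profiles()
  list(pi = unname(epii_class_weights()),
       rho = unname(as.matrix(pr[paste0("class", 1:5)])),
       item_ids = pr$item_id)
}

# two well-separated classes: handy for quick recovery checks
separated_2class <- function(n = 400, j = 6, seed = 1) {
  rho <- cbind(rep(0.9, j), rep(0.1, j))
  simulate_lca_matrix(n, c(0.5, 0.5), rho, seed = seed)
}

expect_monotone_ll <- function(fit) {
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
}
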