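# Class enumeration battery: information criteria, BIC-based evidence
# weights, entropy diagnostics, the parametric bootstrap likelihood-ratio
# test, and the enumeration driver that assembles the fit table.

#' Information criteria for model comparison
#'
#' Computes the four penalized-likelihood criteria used in class
#' enumeration, all on the "lower is better" scale:
#' \itemize{
#'   \item BIC \eqn{= -2LL + d\,\ln N}
#'   \item sample-size-adjusted BIC \eqn{= -2LL + d\,\ln((N+2)/24)}
#'   \item CAIC \eqn{= -2LL + d\,(\ln N + 1)}
#'   \item AWE \eqn{= -2LL + 2d\,(\ln N + 1.5)}
#' }
#'
#' @param loglik Log-likelihood (vectorized over models).
#' @param n_params Number of free parameters d.
#' @param n Sample size (> 1).
#' @return A tibble with columns `bic`, `sabic`, `caic`, `awe`.
#' @export
information_criteria <- function(loglik, n_params, n) {
  if (n <= 1) stop("information criteria require n > 1")
  stopifnot(all(n_params >= 0))
  tibble::tibble(
    bic = -2 * loglik + n_params * log(n),
    sabic = -2 * loglik + n_params * log((n + 2) / 24),
    caic = -2 * loglik + n_params * (log(n) + 1),
    awe = -2 * loglik + 2 * n_params * (log(n) + 1.5)
  )
}

#' BIC-based evidence weights
#'
#' Approximates pairwise Bayes factors between adjacent candidate models
#' and the approximate correct-model probability (cmP) across the whole
#' candidate set, from the Schwarz information \eqn{SIC = -BIC/2}:
#' \eqn{BF_{A,B} = \exp(SIC_A - SIC_B)} and
#' \eqn{cmP_A = \exp(SIC_A) / \sum_j \exp(SIC_j)}, computed in log space.
#' `bf` in row i compares model i against model i+1, so `bf > 10` is
#' strong evidence for the model with fewer classes.
#'
#' @param bic Numeric vector of BIC values for the ordered candidate set.
#' @return A tibble with `bf` and `log_bf` (NA in the last row; `log_bf`
#'   stays finite when `bf` over- or underflows) and `cmp` (sums to 1).
#' @export
evidence_weights <- function(bic) {
  if (length(bic) < 1L) stop("no models")
  sic <- -bic / 2
  log_bf <- c(sic[-length(sic)] - sic[-1L], NA_real_)
  if (length(bic) == 1L) log_bf <- NA_real_
  cmp <- exp(sic - max(sic))
  cmp <- cmp / sum(cmp)
  tibble::tibble(bf = exp(log_bf), log_bf = log_bf, cmp = cmp)
}

#' Relative entropy of a classification
#'
#' The normalized classification-certainty summary
#' \eqn{E = 1 - \sum_{ik} (-\tau_{ik} \ln \tau_{ik}) / (N \ln K)},
#' 1 for perfectly separated classes, 0 for uniformly uncertain
#' posteriors.
#'
#' @param posterior N x K posterior matrix with rows summing to 1, K >= 2.
#' @return Scalar in \[0, 1\].
#' @export
relative_entropy <- function(posterior) {
  tau <- as.matrix(posterior)
  k <- ncol(tau)
  if (k < 2L) stop("relative entropy is undefined for a single class")
  if (any(abs(rowSums(tau) - 1) > 1e-6)) stop("posterior rows must sum to 1")
  h <- -tau * log(tau)
  h[tau == 0] <- 0
  1 - sum(h) / (nrow(tau) * log(k))
}

#' Univariate entropy of single indicators
#'
#' Measures how much a single item separates the classes: the relative
#' entropy of the posterior computed from that item alone,
#' \eqn{\tau^{(j)}_k(y) \propto \pi_k \rho_{jk}^{y}(1-\rho_{jk})^{1-y}},
#' averaged over the model-implied marginal distribution of the item.
#' An item with identical conditional probabilities in every class scores
#' 0; an item that identifies a class deterministically approaches 1.
#'
#' @param pi Class weights, or an `lca_fit` (then `rho` is taken from it).
#' @param rho J x K conditional probability matrix.
#' @param items Which items (row indices) to evaluate; default all.
#' @return A numeric vector of per-item univariate entropies.
#' @export
univariate_entropy <- function(pi, rho = NULL, items = NULL) {
  if (inherits(pi, "lca_fit")) { rho <- pi$rho; pi <- pi$pi }
  rho <- as.matrix(rho)
  k <- length(pi)
  if (k < 2L) stop("univariate entropy is undefined for a single class")
  items <- items %||% seq_len(nrow(rho))
  if (any(items < 1L | items > nrow(rho))) stop("item index outside the model")
  vapply(items, function(j) {
    p1 <- sum(pi * rho[j, ])          # marginal P(y_j = 1)
    h <- 0
    for (yv in c(0L, 1L)) {
      tau <- pi * (if (yv == 1L) rho[j, ] else 1 - rho[j, ])
      py <- sum(tau)
      if (py == 0) next
      tau <- tau / py
      hy <- -tau * log(tau); hy[tau == 0] <- 0
      h <- h + (if (yv == 1L) p1 else 1 - p1) * sum(hy)
    }
    1 - h / log(k)
  }, numeric(1))
}

#' Average posterior probabilities by assigned class
#'
#' The K x K diagnostic table whose row s holds the mean posterior
#' probability of each class among respondents modally assigned to class
#' s; a well-separated solution has a dominant diagonal.
#'
#' @param posterior N x K posterior matrix.
#' @param assignment Modal assignments consistent with `posterior`;
#'   computed if missing.
#' @return A tibble with `assigned_class`, `n`, and `mean_p1` ... columns.
#'   Classes with no assigned respondents yield a row of `NA` (with a
#'   warning).
#' @export
avg_posterior_table <- function(posterior, assignment = NULL) {
  tau <- as.matrix(posterior)
  k <- ncol(tau)
  w <- assignment %||% modal_assignment(tau)
  rows <- purrr::map_dfr(seq_len(k), function(s) {
    sel <- w == s
    if (!any(sel)) {
      warning("no respondents assigned to class ", s)
      m <- rep(NA_real_, k)
    } else {
      m <- colMeans(tau[sel, , drop = FALSE])
    }
    out <- tibble::tibble(assigned_class = s, n = sum(sel))
    for (kk in seq_len(k)) out[[paste0("mean_p", kk)]] <- m[kk]
    out
  })
  rows
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' The observed statistic is \eqn{2(LL_K - LL_{K-1})}. Its null
#' distribution is built by simulating `b` datasets from the fitted
#' (K-1)-class model and refitting both models on each; the p-value uses
#' the add-one convention \eqn{p = (1 + \#\{LR_b \ge LR_{obs}\}) / (b+1)}.
#' Bootstrap refits reuse the parent solutions as warm starts plus a few
#' random starts, trading a little optimism in the null fits for runtime.
#'
#' @param y 0/1 indicator matrix or data frame.
#' @param k Number of classes under the alternative (>= 2).
#' @param b Number of bootstrap replicates (>= 1).
#' @param n_starts Random starts for the two observed-data fits.
#' @param boot_starts Random starts added to the warm start in each
#'   bootstrap refit.
#' @param seed Master seed.
#' @param tol EM convergence tolerance applied consistently to the
#'   observed-data fits and every bootstrap refit (a consistent stopping
#'   rule keeps the reference distribution comparable to the observed
#'   statistic).
#' @param max_iter Maximum EM iterations per fit.
#' @param fit_k,fit_km1 Optional pre-computed `lca_fit`s for K and K-1 on
#'   `y` (skips refitting the observed data).
#' @return A tibble with `k`, `lr_obs`, `p_value`, `b`, `n_failed`
#'   (bootstrap replicates where a refit did not converge; these are
#'   dropped from the reference distribution).
#' @export
bootstrap_lrt <- function(y, k, b = 99, n_starts = 20, boot_starts = 4,
                          seed = 1, tol = 1e-6, max_iter = 3000,
                          fit_k = NULL, fit_km1 = NULL) {
  stopifnot(k >= 2, b >= 1)
  y <- as_binary_matrix(y)
  n <- nrow(y)
  seeds <- derive_seeds(seed, 2L + 2L * b)
  fit_km1 <- fit_km1 %||% lca_fit(y, k - 1L, n_starts = n_starts, tol = tol,
                                  max_iter = max_iter, seed = seeds[1L])
  fit_k <- fit_k %||% lca_fit(y, k, n_starts = n_starts, tol = tol,
                              max_iter = max_iter, seed = seeds[2L])
  lr_obs <- 2 * (fit_k$loglik - fit_km1$loglik)

  warm_fit <- function(yb, kk, warm, seed_s) {
    f_warm <- em_single_start(yb, kk, warm$pi, pmin(pmax(warm$rho, 0.02), 0.98),
                              tol = tol, max_iter = max_iter)
    f <- if (kk == 1L) {
      lca_fit(yb, 1L, seed = seed_s)
    } else {
      tryCatch(lca_fit(yb, kk, n_starts = boot_starts, tol = tol,
                       max_iter = max_iter, seed = seed_s),
               error = function(e) NULL)
    }
    ll <- max(if (!is.null(f)) f$loglik else -Inf,
              if (f_warm$converged) f_warm$loglik else -Inf)
    list(loglik = ll, converged = !is.null(f) || f_warm$converged)
  }

  lr_boot <- rep(NA_real_, b)
  for (r in seq_len(b)) {
    set.seed(seeds[2L + r])
    z <- sample.int(k - 1L + 0L, n, replace = TRUE, prob = fit_km1$pi)
    yb <- matrix(stats::rbinom(n * ncol(y), 1L,
                               t(fit_km1$rho)[cbind(rep(z, each = ncol(y)),
                                                    rep(seq_len(ncol(y)), n))]),
                 n, ncol(y), byrow = TRUE)
    f0 <- warm_fit(yb, k - 1L, fit_km1, seeds[2L + b + r])
    f1 <- warm_fit(yb, k, fit_k, seeds[2L + b + r])
    if (f0$converged && f1$converged) lr_boot[r] <- 2 * (f1$loglik - f0$loglik)
  }
  ok <- !is.na(lr_boot)
  if (!any(ok)) stop("all bootstrap refits failed")
  p <- (1 + sum(lr_boot[ok] >= lr_obs)) / (sum(ok) + 1)
  tibble::tibble(k = k, lr_obs = lr_obs, p_value = p,
                 b = sum(ok), n_failed = sum(!ok))
}

#' Class enumeration with the full fit battery
#'
#' Fits models with 1 up to `k_max` classes and assembles the fit table:
#' parameter counts, log-likelihood, BIC/SABIC/CAIC/AWE, adjacent-model
#' Bayes factors, correct-model probabilities, relative entropy, the
#' naive likelihood-ratio statistic, and (optionally) the parametric
#' bootstrap LRT p-value. Enumeration stops early when a unique maximum
#' cannot be established — the best log-likelihood is not replicated by
#' at least `min_replication` starts — mirroring the practice of adding
#' classes until a trustworthy solution can no longer be determined.
#' The selected model is the smallest-BIC row, with the adjacent Bayes
#' factor and cmP reported as corroboration.
#'
#' @inheritParams lca_fit
#' @param k_max Largest class count to try.
#' @param bootstrap_b If > 0, run [bootstrap_lrt()] with this many
#'   replicates for each K >= 2.
#' @param min_replication Minimum number of starts that must replicate
#'   the best log-likelihood for the solution to count as unique.
#' @return An object of class `lca_enumeration`: list with `fits` (the
#'   `lca_fit`s), `table` (tibble, one row per fitted K), `selected_k`,
#'   `n`, `stopped_early`.
#' @export
lca_enumerate <- function(y, k_max = 7, n_starts = 50, bootstrap_b = 0,
                          tol = 1e-6, max_iter = 1000, seed = 1,
                          min_replication = 2) {
  stopifnot(k_max >= 1)
  y <- as_binary_matrix(y)
  seeds <- derive_seeds(seed, k_max)
  fits <- list()
  stopped_early <- FALSE
  for (k in seq_len(k_max)) {
    f <- tryCatch(lca_fit(y, k, n_starts = n_starts, tol = tol,
                          max_iter = max_iter, seed = seeds[k]),
                  error = function(e) NULL)
    if (is.null(f) || (k > 1L && f$n_starts_replicating_best < min_replication)) {
      stopped_early <- TRUE
      break
    }
    fits[[k]] <- f
  }
  if (length(fits) == 0L) stop("no class solution could be estimated")

  tab <- purrr::map_dfr(fits, glance)
  ew <- evidence_weights(tab$bic)
  tab$bf <- ew$bf
  tab$log_bf <- ew$log_bf
  tab$cmp <- ew$cmp
  tab$lr_naive <- c(NA_real_, 2 * diff(tab$loglik))
  if (bootstrap_b > 0 && length(fits) >= 2L) {
    tab$blrt_p <- c(NA_real_, purrr::map_dbl(2:length(fits), function(k) {
      bootstrap_lrt(y, k, b = bootstrap_b, seed = seeds[k],
                    fit_k = fits[[k]], fit_km1 = fits[[k - 1L]])$p_value
    }))
  }
  selected <- tab$k[which.min(tab$bic)]
  tab$selected <- tab$k == selected
  structure(list(fits = fits, table = tab, selected_k = selected,
                 n = nrow(y), stopped_early = stopped_early),
            class = "lca_enumeration")
}

#' @export
print.lca_enumeration <- function(x, ...) {
  cat(sprintf("Class enumeration over K = 1..%d (N = %d)%s\n",
              max(x$table$k), x$n,
              if (x$stopped_early) " [stopped early: non-replicating solution]" else ""))
  print(as.data.frame(dplyr::mutate(x$table, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, 3)))), row.names = FALSE)
  cat(sprintf("Selected by BIC: %d classes\n", x$selected_k))
  invisible(x)
}

#' @method tidy lca_enumeration
#' @export
tidy.lca_enumeration <- function(x, ...) x$table

#' @method glance lca_enumeration
#' @export
glance.lca_enumeration <- function(x, ...) {
  dplyr::filter(x$table, .data$selected) |>
    dplyr::select(-"selected") |>
    dplyr::mutate(stopped_early = x$stopped_early)
}

#' Information-criterion profile plot for class enumeration
#'
#' @param object An `lca_enumeration`.
#' @param ... Unused.
#' @return A ggplot of BIC/SABIC/CAIC/AWE against the number of classes,
#'   with the BIC-selected model marked.
#' @method autoplot lca_enumeration
#' @export
autoplot.lca_enumeration <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table,
                              c("bic", "sabic", "caic", "awe"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2) +
    ggplot2::labs(x = "number of classes", y = "criterion value") +
    ggplot2::theme_minimal()
}
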