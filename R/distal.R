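# Three-step distal-outcome comparison. Step 1 fits the measurement model,
# step 2 assigns modal classes, step 3 treats the assignment as a fallible
# indicator of true class with the known misclassification matrix
# Q[k, s] = P(assigned = s | true = k), and estimates class-specific
# outcome distributions by ML in the joint model
#   P(W = s, y) = sum_k pi_k Q[k, s] f(y | k),
# with pi and Q held fixed at their step-1 values.

#' Classification error matrix
#'
#' Estimates \eqn{Q_{ks} = P(\mathrm{assigned}=s \mid \mathrm{true}=k)}
#' from the step-1 posteriors:
#' \eqn{Q_{ks} = \sum_i \tau_{ik} 1[W_i=s] / \sum_i \tau_{ik}}.
#' With one-hot posteriors Q is the identity and the three-step
#' correction vanishes.
#'
#' @param posterior N x K posterior matrix.
#' @param assignment Modal assignments; computed from `posterior` if
#'   missing.
#' @return A K x K matrix with rows (true class) summing to 1.
#' @export
classification_error_matrix <- function(posterior, assignment = NULL) {
  tau <- as.matrix(posterior)
  k <- ncol(tau)
  w <- assignment %||% modal_assignment(tau)
  mass <- colSums(tau)
  if (any(mass <= 0)) stop("class with zero posterior mass")
  q <- vapply(seq_len(k), function(s) colSums(tau * (w == s)) / mass,
              numeric(k))
  dimnames(q) <- list(true = NULL, assigned = NULL)
  q
}

entropy_applicability_check <- function(entropy) {
  if (!is.null(entropy) && !is.na(entropy) && entropy < 0.60) {
    warning(sprintf(paste0("step-1 relative entropy %.3f is below 0.60; ",
                           "corrected distal estimates may be unreliable"),
            entropy))
  }
}

# per-respondent class weights pi_k * Q[k, s_i]  (N x K)
threestep_prior <- function(w, q, pi_hat) {
  t(pi_hat * q)[w, , drop = FALSE]
}

#' Compare classes on a continuous distal outcome (corrected 3-step)
#'
#' ML estimation of class-specific normal means and (unequal) variances
#' of an outcome, correcting the naive assigned-class summaries for
#' classification error. Standard errors come from the observed
#' information (numerical Hessian at the optimum); the overall test is a
#' Wald chi-square of mean equality and pairwise tests are Wald z tests
#' with Bonferroni-adjusted significance flags.
#'
#' @param y Numeric outcome, one value per respondent.
#' @param assignment Modal class assignments from step 2.
#' @param q K x K classification error matrix from
#'   [classification_error_matrix()].
#' @param pi_hat Step-1 class weights.
#' @param family_alpha Family-wise alpha for the pairwise comparisons.
#' @param entropy Step-1 relative entropy; a value below 0.60 triggers an
#'   applicability warning (not a hard stop).
#' @param tol Log-likelihood convergence tolerance of the step-3 EM.
#' @return An object of class `lca_distal` with elements `type`,
#'   `estimates` (tibble: class, estimate, se, and for continuous
#'   outcomes `sd`), `overall` (statistic, df, p_value), `pairwise`
#'   (tibble with one row per class pair), `alpha_adjusted`, `loglik`,
#'   `unstable` (logical: a class variance collapsed).
#' @export
distal_continuous <- function(y, assignment, q, pi_hat, family_alpha = 0.05,
                              entropy = NULL, tol = 1e-8) {
  stopifnot(length(y) == length(assignment), is.numeric(y))
  entropy_applicability_check(entropy)
  k <- length(pi_hat)
  pri <- threestep_prior(assignment, q, pi_hat)

  if (k == 1L) {
    est <- tibble::tibble(class = 1L, estimate = mean(y),
                          se = stats::sd(y) / sqrt(length(y)), sd = stats::sd(y))
    return(structure(list(type = "continuous", estimates = est,
                          overall = tibble::tibble(statistic = NA_real_, df = NA_real_,
                                                   p_value = NA_real_),
                          pairwise = tibble::tibble(), alpha_adjusted = family_alpha,
                          loglik = NA_real_, unstable = FALSE),
                     class = "lca_distal"))
  }

  # EM on (mu_k, sigma2_k); start from naive assigned-class moments
  mu <- vapply(seq_len(k), function(s) mean(y[assignment == s]), numeric(1))
  mu[is.nan(mu)] <- mean(y)
  s2 <- vapply(seq_len(k), function(s) {
    v <- stats::var(y[assignment == s]); if (is.na(v) || v == 0) stats::var(y) else v
  }, numeric(1))
  ll_fun <- function(mu, s2) {
    ld <- log(pri) - 0.5 * (log(2 * pi) + log(rep(s2, each = length(y))) +
                              (y - rep(mu, each = length(y)))^2 /
                                rep(s2, each = length(y)))
    dim(ld) <- c(length(y), k)
    sum(row_logsumexp(ld))
  }
  ll_old <- -Inf
  unstable <- FALSE
  for (it in seq_len(10000)) {
    ld <- vapply(seq_len(k), function(kk) {
      log(pri[, kk]) - 0.5 * (log(2 * pi) + log(s2[kk]) + (y - mu[kk])^2 / s2[kk])
    }, numeric(length(y)))
    m <- apply(ld, 1L, max)
    p <- exp(ld - m)
    ll <- sum(log(rowSums(p)) + m)
    tau <- p / rowSums(p)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    nk <- colSums(tau)
    mu <- colSums(tau * y) / nk
    s2 <- colSums(tau * (y - rep(mu, each = length(y)))^2) / nk
    if (any(s2 < 1e-10)) { unstable <- TRUE; s2 <- pmax(s2, 1e-10) }
  }

  # observed-information SEs on theta = (mu, log s2)
  nll <- function(th) -ll_fun(th[seq_len(k)], exp(th[k + seq_len(k)]))
  hess <- pracma::hessian(nll, c(mu, log(s2)))
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 2 * k, 2 * k))
  v_mu <- vc[seq_len(k), seq_len(k), drop = FALSE]
  se <- sqrt(pmax(diag(v_mu), 0))

  cmat <- diff(diag(k)) # (k-1) x k successive-difference contrasts
  wstat <- tryCatch({
    d <- as.vector(cmat %*% mu)
    as.numeric(t(d) %*% solve(cmat %*% v_mu %*% t(cmat)) %*% d)
  }, error = function(e) NA_real_)
  overall <- tibble::tibble(statistic = wstat, df = k - 1,
                            p_value = stats::pchisq(wstat, k - 1, lower.tail = FALSE))

  pairs <- utils::combn(k, 2L)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    vd <- v_mu[a, a] + v_mu[b, b] - 2 * v_mu[a, b]
    z <- (mu[a] - mu[b]) / sqrt(vd)
    tibble::tibble(class_a = a, class_b = b, estimate = mu[a] - mu[b],
                   statistic = z,
                   p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })

  out <- structure(list(
    type = "continuous",
    estimates = tibble::tibble(class = seq_len(k), estimate = mu, se = se,
                               sd = sqrt(s2)),
    overall = overall, pairwise = pw, alpha_adjusted = NA_real_,
    loglik = ll, unstable = unstable
  ), class = "lca_distal")
  pairwise_tests(out, family_alpha)
}

#' Compare classes on a categorical distal outcome (corrected 3-step)
#'
#' ML estimation of class-specific category probabilities of a
#' categorical outcome under the fixed classification-error model. The
#' overall test is a likelihood-ratio chi-square of homogeneity (class-
#' specific probabilities vs a single shared distribution, df
#' (K-1)(C-1)); pairwise tests are Wald tests on log-odds differences
#' with Bonferroni-adjusted flags.
#'
#' @inheritParams distal_continuous
#' @param y Outcome vector (logical, factor, or values coercible to
#'   factor) with at least 2 observed categories; unused factor levels
#'   are dropped with a warning.
#' @return An `lca_distal`; `estimates` has one row per class x category
#'   with `prob` and `se` (for a binary outcome, rows for the "success"
#'   category carry the headline probabilities).
#' @export
distal_categorical <- function(y, assignment, q, pi_hat, family_alpha = 0.05,
                               entropy = NULL, tol = 1e-8) {
  stopifnot(length(y) == length(assignment))
  entropy_applicability_check(entropy)
  f <- if (is.factor(y)) y else factor(y)
  if (any(table(f) == 0L)) {
    warning("dropping categories absent from the data")
    f <- droplevels(f)
  }
  cc <- nlevels(f)
  yi <- as.integer(f)
  k <- length(pi_hat)
  if (cc < 2L) {
    est <- tibble::tibble(class = seq_len(k), category = levels(f)[1L],
                          prob = 1, se = 0)
    return(structure(list(type = "categorical", estimates = est,
                          overall = tibble::tibble(statistic = 0, df = 0, p_value = 1),
                          pairwise = tibble::tibble(), alpha_adjusted = family_alpha,
                          loglik = NA_real_, unstable = FALSE),
                     class = "lca_distal"))
  }
  pri <- threestep_prior(assignment, q, pi_hat)

  # EM on p[k, c]
  p <- matrix(1 / cc, k, cc)
  for (kk in seq_len(k)) {
    sel <- assignment == kk
    if (any(sel)) p[kk, ] <- (tabulate(yi[sel], cc) + 1) / (sum(sel) + cc)
  }
  ll_old <- -Inf
  for (it in seq_len(10000)) {
    lik <- pri * t(p)[yi, , drop = FALSE] # N x K
    rs <- rowSums(lik)
    ll <- sum(log(rs))
    tau <- lik / rs
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    for (c_i in seq_len(cc)) p[, c_i] <- colSums(tau * (yi == c_i))
    p <- p / rowSums(p)
  }

  # homogeneity null: shared category distribution
  p0 <- as.vector(tabulate(yi, cc) / length(yi))
  ll0 <- sum(log(rowSums(pri) * p0[yi]))
  lr <- 2 * (ll - ll0)
  overall <- tibble::tibble(statistic = lr, df = (k - 1) * (cc - 1),
                            p_value = stats::pchisq(lr, (k - 1) * (cc - 1),
                                                    lower.tail = FALSE))

  # observed-information SEs on the logit scale (categories 2..C vs 1)
  eps <- 1e-8
  p_cl <- pmin(pmax(p, eps), 1 - eps)
  theta0 <- as.vector(log(p_cl[, -1L, drop = FALSE] / p_cl[, 1L]))
  nll <- function(th) {
    lg <- cbind(0, matrix(th, k, cc - 1L))
    pm <- exp(lg - apply(lg, 1L, max))
    pm <- pm / rowSums(pm)
    -sum(log(rowSums(pri * t(pm)[yi, , drop = FALSE])))
  }
  hess <- pracma::hessian(nll, theta0)
  vc <- tryCatch(solve(hess),
                 error = function(e) matrix(NA_real_, length(theta0), length(theta0)))
  # delta method to per-cell probability SEs
  grad_cell <- function(kk, c_i) {
    g <- numeric(length(theta0))
    for (c2 in 2:cc) {
      g[(c2 - 2L) * k + kk] <- p[kk, c_i] * ((c_i == c2) - p[kk, c2])
    }
    g
  }
  se <- matrix(NA_real_, k, cc)
  for (kk in seq_len(k)) {
    for (c_i in seq_len(cc)) {
      g <- grad_cell(kk, c_i)
      se[kk, c_i] <- sqrt(max(as.numeric(t(g) %*% vc %*% g), 0))
    }
  }

  est <- purrr::map_dfr(seq_len(k), function(kk) {
    tibble::tibble(class = kk, category = levels(f), prob = p[kk, ],
                   se = se[kk, ])
  })

  pw <- if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    idx <- function(kk) (seq_len(cc - 1L) - 1L) * k + kk # theta indices of class kk
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      d <- theta0[idx(a)] - theta0[idx(b)]
      vv <- vc[idx(a), idx(a), drop = FALSE] + vc[idx(b), idx(b), drop = FALSE] -
        vc[idx(a), idx(b), drop = FALSE] - vc[idx(b), idx(a), drop = FALSE]
      stat <- tryCatch(as.numeric(t(d) %*% solve(vv) %*% d),
                       error = function(e) NA_real_)
      tibble::tibble(class_a = a, class_b = b,
                     estimate = p[a, cc] - p[b, cc], statistic = stat,
                     p_value = stats::pchisq(stat, cc - 1L, lower.tail = FALSE))
    })
  } else tibble::tibble()

  out <- structure(list(type = "categorical", estimates = est,
                        overall = overall, pairwise = pw,
                        alpha_adjusted = NA_real_, loglik = ll,
                        unstable = FALSE),
                   class = "lca_distal")
  pairwise_tests(out, family_alpha)
}

#' Bonferroni-adjusted pairwise significance flags
#'
#' Divides the family-wise alpha by the number of class pairs
#' \eqn{K(K-1)/2} and flags each pairwise comparison whose p-value falls
#' below the adjusted level. With 5 classes and family alpha 0.05 the
#' adjusted threshold is 0.005.
#'
#' @param estimate An `lca_distal`.
#' @param family_alpha Family-wise alpha.
#' @return The `lca_distal` with `alpha_adjusted` set and a `significant`
#'   column in its `pairwise` table.
#' @export
pairwise_tests <- function(estimate, family_alpha = 0.05) {
  stopifnot(inherits(estimate, "lca_distal"))
  n_pairs <- nrow(estimate$pairwise)
  estimate$alpha_adjusted <- if (n_pairs > 0L) family_alpha / n_pairs else family_alpha
  if (n_pairs > 0L) {
    estimate$pairwise$significant <-
      !is.na(estimate$pairwise$p_value) &
      estimate$pairwise$p_value < estimate$alpha_adjusted
  }
  estimate
}

#' @export
print.lca_distal <- function(x, ...) {
  cat(sprintf("Corrected 3-step class comparison (%s outcome)\n", x$type))
  print(as.data.frame(x$estimates), row.names = FALSE)
  if (nrow(x$overall) > 0L && !is.na(x$overall$statistic[1L])) {
    cat(sprintf("Overall chi-square %.2f (df %d), p = %.4g\n",
                x$overall$statistic, x$overall$df, x$overall$p_value))
  }
  sig <- x$pairwise[isTRUE_vec(x$pairwise$significant), ]
  if (nrow(sig) > 0L) {
    cat("Significant pairs (Bonferroni-adjusted alpha ",
        format(x$alpha_adjusted), "): ",
        paste(sprintf("C%d vs C%d", sig$class_a, sig$class_b), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' @method tidy lca_distal
#' @export
tidy.lca_distal <- function(x, ...) x$estimates

#' @method glance lca_distal
#' @export
glance.lca_distal <- function(x, ...) {
  dplyr::bind_cols(x$overall,
                   tibble::tibble(alpha_adjusted = x$alpha_adjusted,
                                  n_significant_pairs = sum(isTRUE_vec(x$pairwise$significant)),
                                  unstable = x$unstable))
}
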