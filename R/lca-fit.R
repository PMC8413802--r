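# Latent class model for dichotomous indicators, estimated by EM with
# multiple random starts. The model is a finite mixture of independent
# Bernoulli responses: P(y_i) = sum_k pi_k prod_j rho_jk^y_ij (1-rho_jk)^(1-y_ij).

RHO_EPS <- 1e-5 # boundary clamp on conditional probabilities

as_binary_matrix <- function(y) {
  if (is.data.frame(y)) {
    cols <- grep("^EPII[0-9]{2}$", names(y), value = TRUE)
    if (length(cols) > 0L) y <- y[cols] else y <- y[setdiff(names(y), "respondent_id")]
    y <- as.matrix(y)
  }
  storage.mode(y) <- "double"
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("indicator matrix must be complete 0/1")
  y
}

# N x K matrix of per-class complete-data log densities log(pi_k) + log P(y_i | k)
class_logdens <- function(y, pi, rho) {
  rho <- pmin(pmax(rho, RHO_EPS), 1 - RHO_EPS)
  a <- log(rho) - log1p(-rho)               # J x K
  sweep(y %*% a, 2L, colSums(log1p(-rho)) + log(pi), `+`)
}

#' Log-likelihood of a binary latent class model
#'
#' Computes \eqn{\sum_i \log \sum_k \pi_k \prod_j \rho_{jk}^{y_{ij}}
#' (1-\rho_{jk})^{1-y_{ij}}} with log-sum-exp stabilization.
#'
#' @param y An N x J 0/1 matrix (or data frame with `EPIInn` columns).
#' @param pi Length-K class weights summing to 1.
#' @param rho J x K conditional endorsement probabilities.
#' @return The scalar log-likelihood.
#' @export
lca_loglik <- function(y, pi, rho) {
  y <- as_binary_matrix(y)
  rho <- as.matrix(rho)
  if (any(rho < 0 | rho > 1)) stop("rho entries must lie in [0, 1]")
  if (nrow(rho) != ncol(y) || length(pi) != ncol(rho)) stop("dimension mismatch")
  sum(row_logsumexp(class_logdens(y, pi, rho)))
}

#' Number of free parameters
#'
#' A K-class model for J dichotomous indicators has `K*J` conditional
#' probabilities plus `K - 1` free mixing weights.
#'
#' @param k Number of classes.
#' @param j Number of indicators.
#' @return Integer parameter count `k*j + (k-1)`.
#' @export
#' @examples
#' n_parameters(5, 38) # 194
n_parameters <- function(k, j) {
  stopifnot(k >= 1, j >= 1)
  as.integer(k * j + (k - 1))
}

#' Modal class assignment
#'
#' Assigns each respondent to the class with the highest posterior
#' probability. Exact ties are broken toward the lowest class index and
#' flagged.
#'
#' @param posterior N x K matrix of posterior class probabilities; rows
#'   must sum to 1.
#' @return Integer vector of assignments with a logical `tie` attribute.
#' @export
modal_assignment <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(abs(rowSums(posterior) - 1) > 1e-6) || any(posterior < 0)) {
    stop("posterior rows must be probabilities summing to 1")
  }
  w <- max.col(posterior, ties.method = "first")
  mx <- posterior[cbind(seq_len(nrow(posterior)), w)]
  tie <- rowSums(abs(posterior - mx) < 1e-12) > 1L
  structure(w, tie = tie)
}

# aggregate duplicate response patterns; EM cost scales with the number
# of distinct patterns rather than respondents
compress_patterns <- function(y) {
  j <- ncol(y)
  key <- if (j <= 50L) {
    as.vector(y %*% 2^(seq_len(j) - 1)) # exact in doubles for j <= 50
  } else {
    apply(y, 1L, paste0, collapse = "")
  }
  idx <- match(key, key[!duplicated(key)])
  keep <- !duplicated(key)
  yp <- y[keep, , drop = FALSE]
  storage.mode(yp) <- "integer"
  list(y = yp, wt = as.numeric(tabulate(idx, sum(keep))), idx = idx)
}

em_single_start <- function(y, k, pi, rho, tol, max_iter) {
  comp <- if (is.list(y)) y else compress_patterns(as_binary_matrix(y))
  f <- .em_core(comp$y, comp$wt, as.numeric(pi), as.matrix(rho), tol,
                as.integer(max_iter), RHO_EPS)
  f$posterior <- f$posterior[comp$idx, , drop = FALSE]
  f
}

#' Fit a binary latent class model by multi-start EM
#'
#' Maximum-likelihood estimation of the K-class model for dichotomous
#' indicators. Each start draws mixing weights from a flat simplex and
#' conditional probabilities uniformly in (0.1, 0.9), runs EM to
#' convergence (absolute log-likelihood change below `tol`), and the best
#' converged start is returned together with the number of starts that
#' replicated the best log-likelihood within `1e-4` — the replication
#' count is the operational check that a unique maximum was found.
#'
#' @param y N x J 0/1 matrix or data frame (`EPIInn` columns are used if
#'   present).
#' @param k Number of classes (>= 1). `k = 1` is closed-form.
#' @param n_starts Number of random starts (default 50).
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Master seed; per-start streams are derived from it so runs
#'   are reproducible.
#' @return An object of class `lca_fit`: a list with elements `k`, `pi`,
#'   `rho` (J x K), `loglik`, `n_params`, `posterior` (N x K),
#'   `assignment`, `entropy`, `converged`, `n_starts_replicating_best`,
#'   `clamp_events`, `n`, `j`, `seed`, `item_ids`.
#' @seealso [tidy.lca_fit()], [glance.lca_fit()], [autoplot.lca_fit()]
#' @export
lca_fit <- function(y, k, n_starts = 50, tol = 1e-6, max_iter = 1000, seed = 1) {
  item_ids <- NULL
  if (is.data.frame(y)) {
    cols <- grep("^EPII[0-9]{2}$", names(y), value = TRUE)
    if (length(cols) > 0L) item_ids <- as.integer(sub("EPII", "", cols))
  }
  y <- as_binary_matrix(y)
  n <- nrow(y); j <- ncol(y)
  stopifnot(k >= 1, n_starts >= 1, tol > 0)
  if (n <= k) stop("need more respondents than classes")
  n_pattern <- nrow(unique(y))
  if (k > n_pattern) {
    warning("k exceeds the number of distinct response patterns (", n_pattern,
            "); solution is degenerate-risk")
  }

  if (k == 1L) {
    rho <- matrix(pmin(pmax(colMeans(y), RHO_EPS), 1 - RHO_EPS), j, 1L)
    fit <- list(pi = 1, rho = rho, loglik = lca_loglik(y, 1, rho),
                posterior = matrix(1, n, 1L), converged = TRUE, iterations = 1L)
    best <- fit
    n_rep <- n_starts
  } else {
    comp <- compress_patterns(y)
    seeds <- derive_seeds(seed, n_starts)
    lls <- rep(NA_real_, n_starts)
    best <- NULL
    for (s in seq_len(n_starts)) {
      set.seed(seeds[s])
      pi0 <- rexp(k); pi0 <- pi0 / sum(pi0)
      rho0 <- matrix(stats::runif(j * k, 0.1, 0.9), j, k)
      f <- em_single_start(comp, k, pi0, rho0, tol, max_iter)
      if (f$converged) lls[s] <- f$loglik
      if (f$converged && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (is.null(best)) stop("no EM start converged")
    n_rep <- sum(!is.na(lls) & abs(lls - best$loglik) < 1e-4)
  }

  clamp_events <- sum(best$rho <= RHO_EPS | best$rho >= 1 - RHO_EPS)
  w <- modal_assignment(best$posterior)
  structure(list(
    k = as.integer(k), pi = as.numeric(best$pi), rho = unname(best$rho),
    loglik = best$loglik, n_params = n_parameters(k, j),
    posterior = unname(best$posterior), assignment = as.integer(w),
    tie = attr(w, "tie"),
    entropy = if (k > 1L) relative_entropy(best$posterior) else NA_real_,
    converged = best$converged,
    n_starts_replicating_best = n_rep, clamp_events = clamp_events,
    n = n, j = j, seed = seed, n_starts = n_starts,
    item_ids = item_ids, ll_trace = best$ll_trace %||% best$loglik
  ), class = "lca_fit")
}

#' Align class labels to a reference parameterization
#'
#' Mixture labels are arbitrary; this finds the permutation of estimated
#' classes minimizing the total absolute difference between conditional-
#' probability columns and a reference (exhaustive optimal assignment,
#' fine for the small K used in class enumeration).
#'
#' @param est J x K estimated conditional probabilities, or an `lca_fit`.
#' @param ref J x K reference conditional probabilities.
#' @return An integer permutation `p` such that `est[, p]` matches `ref`
#'   column-for-column.
#' @export
align_labels <- function(est, ref) {
  if (inherits(est, "lca_fit")) est <- est$rho
  est <- as.matrix(est); ref <- as.matrix(ref)
  if (!all(dim(est) == dim(ref))) stop("est and ref must have equal dimensions")
  k <- ncol(est)
  best_p <- seq_len(k); best_cost <- Inf
  for (p in all_permutations(k)) {
    cost <- sum(abs(est[, p, drop = FALSE] - ref))
    if (cost < best_cost) { best_cost <- cost; best_p <- p }
  }
  as.integer(best_p)
}

#' Permute the class labels of a fitted model
#'
#' Applies a label permutation consistently to weights, conditional
#' probabilities, posteriors and assignments.
#'
#' @param fit An `lca_fit`.
#' @param perm Integer permutation of `1:k`, e.g. from [align_labels()].
#' @return The relabeled `lca_fit`.
#' @export
permute_classes <- function(fit, perm) {
  stopifnot(inherits(fit, "lca_fit"), sort(perm) == seq_len(fit$k))
  fit$pi <- fit$pi[perm]
  fit$rho <- fit$rho[, perm, drop = FALSE]
  fit$posterior <- fit$posterior[, perm, drop = FALSE]
  fit$assignment <- order(perm)[fit$assignment]
  fit
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Binary latent class model: %d classes, %d indicators, N = %d\n",
              x$k, x$j, x$n))
  cat(sprintf("  log-likelihood %.2f (%d parameters), entropy %s\n",
              x$loglik, x$n_params,
              if (is.na(x$entropy)) "n/a" else sprintf("%.3f", x$entropy)))
  cat(sprintf("  class weights: %s\n", paste(sprintf("%.3f", x$pi), collapse = " ")))
  cat(sprintf("  best log-likelihood replicated by %d of %d starts\n",
              x$n_starts_replicating_best, x$n_starts))
  invisible(x)
}

#' Tidy a fitted latent class model
#'
#' @param x An `lca_fit`.
#' @param ... Unused.
#' @return A long tibble with one row per item x class: `item`, `item_id`
#'   (when the fit was given EPII columns), `class`, `estimate` (the
#'   conditional endorsement probability).
#' @method tidy lca_fit
#' @export
tidy.lca_fit <- function(x, ...) {
  ids <- x$item_ids %||% seq_len(x$j)
  out <- tibble::as_tibble(x$rho, .name_repair = ~ paste0("class", seq_len(x$k)))
  out$item_id <- ids
  tidyr::pivot_longer(out, -"item_id", names_to = "class",
                      names_prefix = "class", values_to = "estimate") |>
    dplyr::mutate(class = as.integer(.data$class)) |>
    dplyr::arrange(.data$class, .data$item_id)
}

#' One-row summary of a fitted latent class model
#'
#' @param x An `lca_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `loglik`, `n_params`, `bic`,
#'   `sabic`, `caic`, `awe`, `entropy`, `converged`,
#'   `n_starts_replicating_best`.
#' @method glance lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  ic <- information_criteria(x$loglik, x$n_params, x$n)
  tibble::tibble(
    k = x$k, loglik = x$loglik, n_params = x$n_params,
    bic = ic$bic, sabic = ic$sabic, caic = ic$caic, awe = ic$awe,
    entropy = x$entropy, converged = x$converged,
    n_starts_replicating_best = x$n_starts_replicating_best
  )
}

#' Profile plot of conditional item probabilities
#'
#' @param object An `lca_fit`.
#' @param ... Unused.
#' @return A ggplot: items on the x axis, conditional endorsement
#'   probability on the y axis, one line per class.
#' @method autoplot lca_fit
#' @export
autoplot.lca_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = factor(.data$item_id, levels = unique(.data$item_id)),
    y = .data$estimate,
    colour = factor(.data$class), group = factor(.data$class)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "item", y = "conditional endorsement probability",
                  colour = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
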