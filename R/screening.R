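# Indicator screening: base-rate exclusion, then a Spearman correlation
# screen against the perceived-stress total. Items surviving both screens
# become the LCA indicators.

#' Base-rate filter
#'
#' Flags items whose endorsement base rate falls strictly below a
#' threshold (default 5%); such rare experiences are excluded from the
#' candidate indicator set before the correlation screen. The comparison
#' is strict, so an item at exactly the threshold is kept.
#'
#' @param base_rate Numeric vector of per-item endorsement proportions,
#'   or a binary-matrix tibble from [dichotomize_epii()] whose column
#'   means are used.
#' @param threshold Exclusion threshold as a proportion in (0, 1).
#' @return A tibble with `item_id`, `base_rate` and logical
#'   `excluded_low_base_rate`.
#' @export
#' @examples
#' base_rate_filter(c(0.04, 0.05, 0.50))
base_rate_filter <- function(base_rate, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.data.frame(base_rate)) {
    cols <- grep("^EPII[0-9]{2}$", names(base_rate), value = TRUE)
    if (length(cols) == 0L || nrow(base_rate) == 0L) stop("empty binary matrix")
    ids <- as.integer(sub("EPII", "", cols))
    base_rate <- colMeans(as.matrix(base_rate[cols]))
  } else {
    if (length(base_rate) == 0L) stop("empty base-rate vector")
    ids <- seq_along(base_rate)
  }
  tibble::tibble(
    item_id = ids,
    base_rate = unname(base_rate),
    excluded_low_base_rate = unname(base_rate) < threshold
  )
}

# Spearman rho with midranks plus a p-value: large-sample t approximation
# by default, random-permutation reference for small samples on request.
spearman_one <- function(x, y, alternative = "greater",
                         method = c("t", "permutation"), n_perm = 10000,
                         seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- switch(alternative,
      greater = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
      less = stats::pt(tstat, df = n - 2),
      two.sided = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    )
  } else {
    if (!is.null(seed)) set.seed(seed)
    rx <- rank(x); ry <- rank(y)
    sims <- vapply(seq_len(n_perm), function(i) stats::cor(rx, sample(ry)), numeric(1))
    p <- switch(alternative,
      greater = (1 + sum(sims >= rho)) / (n_perm + 1),
      less = (1 + sum(sims <= rho)) / (n_perm + 1),
      two.sided = (1 + sum(abs(sims) >= abs(rho))) / (n_perm + 1)
    )
  }
  list(rho = rho, p_value = min(p, 1))
}

#' Spearman screen of candidate indicators
#'
#' Correlates each binary item with the perceived-stress total using
#' Spearman's rank correlation (midranks for ties) and tests for a
#' significantly positive association. The default is one-sided
#' (`alternative = "greater"`): the screen is meant to retain items whose
#' endorsement accompanies *higher* stress. Constant columns get an
#' undefined rho, a warning, and are never retained.
#'
#' @param bin Binary-matrix tibble from [dichotomize_epii()] (columns
#'   `EPIInn`).
#' @param pss Numeric vector of PSS totals, one per respondent.
#' @param alpha Significance level for retention.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param method `"t"` for the large-sample t approximation, or
#'   `"permutation"` (recommended for N < 30).
#' @param seed Optional seed used only by the permutation method.
#' @return A tibble with `item_id`, `rho`, `p_value` and logical
#'   `retained` (significance at `alpha`).
#' @export
spearman_screen <- function(bin, pss, alpha = 0.05, alternative = "greater",
                            method = c("t", "permutation"), seed = NULL) {
  method <- match.arg(method)
  cols <- grep("^EPII[0-9]{2}$", names(bin), value = TRUE)
  if (length(pss) != nrow(bin)) stop("pss must have one value per respondent")
  res <- purrr::map(cols, function(cl) {
    spearman_one(bin[[cl]], pss, alternative = alternative, method = method,
                 seed = seed)
  })
  out <- tibble::tibble(
    item_id = as.integer(sub("EPII", "", cols)),
    rho = purrr::map_dbl(res, "rho"),
    p_value = purrr::map_dbl(res, "p_value")
  )
  n_const <- sum(is.na(out$rho))
  if (n_const > 0L) {
    warning(n_const, " constant item column(s); rho undefined, not retained")
  }
  out$retained <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Full indicator screening report
#'
#' Applies both screens — base-rate exclusion, then the Spearman screen on
#' the surviving items — and assembles a per-item report in the shape of
#' the published base-rate/correlation table.
#'
#' @inheritParams spearman_screen
#' @param threshold Base-rate exclusion threshold.
#' @param catalog Item catalog for domain attribution.
#' @return A tibble with `item_id`, `domain`, `base_rate`,
#'   `excluded_low_base_rate`, `rho`, `p_value`, `retained`. Items removed
#'   by the base-rate filter carry `NA` rho/p and are never retained.
#' @export
screen_indicators <- function(bin, pss, threshold = 0.05, alpha = 0.05,
                              alternative = "greater",
                              method = c("t", "permutation"), seed = NULL,
                              catalog = epii_item_catalog()) {
  br <- base_rate_filter(bin, threshold)
  keep_cols <- sprintf("EPII%02d", br$item_id[!br$excluded_low_base_rate])
  sp <- spearman_screen(bin[c(intersect("respondent_id", names(bin)), keep_cols)],
                        pss, alpha = alpha, alternative = alternative,
                        method = method, seed = seed)
  out <- dplyr::left_join(br, sp, by = "item_id")
  out$retained <- !is.na(out$retained) & out$retained
  dplyr::left_join(out, catalog[, c("item_id", "domain")], by = "item_id") |>
    dplyr::relocate("domain", .after = "item_id")
}

#' Select the final indicator set
#'
#' Extracts the retained item ids from a screening report, ordered by
#' catalog id, and attaches the per-domain breakdown.
#'
#' @param report A screening report from [screen_indicators()].
#' @return An integer vector of retained item ids (catalog order) with a
#'   `domain_breakdown` attribute; errors if nothing is retained.
#' @export
select_indicators <- function(report) {
  ids <- sort(report$item_id[report$retained])
  if (length(ids) == 0L) stop("screening retained zero indicators; pipeline cannot proceed")
  if ("domain" %in% names(report)) {
    bd <- table(report$domain[report$retained & !is.na(report$domain)])
    attr(ids, "domain_breakdown") <- bd
  }
  ids
}
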