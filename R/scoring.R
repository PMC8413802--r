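# EPII dichotomization, domain counts, and psychosocial scale scoring.
#
# Raw EPII responses are coded 0 = "No", 1 = "Yes, Me", 2 = "Yes, Person in
# Home", 3 = "Not Applicable", 9 = nondisclosed. Analysis collapses the two
# "Yes" codes to 1 and everything else to 0.

#' Dichotomize raw EPII responses
#'
#' Collapses the four-level raw EPII coding into binary endorsement
#' indicators: "Yes, Me" (1) and "Yes, Person in Home" (2) become 1;
#' "No" (0), "Not Applicable" (3) and the rare nondisclosure code (9)
#' become 0. Treating nondisclosure as not-endorsed is the conservative
#' choice; the number of nondisclosed cells mapped to zero is attached as
#' an attribute and reported by the pipeline run record.
#'
#' @param data A data frame with one row per respondent containing the
#'   columns `EPII01` ... `EPII92` (or any subset named that way) coded
#'   0/1/2/3/9, plus an optional `respondent_id` column.
#' @return A tibble with `respondent_id` and one 0/1 column per EPII item,
#'   in the input row order. Attribute `n_nondisclosed` counts opt-out
#'   cells coerced to 0.
#' @export
#' @examples
#' raw <- tibble::tibble(respondent_id = 1:2, EPII01 = c(1, 3), EPII02 = c(2, 0))
#' dichotomize_epii(raw)
dichotomize_epii <- function(data) {
  cols <- grep("^EPII[0-9]{2}$", names(data), value = TRUE)
  if (length(cols) == 0L) stop("no EPII item columns (EPII01..EPII92) found")
  id <- if ("respondent_id" %in% names(data)) data[["respondent_id"]] else seq_len(nrow(data))
  x <- as.matrix(data[cols])
  bad <- !(x %in% c(0, 1, 2, 3, 9))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(x)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid EPII code %s at row %d, column %s",
                 format(x[w[1L], w[2L]]), w[1L], cols[w[2L]]))
  }
  n_nondisc <- sum(x == 9)
  y <- matrix(as.integer(x %in% c(1, 2)), nrow(x), dimnames = list(NULL, cols))
  out <- tibble::as_tibble(y)
  out <- dplyr::bind_cols(tibble::tibble(respondent_id = id), out)
  attr(out, "n_nondisclosed") <- n_nondisc
  out
}

#' Cumulative EPII experience counts per domain
#'
#' Counts endorsed items per respondent within each EPII thematic domain,
#' plus the adverse total (all domains except positive change). Counts are
#' over whichever catalog items are present in `bin`, so they apply both
#' to the full 92-item inventory and to screened subsets.
#'
#' @param bin A binary matrix tibble as produced by [dichotomize_epii()].
#' @param catalog The item catalog; defaults to [epii_item_catalog()].
#' @return A tibble with `respondent_id`, one count column per domain, and
#'   `adverse_total`.
#' @export
epii_domain_counts <- function(bin, catalog = epii_item_catalog()) {
  cols <- grep("^EPII[0-9]{2}$", names(bin), value = TRUE)
  ids <- as.integer(sub("EPII", "", cols))
  missing_ids <- setdiff(ids, catalog$item_id)
  if (length(missing_ids) > 0L) {
    stop("columns without catalog entry: ", paste0("EPII", missing_ids, collapse = ", "))
  }
  y <- as.matrix(bin[cols])
  doms <- levels(catalog$domain)
  counts <- tibble::as_tibble(lapply(stats::setNames(doms, doms), function(d) {
    keep <- cols[ids %in% catalog$item_id[catalog$domain == d]]
    if (length(keep) == 0L) rep(0L, nrow(y)) else as.integer(rowSums(y[, keep, drop = FALSE]))
  }))
  id <- if ("respondent_id" %in% names(bin)) bin[["respondent_id"]] else seq_len(nrow(bin))
  dplyr::bind_cols(
    tibble::tibble(respondent_id = id),
    counts,
    tibble::tibble(adverse_total = rowSums(counts[setdiff(doms, "positive")]))
  )
}

# score one scale from an item matrix; code 9 (or NA) = nondisclosed.
# Nondisclosed items are imputed with the respondent's own mean over the
# disclosed items of the same scale; all-nondisclosed rows score NA.
score_one_scale <- function(items, item_min, item_max) {
  x <- as.matrix(items)
  x[x == 9] <- NA
  if (any(x < item_min | x > item_max, na.rm = TRUE)) {
    stop("item response outside the scale range [", item_min, ", ", item_max, "]")
  }
  n_miss <- rowSums(is.na(x))
  row_mean <- rowMeans(x, na.rm = TRUE)
  total <- rowSums(x, na.rm = TRUE) + n_miss * row_mean
  total[n_miss == ncol(x)] <- NA_real_
  list(total = total, imputed_fraction = n_miss / ncol(x))
}

#' Score the psychosocial scales
#'
#' Computes total scores for the PSS, PHQ-9, GAD-7, PC-PTSD-5 and the
#' Duke-UNC social support scale from item-level columns, applying the
#' within-respondent mean-imputation rule for nondisclosed items (code 9
#' or `NA`), and derives the screening flags (PHQ-9 >= 15, GAD-7 >= 15,
#' PC-PTSD-5 >= 3).
#'
#' @param data A data frame with item columns named `<PREFIX><nn>`, e.g.
#'   `PSS01` ... `PSS10`, `PHQ01` ... `PHQ09`, `GAD01` ... `GAD07`,
#'   `PTSD01` ... `PTSD05`, `SSQ01` ... `SSQ05`. Scales whose columns are
#'   absent are skipped.
#' @param scales Scale definitions, defaults to [epii_scale_defs()].
#' @return A tibble with `respondent_id`, one `<scale>_total` and
#'   `<scale>_imputed_fraction` column per scored scale, and the flags
#'   from [screen_flags()].
#' @export
score_scales <- function(data, scales = epii_scale_defs()) {
  id <- if ("respondent_id" %in% names(data)) data[["respondent_id"]] else seq_len(nrow(data))
  out <- tibble::tibble(respondent_id = id)
  for (i in seq_len(nrow(scales))) {
    sc <- scales[i, ]
    cols <- sprintf("%s%02d", sc$prefix, seq_len(sc$n_items))
    if (!all(cols %in% names(data))) next
    s <- score_one_scale(data[cols], sc$item_min, sc$item_max)
    out[[paste0(sc$scale, "_total")]] <- s$total
    out[[paste0(sc$scale, "_imputed_fraction")]] <- s$imputed_fraction
  }
  screen_flags(out, scales)
}

#' Screening flags from scale totals
#'
#' Adds the boolean screening indicators used in class comparisons:
#' `phq9_ge15`, `gad7_ge15` and `pcptsd_ge3`. A missing total yields a
#' missing flag.
#'
#' @param scores A data frame with `phq9_total`, `gad7_total` and/or
#'   `pcptsd_total` columns.
#' @param scales Scale definitions carrying the cutoffs.
#' @return `scores` with one logical flag column per cutoff scale present.
#' @export
screen_flags <- function(scores, scales = epii_scale_defs()) {
  cut <- scales[!is.na(scales$cutoff), ]
  for (i in seq_len(nrow(cut))) {
    tot <- paste0(cut$scale[i], "_total")
    if (!tot %in% names(scores)) next
    flag <- paste0(cut$scale[i], "_ge", sub("\\..*$", "", format(cut$cutoff[i])))
    scores[[flag]] <- scores[[tot]] >= cut$cutoff[i]
  }
  scores
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = \frac{m}{m-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' for an N x m item matrix, where \eqn{s_j^2} are item variances and
#' \eqn{s_T^2} the variance of row totals.
#'
#' @param items A numeric matrix or data frame, respondents in rows and
#'   at least two item columns.
#' @return A single numeric value in \eqn{(-\infty, 1]}.
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(200)
#' cronbach_alpha(cbind(z + rnorm(200), z + rnorm(200), z + rnorm(200)))
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  m <- ncol(x)
  if (m < 2L) stop("Cronbach's alpha needs at least 2 items")
  if (nrow(x) < 2L) stop("Cronbach's alpha needs at least 2 respondents")
  v_tot <- stats::var(rowSums(x))
  if (v_tot == 0) stop("total score has zero variance; alpha undefined")
  m / (m - 1) * (1 - sum(apply(x, 2L, stats::var)) / v_tot)
}
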