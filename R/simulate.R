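# Synthetic EPII-style survey generator. Classes are drawn from the
# published mixing proportions; the 38 LCA indicators follow the published
# class-conditional endorsement probabilities; the remaining 54 items are
# class-independent at their published base rates; psychosocial screens
# are class-conditional Bernoulli draws at the published three-step
# probabilities, realized as scale item vectors whose totals land on the
# correct side of the screening cutoff.

#' Draw a binary indicator matrix from a latent class model
#'
#' Low-level generator: class labels from `pi`, then item j as
#' Bernoulli(`rho[j, class]`).
#'
#' @param n Number of respondents.
#' @param pi Class weights.
#' @param rho J x K conditional probabilities.
#' @param seed Seed (mandatory for reproducibility).
#' @return A list with `y` (n x J integer 0/1 matrix) and `class`
#'   (integer labels).
#' @export
simulate_lca_matrix <- function(n, pi, rho, seed) {
  stopifnot(all(pi >= 0), abs(sum(pi) - 1) < 1e-8,
            all(rho >= 0 & rho <= 1))
  rho <- as.matrix(rho)
  set.seed(seed)
  z <- sample.int(length(pi), n, replace = TRUE, prob = pi)
  y <- matrix(0L, n, nrow(rho))
  for (j in seq_len(nrow(rho))) y[, j] <- stats::rbinom(n, 1L, rho[j, z])
  list(y = y, class = z)
}

# allocate an integer total across n_items items each bounded by item_max,
# uniformly at random among feasible roundings
allocate_total <- function(total, n_items, item_max) {
  total <- as.integer(max(0L, min(round(total), n_items * item_max)))
  x <- integer(n_items)
  remaining <- total
  for (i in seq_len(n_items)) {
    slots_left <- n_items - i
    lo <- max(0L, remaining - slots_left * item_max)
    hi <- min(item_max, remaining)
    x[i] <- if (hi > lo) sample(lo:hi, 1L) else lo
    remaining <- remaining - x[i]
  }
  sample(x) # shuffle so early items are not systematically larger
}

# draw a scale total on the requested side of a cutoff
total_given_screen <- function(screen, cutoff, total_max) {
  if (screen) sample(cutoff:total_max, 1L) else sample(0:(cutoff - 1L), 1L)
}

#' Simulate an EPII-style survey
#'
#' Generates a complete synthetic survey table with the statistical
#' structure the analysis pipeline assumes: a 5-class (by default) binary
#' mixture over the 38 published LCA indicators, class-independent
#' non-indicator EPII items at the published base rates, raw 4-level EPII
#' coding (endorsements split into "Yes, Me" / "Yes, Person in Home"),
#' item-level psychosocial scales whose screening status is
#' class-conditional at the published three-step probabilities,
#' class-conditional binary sociodemographics, and continuous PSS /
#' social-support totals with class-specific means. True class labels and
#' every generator parameter are retained for recovery scoring via
#' [truth_table()].
#'
#' @param n Number of respondents.
#' @param seed Master seed (mandatory; same seed, same dataset).
#' @param class_weights Class mixing proportions, default
#'   [epii_class_weights()].
#' @param profiles Indicator profile table (item_id + classK columns),
#'   default [epii_class_profiles()].
#' @param nonindicator_rates Tibble with `item_id`, `base_rate` for the
#'   class-independent items; default derived from
#'   [epii_reference_rates()].
#' @param distal Distal profile table, default [epii_distal_profiles()];
#'   psychosocial rows become scale-item vectors, sociodemographic rows
#'   binary columns.
#' @param pss_means,pss_sd Class-specific means and common SD of the PSS
#'   total (truncated to 0-40, 10 items of 0-4).
#' @param ssq_means,ssq_sd Class-specific means and common SD of the
#'   social-support total (0-25, 5 items of 0-5).
#' @param yes_me_split Probability that an endorsed individual-level item
#'   is coded "Yes, Me" rather than "Yes, Person in Home".
#' @param nondisclosure_rate Per-cell probability of the rare opt-out
#'   code (9) on scale items.
#' @return A tibble with `respondent_id`, `true_class`, raw `EPIInn`
#'   columns (codes 0/1/2/3/9), scale item columns, and one 0/1 column
#'   per sociodemographic outcome. Generator parameters are attached as
#'   attribute `truth` (see [truth_table()]).
#' @export
#' @examples
#' dat <- simulate_epii_survey(200, seed = 1)
#' dplyr::count(dat, true_class)
simulate_epii_survey <- function(n, seed,
                                 class_weights = epii_class_weights(),
                                 profiles = epii_class_profiles(),
                                 nonindicator_rates = NULL,
                                 distal = epii_distal_profiles(),
                                 pss_means = c(24, 26, 22, 16, 12),
                                 pss_sd = 6,
                                 ssq_means = c(14, 13, 15, 19, 20),
                                 ssq_sd = 4,
                                 yes_me_split = 0.8,
                                 nondisclosure_rate = 0.002) {
  if (missing(seed)) stop("seed is mandatory")
  k <- length(class_weights)
  class_weights <- class_weights / sum(class_weights)
  rho <- as.matrix(profiles[grep("^class[0-9]+$", names(profiles))])
  stopifnot(ncol(rho) == k, all(rho >= 0 & rho <= 1))
  indicator_ids <- profiles$item_id

  if (is.null(nonindicator_rates)) {
    rr <- epii_reference_rates()
    nonindicator_rates <- rr[!rr$item_id %in% indicator_ids,
                             c("item_id", "base_rate")]
  }
  stopifnot(all(nonindicator_rates$base_rate >= 0 & nonindicator_rates$base_rate <= 1))

  ind <- simulate_lca_matrix(n, class_weights, rho, seed)
  z <- ind$class
  # subsequent draws continue the stream set by simulate_lca_matrix

  all_ids <- sort(c(indicator_ids, nonindicator_rates$item_id))
  endorsed <- matrix(0L, n, length(all_ids),
                     dimnames = list(NULL, sprintf("EPII%02d", all_ids)))
  endorsed[, sprintf("EPII%02d", indicator_ids)] <- ind$y
  for (i in seq_len(nrow(nonindicator_rates))) {
    cl <- sprintf("EPII%02d", nonindicator_rates$item_id[i])
    endorsed[, cl] <- stats::rbinom(n, 1L, nonindicator_rates$base_rate[i])
  }

  # raw coding: endorsed -> Yes-Me / Yes-Other (household items always 1),
  # not endorsed -> No or N/A
  catalog <- epii_item_catalog()
  household <- catalog$item_id[catalog$household_level]
  raw <- endorsed
  for (cl in colnames(endorsed)) {
    id <- as.integer(sub("EPII", "", cl))
    e <- endorsed[, cl] == 1L
    if (id %in% household) {
      raw[e, cl] <- 1L
    } else {
      raw[e, cl] <- ifelse(stats::runif(sum(e)) < yes_me_split, 1L, 2L)
    }
    raw[!e, cl] <- ifelse(stats::runif(sum(!e)) < 0.8, 0L, 3L)
  }

  scales <- epii_scale_defs()
  psych <- distal[distal$group == "psychosocial", ]
  pmat <- as.matrix(psych[grep("^p[0-9]+$", names(psych))])
  rownames(pmat) <- psych$outcome
  screen_scale <- c(pcptsd_ge3 = "pcptsd", phq9_ge15 = "phq9", gad7_ge15 = "gad7")

  scale_items <- list()
  screens <- list()
  for (o in psych$outcome) {
    sc <- scales[scales$scale == screen_scale[[o]], ]
    cutoff <- as.integer(sc$cutoff)
    total_max <- sc$n_items * sc$item_max
    flag <- stats::rbinom(n, 1L, pmat[o, z]) == 1L
    items <- t(vapply(seq_len(n), function(i) {
      tot <- total_given_screen(flag[i], cutoff, total_max)
      allocate_total(tot, sc$n_items, sc$item_max)
    }, integer(sc$n_items)))
    colnames(items) <- sprintf("%s%02d", sc$prefix, seq_len(sc$n_items))
    scale_items[[o]] <- items
    screens[[o]] <- flag
  }

  # continuous totals: PSS (perceived stress) and SSQ (social support)
  stopifnot(length(pss_means) == k, length(ssq_means) == k)
  pss_total <- round(pmin(pmax(stats::rnorm(n, pss_means[z], pss_sd), 0), 40))
  ssq_total <- round(pmin(pmax(stats::rnorm(n, ssq_means[z], ssq_sd), 0), 25))
  pss_items <- t(vapply(pss_total, allocate_total, integer(10), n_items = 10L,
                        item_max = 4L))
  colnames(pss_items) <- sprintf("PSS%02d", 1:10)
  ssq_items <- t(vapply(ssq_total, allocate_total, integer(5), n_items = 5L,
                        item_max = 5L))
  colnames(ssq_items) <- sprintf("SSQ%02d", 1:5)

  demo <- distal[distal$group == "sociodemographic", ]
  dmat <- as.matrix(demo[grep("^p[0-9]+$", names(demo))])
  demo_cols <- vapply(seq_len(nrow(demo)), function(i) {
    stats::rbinom(n, 1L, dmat[i, z])
  }, integer(n))
  colnames(demo_cols) <- demo$outcome

  out <- dplyr::bind_cols(
    tibble::tibble(respondent_id = seq_len(n), true_class = z),
    tibble::as_tibble(raw),
    tibble::as_tibble(pss_items),
    tibble::as_tibble(scale_items[["phq9_ge15"]]),
    tibble::as_tibble(scale_items[["gad7_ge15"]]),
    tibble::as_tibble(scale_items[["pcptsd_ge3"]]),
    tibble::as_tibble(ssq_items),
    tibble::as_tibble(demo_cols)
  )

  # rare opt-out on scale items (imputed downstream by score_scales)
  if (nondisclosure_rate > 0) {
    sc_cols <- grep("^(PSS|PHQ|GAD|PTSD|SSQ)[0-9]{2}$", names(out), value = TRUE)
    for (cl in sc_cols) {
      hit <- stats::runif(n) < nondisclosure_rate
      out[[cl]][hit] <- 9L
    }
  }

  attr(out, "truth") <- list(
    n = n, seed = seed, pi = class_weights, rho = rho,
    indicator_ids = indicator_ids,
    nonindicator_rates = nonindicator_rates,
    distal = distal, pss_means = pss_means, pss_sd = pss_sd,
    ssq_means = ssq_means, ssq_sd = ssq_sd,
    yes_me_split = yes_me_split, nondisclosure_rate = nondisclosure_rate,
    class = z
  )
  out
}

#' Generator truth record of a synthetic dataset
#'
#' Returns the exact parameters and labels a synthetic dataset was drawn
#' with, for recovery scoring.
#'
#' @param dataset A tibble from [simulate_epii_survey()].
#' @return A list with `pi`, `rho`, `indicator_ids`,
#'   `nonindicator_rates`, `distal`, the continuous-outcome parameters,
#'   `class` labels, `n` and `seed`.
#' @export
truth_table <- function(dataset) {
  tr <- attr(dataset, "truth")
  if (is.null(tr)) stop("dataset carries no generator truth record")
  tr
}
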