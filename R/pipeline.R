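# End-to-end orchestration: score -> dichotomize -> screen -> enumerate ->
# distal comparison -> report bundle. Every stage logs its input/output
# dimensions into the run record; a failure aborts with a stage-tagged
# message.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full profiling pipeline
#'
#' Executes the complete analysis on a survey table (or on a freshly
#' simulated one): psychosocial scale scoring with screening flags, EPII
#' dichotomization and domain counts, base-rate and Spearman indicator
#' screening, class enumeration with the fit battery, classification
#' diagnostics, and corrected three-step class comparisons on the
#' psychosocial screens, continuous totals, cumulative adverse counts and
#' any sociodemographic columns present.
#'
#' @param data Survey tibble in the schema of [simulate_epii_survey()]
#'   (raw `EPIInn` codes plus scale item columns). If `NULL`, a synthetic
#'   survey of size `n` is generated.
#' @param n Size of the simulated survey when `data` is NULL.
#' @param seed Master seed for simulation, estimation and bootstrap.
#' @param k_max Largest class count to enumerate.
#' @param n_starts Random EM starts per model.
#' @param base_rate_threshold Exclusion threshold of the base-rate screen.
#' @param alpha Significance level of the Spearman screen.
#' @param alternative Sidedness of the Spearman screen.
#' @param bootstrap_b Bootstrap LRT replicates (0 = skip).
#' @param family_alpha Family-wise alpha for pairwise class comparisons.
#' @param out_dir If non-NULL, [write_report()] is called on the result.
#' @return An object of class `epii_pipeline`: list with `scores`,
#'   `binary`, `domain_counts`, `screening`, `indicator_ids`,
#'   `enumeration`, `fit` (selected model), `posterior_diagnostics`,
#'   `profile` (conditional probabilities with univariate entropy),
#'   `distal` (named list of `lca_distal`), `run_record`.
#' @export
run_epii_pipeline <- function(data = NULL, n = 1000, seed = 1, k_max = 7,
                              n_starts = 50, base_rate_threshold = 0.05,
                              alpha = 0.05, alternative = "greater",
                              bootstrap_b = 0, family_alpha = 0.05,
                              out_dir = NULL) {
  record <- list(
    config = list(n = n, seed = seed, k_max = k_max, n_starts = n_starts,
                  base_rate_threshold = base_rate_threshold, alpha = alpha,
                  alternative = alternative, bootstrap_b = bootstrap_b,
                  family_alpha = family_alpha,
                  simulated = is.null(data)),
    package_version = as.character(utils::packageVersion("epiilca")),
    stages = list(), warnings = character()
  )
  note <- function(stage, ...) {
    record$stages[[stage]] <<- list(...)
  }

  if (is.null(data)) {
    data <- run_stage("simulate", simulate_epii_survey(n, seed = seed))
    note("simulate", rows = nrow(data), cols = ncol(data))
  }

  scores <- run_stage("score", score_scales(data))
  note("score", rows = nrow(scores), scales = sum(grepl("_total$", names(scores))))

  bin <- run_stage("dichotomize", dichotomize_epii(data))
  record$n_nondisclosed_epii <- attr(bin, "n_nondisclosed") %||% 0L
  counts <- run_stage("domain_counts", epii_domain_counts(bin))
  note("dichotomize", rows = nrow(bin), items = sum(grepl("^EPII", names(bin))))

  screening <- run_stage("screen", screen_indicators(
    bin, scores$pss_total, threshold = base_rate_threshold,
    alpha = alpha, alternative = alternative))
  ids <- run_stage("screen", select_indicators(screening))
  note("screen", candidates = nrow(screening), retained = length(ids))

  bin_sel <- bin[c("respondent_id", sprintf("EPII%02d", ids))]
  enum <- run_stage("enumerate", lca_enumerate(
    bin_sel, k_max = k_max, n_starts = n_starts, bootstrap_b = bootstrap_b,
    seed = seed))
  fit <- enum$fits[[enum$selected_k]]
  note("enumerate", k_fitted = length(enum$fits), k_selected = enum$selected_k)

  diag_tab <- run_stage("diagnostics", avg_posterior_table(fit$posterior,
                                                           fit$assignment))
  profile <- run_stage("diagnostics", {
    td <- tidy(fit)
    wide <- tidyr::pivot_wider(td, names_from = "class", values_from = "estimate",
                               names_prefix = "class")
    wide$univariate_entropy <- if (fit$k > 1L) univariate_entropy(fit) else NA_real_
    dplyr::relocate(wide, "univariate_entropy", .after = "item_id")
  })

  distal <- run_stage("distal", {
    q <- classification_error_matrix(fit$posterior, fit$assignment)
    out <- list()
    for (o in intersect(c("pcptsd_ge3", "phq9_ge15", "gad7_ge15"), names(scores))) {
      out[[o]] <- distal_categorical(scores[[o]], fit$assignment, q, fit$pi,
                                     family_alpha = family_alpha,
                                     entropy = fit$entropy)
    }
    cont <- list(pss_total = scores$pss_total,
                 ssq_total = scores$ssq_total,
                 adverse_total = counts$adverse_total)
    for (o in names(cont)) {
      if (is.null(cont[[o]])) next
      out[[o]] <- distal_continuous(cont[[o]], fit$assignment, q, fit$pi,
                                    family_alpha = family_alpha,
                                    entropy = fit$entropy)
    }
    demo <- intersect(epii_distal_profiles()$outcome[
      epii_distal_profiles()$group == "sociodemographic"], names(data))
    for (o in demo) {
      out[[o]] <- distal_categorical(data[[o]], fit$assignment, q, fit$pi,
                                     family_alpha = family_alpha,
                                     entropy = fit$entropy)
    }
    out
  })
  note("distal", outcomes = length(distal))

  res <- structure(list(
    scores = scores, binary = bin, domain_counts = counts,
    screening = screening, indicator_ids = ids, enumeration = enum,
    fit = fit, posterior_diagnostics = diag_tab, profile = profile,
    distal = distal, run_record = record
  ), class = "epii_pipeline")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.epii_pipeline <- function(x, ...) {
  cat("EPII profiling pipeline run\n")
  cat(sprintf("  respondents: %d, indicators retained: %d\n",
              nrow(x$binary), length(x$indicator_ids)))
  cat(sprintf("  selected model: %d classes (entropy %.3f)\n",
              x$fit$k, x$fit$entropy))
  cat(sprintf("  distal outcomes compared: %d\n", length(x$distal)))
  invisible(x)
}

fmt_prob <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
fmt_pct <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

#' Write the report bundle of a pipeline run
#'
#' Emits deterministic CSVs shaped like the published tables — screening
#' report (base rates as percentages to one decimal, correlations to two
#' decimals), fit-index table, average-posterior diagnostics, conditional
#' item probability profile, and class comparisons — plus a JSON run
#' record with the configuration, seeds and stage dimensions.
#'
#' @param result An `epii_pipeline`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "epii_pipeline"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, file) {
    fp <- file.path(path, file)
    readr::write_csv(df, fp)
    paths <<- c(paths, fp)
  }

  scr <- dplyr::mutate(result$screening,
                       base_rate_pct = fmt_pct(.data$base_rate * 100),
                       rho = fmt_prob(.data$rho),
                       p_value = ifelse(is.na(.data$p_value), "",
                                        sprintf("%.4f", .data$p_value)))
  wr(scr[c("item_id", "domain", "base_rate_pct", "rho", "p_value",
           "excluded_low_base_rate", "retained")], "screening.csv")

  fit_tab <- dplyr::mutate(result$enumeration$table, dplyr::across(
    c("loglik", "bic", "sabic", "caic", "awe"), ~ sprintf("%.2f", .x)))
  wr(fit_tab, "fit_indices.csv")

  diag_tab <- dplyr::mutate(result$posterior_diagnostics, dplyr::across(
    dplyr::starts_with("mean_p"), fmt_prob))
  wr(diag_tab, "posterior_diagnostics.csv")

  prof <- dplyr::mutate(result$profile, dplyr::across(
    dplyr::starts_with("class"), fmt_prob))
  wr(prof, "class_profiles.csv")

  comp <- purrr::imap_dfr(result$distal, function(d, o) {
    est <- if (d$type == "categorical") {
      last_cat <- utils::tail(unique(d$estimates$category), 1L)
      e <- d$estimates[d$estimates$category == last_cat, ]
      tibble::tibble(class = e$class, estimate = e$prob, se = e$se)
    } else {
      d$estimates[c("class", "estimate", "se")]
    }
    wide <- tidyr::pivot_wider(est, names_from = "class",
                               values_from = c("estimate", "se"))
    sig <- d$pairwise[isTRUE_vec(d$pairwise$significant), , drop = FALSE]
    sig_str <- if (nrow(sig) == 0L) "" else paste(
      sprintf("C%d>C%d",
              ifelse(sig$estimate >= 0, sig$class_a, sig$class_b),
              ifelse(sig$estimate >= 0, sig$class_b, sig$class_a)),
      collapse = "; ")
    dplyr::bind_cols(tibble::tibble(outcome = o, type = d$type), wide,
                     tibble::tibble(chisq = d$overall$statistic,
                                    df = d$overall$df,
                                    p_value = d$overall$p_value,
                                    significant_pairs = sig_str))
  })
  comp <- dplyr::mutate(comp, dplyr::across(
    dplyr::starts_with(c("estimate_", "se_")), fmt_prob))
  wr(comp, "class_comparisons.csv")

  rec <- result$run_record
  rec$selected_k <- result$fit$k
  rec$entropy <- result$fit$entropy
  rec$indicator_ids <- result$indicator_ids
  jsonlite::write_json(rec, file.path(path, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  paths <- c(paths, file.path(path, "run_record.json"))
  invisible(paths)
}
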