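#' EPII item catalog
#'
#' The 92 items of the Epidemic-Pandemic Impacts Inventory (EPII), with
#' their thematic domain and a short label key. Domains are Work Life
#' (12 items), Home Life (19), Social Activities and Isolation (18),
#' Emotional/Physical Health and Infection (24), and Positive Change (19).
#' Items 42, 43 and 65 are asked at the household level (a single yes/no,
#' no person attribution).
#'
#' @return A tibble with columns `item_id` (integer 1-92), `domain`
#'   (factor: work, home, social, health, positive), `label` (short key)
#'   and `household_level` (logical).
#' @export
#' @examples
#' dplyr::count(epii_item_catalog(), domain)
epii_item_catalog <- function() {
  domain_of <- integer(92)
  dom <- rep(NA_character_, 92)
  dom[c(1:11, 13)] <- "work"
  dom[c(12, 14:26, 37:41)] <- "home"
  dom[c(27:36, 58:65)] <- "social"
  dom[c(42:57, 66:73)] <- "health"
  dom[74:92] <- "positive"
  labels <- c(
    "laid_off", "reduced_hours", "had_to_lay_off_others", "work_despite_exposure",
    "disinfecting_after_work", "increased_workload", "job_vs_caregiving",
    "hard_transition_wfh", "direct_care_infected", "supportive_care_infected",
    "care_for_dying", "child_out_of_school", "adult_out_of_school",
    "childcare_unavailable", "difficulty_childcare", "harsher_discipline",
    "teaching_child_at_home", "others_moved_in", "caring_for_family_member",
    "had_to_relocate", "became_homeless", "partner_verbal_conflict",
    "partner_physical_conflict", "adult_verbal_conflict", "adult_physical_conflict",
    "child_physical_conflict", "separated_from_family", "no_way_to_contact",
    "cannot_visit_care_facility", "celebrations_cancelled", "travel_cancelled",
    "religious_activities_cancelled", "family_member_critical", "missed_funeral",
    "clubs_sports_cancelled", "no_hobbies", "food_insecurity", "no_clean_water",
    "cannot_pay_bills", "transport_difficulty", "cannot_get_medications",
    "child_behavior_problems", "child_sleep_problems", "mental_health_increase",
    "sleep_problems", "alcohol_substance_increase", "no_mh_treatment_access",
    "mh_treatment_unsatisfactory", "more_screen_time", "other_health_problems",
    "less_exercise", "overeating", "more_sedentary", "procedure_cancelled",
    "no_care_serious_condition", "less_medical_care", "elderly_relative_no_help",
    "quarantine_exposure", "quarantine_symptoms", "isolated_health_risk",
    "limited_physical_closeness", "moved_out_high_risk_job", "relative_quarantined",
    "relative_cannot_return", "household_quarantined", "symptoms_untested_current",
    "tested_positive_current", "symptoms_never_tested", "tested_positive_recovered",
    "treated_severe_symptoms", "hospital_stay", "death_in_home", "death_of_close_person",
    "quality_time_family", "quality_time_partner", "quality_time_children",
    "improved_relationships", "new_connections", "more_exercise", "more_time_outdoors",
    "more_enjoyable_activities", "new_hobbies", "more_appreciative",
    "attention_personal_health", "attention_injury_prevention", "ate_healthier",
    "less_alcohol_substance", "less_screen_time", "volunteered", "donated",
    "greater_meaning_work", "more_productive_work"
  )
  # labels above follow raw item numbering: positions 1..26 are items 1..26,
  # 27..41 are items 27..41 etc.; build in item order directly
  tibble::tibble(
    item_id = 1:92,
    domain = factor(dom, levels = c("work", "home", "social", "health", "positive")),
    label = labels,
    household_level = 1:92 %in% c(42L, 43L, 65L)
  )
}

#' Published EPII base rates and perceived-stress correlations
#'
#' Item-level summary statistics reported for the development sample
#' (N = 652): the endorsement base rate (percent answering "Yes, Me" or
#' "Yes, Person in Home"), the Spearman correlation of the dichotomized
#' item with the Perceived Stress Scale total, and the printed
#' significance stars (0 = ns, 1 = p < .05, 2 = p < .01). These drive the
#' indicator screens and the class-independent part of the synthetic
#' generator.
#'
#' @return A tibble with columns `item_id`, `domain`, `base_rate_pct`,
#'   `base_rate` (proportion), `rho_pss`, `stars`.
#' @export
epii_reference_rates <- function() {
  # item_id, base rate %, Spearman rho with PSS, stars (0 / 1 = p<.05 / 2 = p<.01)
  x <- matrix(c(
    1, 16.0, -0.003, 0,   2, 30.8, -0.008, 0,   3, 7.2, 0.002, 0,
    4, 34.8, 0.125, 2,    5, 32.4, 0.103, 2,    6, 38.7, 0.192, 2,
    7, 18.4, 0.171, 2,    8, 34.5, 0.179, 2,    9, 8.7, 0.063, 0,
    10, 14.1, 0.097, 1,   11, 4.8, 0.107, 2,    12, 33.0, 0.038, 0,
    13, 13.3, 0.063, 0,   14, 11.5, 0.110, 2,   15, 12.3, 0.184, 2,
    16, 13.2, 0.159, 2,   17, 20.7, 0.096, 1,   18, 7.5, 0.032, 0,
    19, 19.2, 0.129, 2,   20, 4.6, 0.082, 1,    21, 0.3, 0.046, 0,
    22, 20.1, 0.185, 2,   23, 1.2, 0.068, 0,    24, 13.0, 0.218, 2,
    25, 0.6, 0.102, 2,    26, 3.1, 0.107, 2,    27, 90.2, 0.021, 0,
    28, 10.7, -0.030, 0,  29, 22.5, -0.021, 0,  30, 90.8, 0.070, 0,
    31, 79.4, 0.011, 0,   32, 51.4, 0.018, 0,   33, 12.4, 0.099, 2,
    34, 24.2, 0.043, 0,   35, 73.9, -0.015, 0,  36, 85.1, 0.080, 1,
    37, 9.5, 0.172, 2,    38, 0.5, -0.008, 0,   39, 7.2, 0.147, 2,
    40, 16.1, 0.100, 1,   41, 6.1, 0.045, 0,    42, 16.1, 0.160, 2,
    43, 12.9, 0.121, 2,   44, 69.8, 0.388, 2,   45, 66.3, 0.268, 2,
    46, 32.7, 0.094, 1,   47, 12.1, 0.149, 2,   48, 13.7, 0.170, 2,
    49, 87.3, 0.077, 1,   50, 21.3, 0.116, 2,   51, 69.8, 0.104, 2,
    52, 66.7, 0.113, 2,   53, 87.6, 0.070, 0,   54, 17.3, -0.034, 0,
    55, 3.7, 0.066, 0,    56, 66.7, 0.095, 1,   57, 9.0, 0.084, 1,
    58, 30.5, 0.074, 0,   59, 10.4, 0.098, 1,   60, 33.9, -0.040, 0,
    61, 44.6, 0.081, 1,   62, 3.5, 0.061, 0,    63, 14.9, 0.073, 0,
    64, 6.4, 0.027, 0,    65, 13.3, 0.092, 1,   66, 2.8, 0.046, 0,
    67, 0.6, 0.037, 0,    68, 18.1, 0.096, 1,   69, 1.4, 0.025, 0,
    70, 2.6, 0.082, 1,    71, 0.5, 0.029, 0,    72, 0.2, 0.052, 0,
    73, 4.9, 0.063, 0,    74, 67.2, 0.091, 1,   75, 51.1, -0.039, 0,
    76, 36.2, 0.017, 0,   77, 35.7, 0.069, 0,   78, 22.4, 0.105, 2,
    79, 27.0, 0.001, 0,   80, 45.2, 0.025, 0,   81, 57.4, -0.087, 0,
    82, 28.8, 0.008, 0,   83, 81.3, 0.051, 0,   84, 54.3, 0.023, 0,
    85, 41.4, 0.095, 1,   86, 33.3, 0.000, 0,   87, 12.7, 0.057, 0,
    88, 5.5, -0.009, 0,   89, 19.3, -0.009, 0,  90, 34.0, 0.045, 0,
    91, 33.7, 0.068, 0,   92, 26.1, -0.017, 0
  ), ncol = 4, byrow = TRUE)
  cat <- epii_item_catalog()
  out <- tibble::tibble(
    item_id = as.integer(x[, 1]),
    base_rate_pct = x[, 2],
    rho_pss = x[, 3],
    stars = as.integer(x[, 4])
  )
  out <- dplyr::arrange(out, .data$item_id)
  dplyr::transmute(
    dplyr::left_join(out, cat[, c("item_id", "domain")], by = "item_id"),
    item_id = .data$item_id, domain = .data$domain,
    base_rate_pct = .data$base_rate_pct,
    base_rate = .data$base_rate_pct / 100,
    rho_pss = .data$rho_pss, stars = .data$stars
  )
}

#' Published 5-class solution: conditional item probabilities
#'
#' Conditional probabilities of endorsing each of the 38 retained LCA
#' indicators given latent class membership, together with the published
#' univariate entropy score for each item. Class 1 is the
#' parents/high-exposure class, class 2 young adults/high exposure,
#' class 3 older adults/moderate exposure, class 4 young parents/high
#' work, class 5 older adults/low exposure.
#'
#' @return A tibble with columns `item_id`, `univariate_entropy`, and
#'   `class1` ... `class5` (conditional endorsement probabilities).
#' @seealso [epii_class_weights()], [simulate_epii_survey()]
#' @export
epii_class_profiles <- function() {
  x <- matrix(c(
    4, 0.169, 0.45, 0.54, 0.06, 0.91, 0.06,
    5, 0.146, 0.42, 0.62, 0.07, 0.75, 0.02,
    6, 0.084, 0.51, 0.65, 0.20, 0.65, 0.13,
    7, 0.126, 0.65, 0.28, 0.02, 0.06, 0.05,
    8, 0.063, 0.54, 0.59, 0.32, 0.25, 0.11,
    10, 0.075, 0.14, 0.24, 0.03, 0.39, 0.01,
    14, 0.127, 0.55, 0.01, 0.00, 0.07, 0.01,
    15, 0.168, 0.65, 0.01, 0.00, 0.00, 0.02,
    16, 0.162, 0.67, 0.03, 0.00, 0.03, 0.01,
    17, 0.182, 0.84, 0.01, 0.02, 0.18, 0.08,
    19, 0.093, 0.50, 0.43, 0.04, 0.07, 0.08,
    22, 0.067, 0.37, 0.46, 0.14, 0.10, 0.03,
    24, 0.067, 0.19, 0.40, 0.10, 0.04, 0.00,
    37, 0.041, 0.17, 0.21, 0.07, 0.04, 0.02,
    39, 0.037, 0.10, 0.19, 0.05, 0.04, 0.02,
    40, 0.043, 0.13, 0.38, 0.17, 0.08, 0.08,
    33, 0.049, 0.12, 0.37, 0.10, 0.08, 0.02,
    36, 0.036, 0.93, 0.94, 0.85, 0.83, 0.73,
    59, 0.041, 0.17, 0.27, 0.07, 0.04, 0.03,
    61, 0.039, 0.34, 0.68, 0.45, 0.45, 0.36,
    65, 0.039, 0.15, 0.32, 0.10, 0.09, 0.07,
    42, 0.154, 0.73, 0.06, 0.04, 0.02, 0.02,
    43, 0.112, 0.56, 0.04, 0.05, 0.02, 0.01,
    44, 0.175, 0.88, 0.90, 0.95, 0.57, 0.06,
    45, 0.124, 0.76, 0.91, 0.86, 0.53, 0.16,
    46, 0.048, 0.41, 0.47, 0.40, 0.22, 0.11,
    47, 0.072, 0.14, 0.43, 0.10, 0.00, 0.02,
    48, 0.075, 0.17, 0.45, 0.13, 0.01, 0.00,
    49, 0.038, 0.95, 0.90, 0.92, 0.81, 0.75,
    50, 0.060, 0.22, 0.45, 0.28, 0.05, 0.07,
    51, 0.039, 0.71, 0.87, 0.75, 0.61, 0.55,
    52, 0.053, 0.81, 0.83, 0.69, 0.62, 0.40,
    56, 0.037, 0.73, 0.80, 0.71, 0.49, 0.61,
    57, 0.041, 0.14, 0.24, 0.04, 0.06, 0.04,
    68, 0.033, 0.21, 0.28, 0.15, 0.25, 0.07,
    74, 0.033, 0.82, 0.62, 0.64, 0.73, 0.57,
    78, 0.030, 0.20, 0.36, 0.23, 0.20, 0.15,
    85, 0.033, 0.36, 0.64, 0.40, 0.36, 0.37
  ), ncol = 7, byrow = TRUE)
  tibble::tibble(
    item_id = as.integer(x[, 1]),
    univariate_entropy = x[, 2],
    class1 = x[, 3], class2 = x[, 4], class3 = x[, 5],
    class4 = x[, 6], class5 = x[, 7]
  )
}

#' Published class mixing proportions
#'
#' The five class proportions of the published solution (printed to three
#' decimals, sum 0.999), renormalized to sum exactly to one.
#'
#' @return A named numeric vector of length 5 summing to 1.
#' @export
epii_class_weights <- function() {
  w <- c(class1 = 0.181, class2 = 0.144, class3 = 0.314,
         class4 = 0.173, class5 = 0.187)
  w / sum(w)
}

#' Published class-conditional distal profiles
#'
#' Class-specific probabilities (with standard errors) of binary
#' sociodemographic characteristics and psychosocial screens, as estimated
#' for the published 5-class solution by classification-error-corrected
#' three-step comparison. These serve as the default class-conditional
#' Bernoulli rates of the synthetic generator's distal outcomes.
#'
#' @return A tibble with columns `outcome`, `group` (sociodemographic or
#'   psychosocial), `p1`..`p5` (class-conditional probabilities),
#'   `se1`..`se5`, and `chisq` (published overall test statistic).
#' @export
epii_distal_profiles <- function() {
  rows <- list(
    list("age_ge60", "sociodemographic", c(.025, .081, .312, .178, .420), c(.015, .048, .039, .043, .057), 106.35),
    list("age_le29", "sociodemographic", c(.070, .299, .160, .218, .074), c(.031, .074, .034, .047, .039), 14.85),
    list("male", "sociodemographic", c(.098, .101, .198, .106, .212), c(.036, .049, .033, .050, .042), 8.35),
    list("racial_ethnic_minority", "sociodemographic", c(.084, .218, .056, .119, .104), c(.027, .050, .023, .035, .033), 9.06),
    list("living_with_partner", "sociodemographic", c(.882, .659, .646, .778, .729), c(.034, .136, .066, .047, .046), 24.80),
    list("young_child_in_home", "sociodemographic", c(.923, .114, .089, .217, .067), c(.027, .054, .028, .051, .026), 745.75),
    list("adolescent_in_home", "sociodemographic", c(.313, .027, .106, .272, .058), c(.045, .038, .032, .055, .028), 37.41),
    list("young_adult_child_in_home", "sociodemographic", c(.131, .164, .162, .298, .136), c(.033, .047, .032, .051, .035), 8.02),
    list("person_over60_in_home", "sociodemographic", c(.090, .345, .380, .249, .491), c(.027, .126, .048, .071, .062), 73.26),
    list("employed", "sociodemographic", c(.793, .658, .650, .922, .662), c(.039, .106, .045, .036, .058), 38.86),
    list("laid_off_unemployed", "sociodemographic", c(.191, .326, .154, .096, .113), c(.038, .100, .036, .045, .040), 9.08),
    list("public_or_no_insurance", "sociodemographic", c(.862, .861, .794, .967, .692), c(.033, .056, .034, .019, .057), 42.58),
    list("retired", "sociodemographic", c(.018, .024, .194, .000, .221), c(.013, .029, .033, .000, .047), 74.66),
    list("student", "sociodemographic", c(.104, .231, .095, .095, .023), c(.031, .064, .024, .036, .017), 18.42),
    list("pcptsd_ge3", "psychosocial", c(.325, .498, .277, .087, .051), c(.044, .086, .043, .043, .022), 65.50),
    list("phq9_ge15", "psychosocial", c(.369, .645, .438, .208, .009), c(.048, .073, .059, .052, .015), 189.50),
    list("gad7_ge15", "psychosocial", c(.451, .513, .382, .183, .000), c(.050, .092, .050, .059, .000), 214.86)
  )
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      outcome = r[[1]], group = r[[2]],
      p1 = r[[3]][1], p2 = r[[3]][2], p3 = r[[3]][3], p4 = r[[3]][4], p5 = r[[3]][5],
      se1 = r[[4]][1], se2 = r[[4]][2], se3 = r[[4]][3], se4 = r[[4]][4], se5 = r[[4]][5],
      chisq = r[[5]]
    )
  })
}

#' Published class-enumeration fit table
#'
#' Log-likelihoods and parameter counts printed for the 1- to 7-class
#' solutions on the development sample (N = 652). Used as inputs for
#' recomputing information criteria (the fitted models themselves cannot
#' be re-estimated because respondent-level data are not shared).
#'
#' @return A tibble with columns `k`, `d`, `loglik`, and the printed
#'   `bic` and `sabic` values.
#' @export
epii_reference_fit <- function() {
  tibble::tibble(
    k = 1:7,
    d = c(38L, 77L, 116L, 155L, 194L, 233L, 272L),
    loglik = c(-12117.21, -11376.82, -11061.00, -10912.56,
               -10785.57, -10697.33, -10638.31),
    bic = c(24480.67, 23252.61, 22873.93, 22829.52,
            22828.27, 22904.51, 23039.00),
    sabic = c(24360.02, 23008.13, 22505.64, 22337.40,
              22212.32, 22164.73, 22175.59)
  )
}

#' Psychosocial scale definitions
#'
#' Item counts, per-item response ranges, column prefixes and screening
#' cutoffs for the five scales scored by [score_scales()]: the Perceived
#' Stress Scale (PSS, 10 items, 0-4), Patient Health Questionnaire-9
#' (PHQ-9, 9 items, 0-3, screen at >= 15), Generalized Anxiety Disorder-7
#' (GAD-7, 7 items, 0-3, screen at >= 15), Primary Care PTSD Screen for
#' DSM-5 (PC-PTSD-5, 5 yes/no items, screen at >= 3), and the Duke-UNC
#' Social Support Questionnaire (5 items, 0-5).
#'
#' @return A tibble with columns `scale`, `prefix`, `n_items`, `item_min`,
#'   `item_max`, `cutoff` (NA when the scale has no screening cutoff).
#' @export
epii_scale_defs <- function() {
  tibble::tibble(
    scale = c("pss", "phq9", "gad7", "pcptsd", "ssq"),
    prefix = c("PSS", "PHQ", "GAD", "PTSD", "SSQ"),
    n_items = c(10L, 9L, 7L, 5L, 5L),
    item_min = c(0L, 0L, 0L, 0L, 0L),
    item_max = c(4L, 3L, 3L, 1L, 5L),
    cutoff = c(NA_real_, 15, 15, 3, NA_real_)
  )
}
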