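# Published ADNI-1 reference values shipped with the package: the cohort
# summary statistics the synthetic simulator is calibrated to, the
# edge-threshold defaults, and the reference classification results used
# for internal-consistency checks of the metric definitions.

#' ADNI-1 baseline class counts
#'
#' Diagnosis counts of the ADNI-1 baseline cohort this framework emulates:
#' 229 cognitively normal (CN), 382 mild cognitive impairment (MCI) and
#' 187 Alzheimer's disease (AD) subjects.
#'
#' @return Named integer vector with elements `CN`, `MCI`, `AD`.
#' @export
adni1_class_counts <- function() {
  c(CN = 229L, MCI = 382L, AD = 187L)
}

#' ADNI-1 covariate calibration table
#'
#' Per-diagnosis summary statistics of the ADNI-1 baseline cohort used to
#' calibrate [generate_cohort()]: mean and SD for each quantitative
#' covariate, and category probabilities for gender and ApoE4 allele count.
#'
#' @return A list with `quantitative` (tibble: `variable`, `diagnosis`,
#'   `mean`, `sd`, `lower`, `upper` clip bounds) and `categorical` (tibble:
#'   `variable`, `diagnosis`, `level`, `prob`).
#' @export
adni1_covariate_params <- function() {
  qn <- function(variable, ad, mci, cn, lower = -Inf, upper = Inf) {
    tibble(variable = variable,
           diagnosis = c("AD", "MCI", "CN"),
           mean = c(ad[1], mci[1], cn[1]),
           sd = c(ad[2], mci[2], cn[2]),
           lower = lower, upper = upper)
  }
  quantitative <- bind_rows(
    qn("age",      c(75.3, 7.5), c(74.7, 7.5), c(75.9, 5.0), lower = 40, upper = 100),
    qn("MMSE",     c(23.3, 2.0), c(27.3, 1.8), c(29.1, 1.0), lower = 0, upper = 30),
    qn("CDR_SB",   c(4.4, 1.6),  c(1.6, 0.9),  c(0.0, 0.1),  lower = 0, upper = 18),
    qn("ADAS11",   c(19.7, 4.9), c(11.5, 4.4), c(6.2, 2.9),  lower = 0, upper = 70),
    qn("ADAS13",   c(30.3, 6.1), c(18.7, 6.2), c(9.5, 4.2),  lower = 0, upper = 85),
    qn("FAQ",      c(13.2, 6.8), c(3.8, 4.4),  c(0.1, 0.6),  lower = 0, upper = 30),
    qn("ADNI_MEM", c(-0.9, 0.6), c(-0.1, 0.6), c(1.0, 0.5)),
    qn("ADNI_EF",  c(-1.0, 0.9), c(-0.1, 0.9), c(0.6, 0.7)),
    qn("ADNI_LAN", c(-0.8, 0.9), c(-0.1, 0.8), c(0.8, 0.7)),
    qn("ADNI_VS",  c(-0.6, 0.9), c(-0.1, 0.8), c(0.2, 0.6))
  )
  cat_tbl <- function(variable, levels, ad, mci, cn) {
    bind_rows(
      tibble(variable = variable, diagnosis = "AD", level = levels, prob = ad / sum(ad)),
      tibble(variable = variable, diagnosis = "MCI", level = levels, prob = mci / sum(mci)),
      tibble(variable = variable, diagnosis = "CN", level = levels, prob = cn / sum(cn))
    )
  }
  categorical <- bind_rows(
    cat_tbl("gender", c("M", "F"), c(98, 89), c(245, 137), c(119, 110)),
    cat_tbl("apoe4", c("0", "1", "2"), c(64, 87, 36), c(171, 161, 43), c(168, 56, 5))
  )
  list(quantitative = quantitative, categorical = categorical)
}

#' Names of the nine neuropsychological scores
#'
#' Column names of the neuropsychological assessments carried per subject:
#' MMSE, CDR sum-of-boxes, ADAS-Cog 11/13, FAQ, and the four ADNI composite
#' scores (memory, executive function, language, visuospatial).
#'
#' @return Character vector of length 9.
#' @export
score_names <- function() {
  c("MMSE", "CDR_SB", "ADAS11", "ADAS13", "FAQ",
    "ADNI_MEM", "ADNI_EF", "ADNI_LAN", "ADNI_VS")
}

#' Reference edge thresholds per neuropsychological score
#'
#' The published optimal unit-step thresholds (beta) of each
#' neuropsychological score for the AD-vs-MCI and MCI-vs-CN tasks, found by
#' grid search with validation on ADNI-1. Shipped as the package default
#' when no threshold search is requested.
#'
#' @return Tibble: `task` (`ad_mci` or `mci_cn`), `score`, `beta`.
#' @export
adni1_default_thresholds <- function() {
  scores <- score_names()
  bind_rows(
    tibble(task = "ad_mci", score = scores,
           beta = c(1, 2, 3, 3, 5, 0.3, 0.3, 0.7, 0.5)),
    tibble(task = "mci_cn", score = scores,
           beta = c(2, 1.5, 5, 3, 1, 1, 1, 0.3, 0.3))
  )
}

#' Reference ADNI-1 classification results
#'
#' The published test-set metrics (percent) of the graph convolutional
#' network on the real ADNI-1 cohort for each edge-assigning function, as
#' reported for the three ablation experiments. These values are carried
#' for internal-consistency checks (e.g. that F1 is the harmonic mean of
#' the printed precision and recall) and for side-by-side display against
#' synthetic-cohort runs; the package does not treat them as reproduction
#' targets, since the underlying cohort is access-controlled.
#'
#' @param experiment 1 (AD vs CN, demographic edges), 2 (MCI tasks,
#'   neuropsychological edges) or 3 (three-class).
#' @return Tibble. Experiments 1-2: `task`, `edge`, `feature`, `acc`,
#'   `pre`, `rec`, `f1`, `mcc`. Experiment 3: `edge`, `feature`, `acc`,
#'   `mci_recall`.
#' @export
adni1_reference_results <- function(experiment = 1) {
  if (experiment == 1) {
    tibble(
      task = "ad_cn",
      edge = c("Simg", rep("Scom", 7)),
      feature = c("", "age", "gender", "ApoE", "age+gender", "age+ApoE",
                  "gender+ApoE", "age+gender+ApoE"),
      acc = c(86.8, 85.5, 86.8, 88.0, 86.8, 90.4, 89.2, 91.6),
      pre = c(84.2, 83.8, 84.2, 82.9, 84.2, 89.2, 88.9, 91.7),
      rec = c(86.5, 83.8, 86.5, 91.9, 86.5, 89.2, 86.5, 89.2),
      f1  = c(85.3, 83.8, 85.3, 87.2, 85.3, 89.2, 87.7, 90.4),
      mcc = c(71.3, 68.2, 71.3, 74.8, 71.3, 78.7, 75.8, 81.1)
    )
  } else if (experiment == 2) {
    scores <- score_names()
    bind_rows(
      tibble(task = "ad_mci", edge = "Simg", feature = "",
             acc = 66.7, pre = 49.0, rec = 54.0, f1 = 51.4, mcc = 26.2),
      tibble(task = "ad_mci", edge = "Snimg", feature = scores,
             acc = c(83.3, 91.2, 79.0, 80.7, 83.3, 78.9, 74.6, 70.2, 67.5),
             pre = c(100, 90.9, 78.3, 82.6, 75.0, 78.3, 70.0, 60.0, 50.0),
             rec = c(48.7, 81.1, 48.7, 51.4, 73.0, 48.7, 37.8, 24.3, 5.0),
             f1  = c(65.5, 85.7, 60.0, 63.3, 74.0, 60.0, 49.1, 34.6, 9.8),
             mcc = c(62.3, 79.6, 49.3, 53.8, 61.7, 49.1, 37.1, 23.0, 6.0)),
      tibble(task = "ad_mci", edge = "Scom", feature = scores,
             acc = c(85.1, 87.7, 79.8, 80.7, 85.1, 79.8, 74.6, 74.6, 73.7),
             pre = c(95.5, 89.7, 75.0, 72.7, 79.4, 71.9, 72.2, 64.3, 63.0),
             rec = c(56.8, 70.0, 56.8, 64.9, 73.0, 62.2, 35.1, 48.7, 46.0),
             f1  = c(71.2, 79.1, 64.6, 68.6, 76.1, 66.7, 47.3, 55.4, 53.1),
             mcc = c(65.8, 71.3, 51.8, 54.9, 65.4, 52.5, 36.9, 38.9, 36.3)),
      tibble(task = "mci_cn", edge = "Simg", feature = "",
             acc = 68.3, pre = 74.4, rec = 75.3, f1 = 74.8, mcc = 37.7),
      tibble(task = "mci_cn", edge = "Snimg", feature = scores,
             acc = c(74.8, 96.8, 77.2, 85.4, 82.9, 75.0, 67.5, 69.9, 62.6),
             pre = c(73.0, 95.1, 80.3, 89.3, 98.3, 74.0, 66.7, 73.8, 62.6),
             rec = c(94.8, 100, 84.4, 87.0, 74.0, 94.0, 96.1, 80.5, 100),
             f1  = c(82.5, 97.5, 82.3, 88.1, 84.4, 82.8, 78.7, 77.0, 77.0),
             mcc = c(56.4, 93.1, 54.7, 68.9, 61.1, 56.2, 48.2, 42.4, 45.5)),
      tibble(task = "mci_cn", edge = "Scom", feature = scores,
             acc = c(78.1, 96.8, 78.9, 83.7, 82.1, 86.2, 67.5, 69.9, 62.6),
             pre = c(82.9, 97.0, 82.3, 84.8, 98.3, 88.5, 66.7, 73.8, 62.6),
             rec = c(81.8, 84.4, 84.4, 87.0, 72.7, 89.6, 96.1, 80.5, 100),
             f1  = c(82.3, 90.3, 83.3, 85.9, 83.6, 89.0, 78.7, 77.0, 77.0),
             mcc = c(55.0, 93.6, 57.3, 66.0, 59.2, 71.0, 48.2, 42.4, 45.5))
    )
  } else if (experiment == 3) {
    tibble(edge = c("Simg", "Snimg", "Scom"),
           feature = c("", "CDR_SB", "CDR_SB"),
           acc = c(59.4, 89.4, 81.3),
           mci_recall = c(44.2, 85.7, 77.9))
  } else {
    abort("`experiment` must be 1, 2 or 3.")
  }
}
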