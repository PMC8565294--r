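#' Preset cohort configurations
#'
#' Three study conditions used throughout validation:
#' \itemize{
#' \item `null_cohort_config()` — no lesion effect
#'   (`lesion_strength = 0`): patients and controls are draws from the
#'   same distribution, the type-I-error condition;
#' \item `strong_lesion_config()` — every patient at full severity
#'   (`subject_severity_spread = 0`), so lesioned-module within-module
#'   correlation sits at `rho_within - lesion_strength *
#'   (rho_within - rho_between)` (0.6 down to 0.25 under the defaults),
#'   the power condition;
#' \item `coupled_cohort_config()` — the default configuration: graded
#'   severity plus clinical coupling, the brain-behavior recovery
#'   condition.
#' }
#'
#' @param seed RNG seed.
#' @param ... further arguments passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
null_cohort_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, lesion_strength = 0, ...)
}

#' @rdname null_cohort_config
#' @export
strong_lesion_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, subject_severity_spread = 0, ...)
}

#' @rdname null_cohort_config
#' @export
coupled_cohort_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

# Eloc AUC for every subject of a cohort (the cheap path used by the
# simulation studies: no nulls, no nodal metrics).
eloc_auc_by_subject <- function(cohort, grid = threshold_grid()) {
  vapply(names(cohort$series), function(id) {
    fc <- compute_fc_matrix(list(subject_id = id,
                                 data = cohort$series[[id]]))
    p <- profile_subject(fc, grid, global_metrics = "Eloc",
                         nodal_metrics = character(0))
    p$auc$global[["Eloc"]]
  }, numeric(1))
}

#' Type-I error of the global Eloc AUC group test
#'
#' Simulates `n_cohorts` cohorts with no true group difference
#' (`lesion_strength = 0`), runs the Welch t on the patients-vs-controls
#' local-efficiency AUC in each, and reports the rejection rate at
#' `alpha`. Under correct calibration the rate is close to `alpha`.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param seed base RNG seed; cohort k uses `seed + k`.
#' @param alpha nominal level.
#' @param grid threshold grid.
#' @param ... configuration overrides passed to [null_cohort_config()].
#' @return list: `rate`, `n_rejections`, `n_cohorts`, `p_values`.
#' @export
estimate_type1_error <- function(n_cohorts = 500, seed = 1L, alpha = 0.05,
                                 grid = threshold_grid(), ...) {
  p_values <- vapply(seq_len(n_cohorts), function(k) {
    cohort <- generate_cohort(null_cohort_config(seed = seed + k, ...))
    auc <- eloc_auc_by_subject(cohort, grid)
    is_pat <- cohort$clinical$group == "patient"
    two_sample_t(auc[is_pat], auc[!is_pat])$p_value
  }, numeric(1))
  list(rate = mean(p_values < alpha),
       n_rejections = sum(p_values < alpha),
       n_cohorts = n_cohorts, p_values = p_values)
}

#' Power of the global Eloc AUC group test under the strong lesion
#'
#' Simulates cohorts in which every patient carries the full lesion
#' effect and reports how often the Welch t on the Eloc AUC rejects at
#' `alpha`.
#'
#' @inheritParams estimate_type1_error
#' @param ... configuration overrides passed to [strong_lesion_config()].
#' @return list: `rate`, `n_rejections`, `n_cohorts`, `p_values`, `t_values`.
#' @export
estimate_power <- function(n_cohorts = 20, seed = 1L, alpha = 0.05,
                           grid = threshold_grid(), ...) {
  res <- lapply(seq_len(n_cohorts), function(k) {
    cohort <- generate_cohort(strong_lesion_config(seed = seed + k, ...))
    auc <- eloc_auc_by_subject(cohort, grid)
    is_pat <- cohort$clinical$group == "patient"
    two_sample_t(auc[is_pat], auc[!is_pat])
  })
  p_values <- vapply(res, function(r) r$p_value, numeric(1))
  t_values <- vapply(res, function(r) r$statistic, numeric(1))
  list(rate = mean(p_values < alpha), n_rejections = sum(p_values < alpha),
       n_cohorts = n_cohorts, p_values = p_values, t_values = t_values)
}

#' Brain-behavior recovery rate
#'
#' Simulates cohorts with graded severity coupled to the clinical
#' scores and reports how often the within-patient Pearson correlation
#' between the Eloc AUC and the composite language score is positive and
#' significant at `alpha`.
#'
#' @inheritParams estimate_type1_error
#' @param score clinical column to correlate (default the composite
#'   language ability).
#' @param ... configuration overrides passed to [coupled_cohort_config()].
#' @return list: `rate`, `n_cohorts`, `r_values`, `p_values`.
#' @export
estimate_behavior_detection <- function(n_cohorts = 20, seed = 1L,
                                        alpha = 0.05,
                                        grid = threshold_grid(),
                                        score = "language_ability", ...) {
  res <- lapply(seq_len(n_cohorts), function(k) {
    cohort <- generate_cohort(coupled_cohort_config(seed = seed + k, ...))
    auc <- eloc_auc_by_subject(cohort, grid)
    is_pat <- cohort$clinical$group == "patient"
    pearson_correlation(auc[is_pat], cohort$clinical[[score]][is_pat])
  })
  r_values <- vapply(res, function(r) r$statistic, numeric(1))
  p_values <- vapply(res, function(r) r$p_value, numeric(1))
  list(rate = mean(r_values > 0 & p_values < alpha),
       n_cohorts = n_cohorts, r_values = r_values, p_values = p_values)
}

#' Printed clinical summary table of the reference study cohort
#'
#' Loads the published mean/sd/n clinical summaries (patients with
#' post-stroke aphasia vs healthy controls) shipped with the package, for
#' re-testing group differences from summary triples.
#'
#' @return data.frame: characteristic, patient and control mean/sd, and
#'   group sizes.
#' @export
clinical_summary_table <- function() {
  utils::read.csv(system.file("extdata", "clinical_summary.csv",
                              package = "fcnet"),
                  stringsAsFactors = FALSE)
}
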