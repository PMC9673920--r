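#' Analysis configuration
#'
#' Bundles the tunable settings of the glycoform-resolved PK analysis.
#'
#' @param reference_glycoform Glycoform against which clearances are
#'   normalized and tested (default `"G0F"`, the agalactosylated fucosylated
#'   diantennary glycan that dominates CHO material).
#' @param analysis_window_h Upper bound of the analysis window in hours
#'   (default 240 h = 10 days); later samples are excluded to avoid
#'   interference from anti-drug antibodies appearing after about a week.
#' @param background_fraction Fraction of the reported LC-MS background
#'   subtracted from analyte signals in addition to the automatic subtraction
#'   (default 0.3); corrects specific interferences that inflate low-abundant
#'   glycoforms at low concentrations.
#' @param fdr False discovery rate for Benjamini-Hochberg adjustment
#'   (default 0.05).
#' @param lloq_ng_ml ELISA lower limit of quantitation in ng/mL (default 7).
#' @param profile_loq_ug_ml Lowest total concentration (\eqn{\mu}g/mL) at
#'   which glycosylation profiles are considered reliable (default 1).
#' @param trapezoid_rule AUC rule: `"linear"` (default; preserves exact
#'   additivity of glycoform AUCs) or `"lin-up-log-down"`.
#' @param lambda_z_min_points Minimum number of terminal points for the
#'   log-linear terminal-slope fit (default 3).
#' @param serum_comparison_time_h Sampling time (h) at which serum profiles
#'   are compared between routes (default 24, the SC Tmax).
#' @return A list of class `glyco_config`.
#' @export
analysis_config <- function(reference_glycoform = "G0F",
                            analysis_window_h = 240,
                            background_fraction = 0.3,
                            fdr = 0.05,
                            lloq_ng_ml = 7,
                            profile_loq_ug_ml = 1.0,
                            trapezoid_rule = c("linear", "lin-up-log-down"),
                            lambda_z_min_points = 3,
                            serum_comparison_time_h = 24) {
  trapezoid_rule <- match.arg(trapezoid_rule)
  stopifnot(analysis_window_h > 0,
            background_fraction >= 0, background_fraction < 1,
            fdr > 0, fdr < 1,
            lloq_ng_ml >= 0, profile_loq_ug_ml >= 0,
            lambda_z_min_points >= 3)
  structure(list(reference_glycoform = reference_glycoform,
                 analysis_window_h = analysis_window_h,
                 background_fraction = background_fraction,
                 fdr = fdr,
                 lloq_ng_ml = lloq_ng_ml,
                 profile_loq_ug_ml = profile_loq_ug_ml,
                 trapezoid_rule = trapezoid_rule,
                 lambda_z_min_points = lambda_z_min_points,
                 serum_comparison_time_h = serum_comparison_time_h),
            class = "glyco_config")
}
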