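# Cardiopulmonary exercise test metrics, default imputation for incomplete
# tests, exercise-capacity stratification and composite risk grading.

# Default values recorded for patients unable to complete a full test.
CPET_DEFAULTS <- list(peak_vo2 = 14, pct_predicted = 46, vevco2_slope = 45)

#' Average raw breath-by-breath samples onto a 10-second grid
#'
#' Consecutive samples are averaged in fixed bins of `bin_s` seconds anchored
#' at the first sample time; the bin time is the bin midpoint and the bin
#' phase the most frequent phase among its breaths.
#'
#' @param series A [cpet_series()] of raw breath samples.
#' @param bin_s Bin width in seconds (default 10).
#' @return A binned [cpet_series()].
#' @export
bin_breaths <- function(series, bin_s = 10) {
  bin <- floor((series$time - series$time[1]) / bin_s)
  agg <- function(x) as.numeric(tapply(x, bin, mean))
  mode_phase <- as.character(tapply(series$phase, bin, function(p)
    names(which.max(table(factor(p, levels = CPET_PHASES))))))
  cpet_series(time = series$time[1] + bin_s * (sort(unique(bin)) + 0.5),
              ve = agg(series$ve), vo2 = agg(series$vo2),
              vco2 = agg(series$vco2), phase = mode_phase)
}

#' Peak oxygen uptake
#'
#' Highest 10-second-averaged VO2 sample obtained during the exercise phase.
#'
#' @param series A [cpet_series()] already on the 10-s grid (use
#'   [bin_breaths()] first for raw breath data).
#' @return Peak VO2 in ml/kg/min.
#' @export
peak_vo2 <- function(series) {
  ex <- series$phase == "exercise"
  if (!any(ex)) stop("no exercise-phase samples")
  max(series$vo2[ex])
}

#' Ventilatory efficiency slope (VE/VCO2 slope)
#'
#' Ordinary-least-squares slope of VE on VCO2 using samples from the start
#' of exercise to the sample achieving peak VO2 (first occurrence on ties).
#'
#' @param series A [cpet_series()] on the 10-s grid.
#' @return Dimensionless slope.
#' @export
ve_vco2_slope <- function(series) {
  ex <- which(series$phase == "exercise")
  if (length(ex) == 0) stop("no exercise-phase samples")
  peak_at <- ex[which.max(series$vo2[ex])]
  idx <- ex[ex <= peak_at]
  if (length(idx) < 3L) stop("need >= 3 samples from exercise start to peak")
  x <- series$vco2[idx]; y <- series$ve[idx]
  if (stats::var(x) == 0) stop("zero variance in VCO2 over the interval")
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Peak VO2 as a percentage of the predicted value
#'
#' @param peak Measured peak VO2, ml/kg/min.
#' @param predicted Normative predicted peak VO2, ml/kg/min (> 0); predicted
#'   values come from external normative equations and are consumed as
#'   inputs.
#' @return Percentage `100 * peak / predicted`.
#' @export
percent_predicted <- function(peak, predicted) {
  if (any(predicted <= 0)) stop("predicted must be > 0")
  100 * peak / predicted
}

#' CPET summary with default imputation for incomplete tests
#'
#' Complete records pass through unchanged; records flagged incomplete
#' receive the default values peak VO2 = 14 ml/kg/min, % predicted = 46%,
#' VE/VCO2 slope = 45.
#'
#' @param peak_vo2,pct_predicted,vevco2_slope Measured values (ignored when
#'   `incomplete`).
#' @param incomplete Logical: subject could not complete the full test.
#' @return An object of class `cpet_summary` with an `imputed` flag and the
#'   stratification of [stratify_cpet()] attached.
#' @export
cpet_summary <- function(peak_vo2 = NA_real_, pct_predicted = NA_real_,
                         vevco2_slope = NA_real_, incomplete = FALSE) {
  if (incomplete) {
    peak_vo2 <- CPET_DEFAULTS$peak_vo2
    pct_predicted <- CPET_DEFAULTS$pct_predicted
    vevco2_slope <- CPET_DEFAULTS$vevco2_slope
  }
  out <- list(peak_vo2 = peak_vo2, pct_predicted = pct_predicted,
              vevco2_slope = vevco2_slope, imputed = incomplete)
  out$strata <- stratify_cpet(out)
  class(out) <- "cpet_summary"
  out
}

#' Exercise-capacity stratification
#'
#' Peak VO2 class: `"abnormal"` iff peak VO2 <= 15 ml/kg/min, else
#' `"preserved"`. Exercise risk flag (intermediate/high-risk exercise
#' capacity): TRUE iff % predicted peak VO2 <= 65 and/or VE/VCO2 slope >= 36
#' (boundary values inclusive).
#'
#' @param summary A `cpet_summary` or list with `peak_vo2`, `pct_predicted`,
#'   `vevco2_slope`.
#' @return List with `peak_vo2_class` and `exercise_risk_flag`.
#' @export
stratify_cpet <- function(summary) {
  list(peak_vo2_class = if (summary$peak_vo2 <= 15) "abnormal" else "preserved",
       exercise_risk_flag = isTRUE(summary$pct_predicted <= 65) ||
                            isTRUE(summary$vevco2_slope >= 36))
}

#' Composite risk grade
#'
#' Overall risk is the mean of the available per-variable grades (each 1 =
#' low, 2 = intermediate, 3 = high) rounded to the nearest integer;
#' half-point means round toward the higher-risk grade by default (the
#' conservative clinical choice).
#'
#' @param grades Vector of grades in `{1, 2, 3}`; `NA` entries (ungraded
#'   variables) are dropped and the count of contributing grades reported.
#' @param half_up Round half-point means up (default TRUE); set FALSE for
#'   round-half-even.
#' @return List with `overall` grade, `mean_grade` and `n_grades`.
#' @export
overall_risk <- function(grades, half_up = TRUE) {
  grades <- grades[!is.na(grades)]
  if (length(grades) == 0) stop("need >= 1 grade")
  if (!all(grades %in% 1:3)) stop("grades must be in {1, 2, 3}")
  m <- mean(grades)
  overall <- if (half_up) floor(m + 0.5) else round(m)
  list(overall = as.integer(overall), mean_grade = m,
       n_grades = length(grades))
}
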