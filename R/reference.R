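# The reference melanoma patient: best-fit specific parameters under the
# package's calibrated general defaults.

#' Reference-patient setup
#'
#' Bundles everything needed to re-simulate the reference pembrolizumab
#' course: the best-fit specific parameters, the calibrated general
#' defaults, a 50 cm^3 baseline load and the uniform 1e8-cell initial
#' T-cell pool.
#'
#' @return list with `sp`, `gp`, `tumor0_cm3`, `total_T`, `dc0`.
#' @export
reference_patient <- function() {
  list(sp = specific_parameters(), gp = general_parameters(),
       tumor0_cm3 = 50, total_T = 1e8, dc0 = 0)
}

#' Simulate the reference patient
#'
#' @param weeks horizon (weeks); default covers the 162-week course.
#' @param schedule dosing schedule; default 120 mg q3w, `NULL` for the
#'   default, [no_treatment()] for the untreated counterpart.
#' @param drug_off simulate without drug effect.
#' @param ... passed to [simulate()].
#' @return an `icisim_trajectory`.
#' @export
simulate_reference <- function(weeks = 162, schedule = NULL,
                               drug_off = FALSE, ...) {
  ref <- reference_patient()
  t_span <- weeks * 168
  if (is.null(schedule))
    schedule <- if (drug_off) no_treatment() else q3w_schedule(t_span)
  init <- initial_state(ref$total_T, ref$tumor0_cm3 * ref$gp$cells_per_cm3,
                        ref$dc0, m = ref$gp$m)
  simulate(ref$sp, ref$gp, schedule, t_span, init = init,
           drug_off = drug_off, ...)
}

#' Local maxima of a tumor-load course
#'
#' Finds the local maxima of a simulated tumor-load series, ignoring
#' ripples below `min_frac` of the baseline load.
#'
#' @param traj an `icisim_trajectory`.
#' @param min_frac discard maxima below this fraction of baseline.
#' @return data.frame with columns `week`, `load_cm3`, `ratio` (to
#'   baseline).
#' @export
find_load_peaks <- function(traj, min_frac = 0.05) {
  tl <- tumor_load(traj)
  x <- tl$load_cm3
  dx <- diff(x)
  idx <- which(dx[-1] < 0 & dx[-length(dx)] > 0) + 1L
  idx <- idx[x[idx] > min_frac * x[1]]
  data.frame(week = tl$week[idx], load_cm3 = x[idx],
             ratio = x[idx] / x[1])
}
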