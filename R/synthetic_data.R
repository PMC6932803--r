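# Synthetic clinical data: forward-simulated tumor-load series with a CT
# measurement-error model.  Stands in for the (unavailable) clinical lesion
# table of the reference patient and feeds the calibration recovery tests.
#
# Error model: each lesion is represented as an equivalent ellipsoid; every
# axis measurement carries an independent uniform error bounded by
# axis_err_mm (3 mm for a standard CT read).  The reported err_cm3 is the
# first-order worst-case volume error.

#' CT measurement-noise model
#'
#' @param axis_err_mm maximal measurement error per image axis (mm).
#' @param n_axes number of measured axes per lesion (3 for volumetric CT).
#' @param lesion_diameters optional vector of relative lesion sizes; the
#'   total load is split across lesions proportionally to `d^3`.  Default:
#'   a single lesion.
#' @param seed RNG seed for reproducible noise draws.
#' @return an object of class `icisim_noise`.
#' @export
noise_model <- function(axis_err_mm = 3, n_axes = 3, lesion_diameters = NULL,
                        seed = NULL) {
  if (axis_err_mm < 0) stop("'axis_err_mm' must be >= 0")
  structure(list(axis_err_mm = axis_err_mm, n_axes = as.integer(n_axes),
                 lesion_diameters = lesion_diameters, seed = seed),
            class = "icisim_noise")
}

# Split a total volume over lesions; returns per-lesion volumes (cm^3).
split_lesions <- function(total_cm3, noise, n_lesions = 1L) {
  if (!is.null(noise$lesion_diameters)) {
    w <- noise$lesion_diameters^3
    total_cm3 * w / sum(w)
  } else {
    rep(total_cm3 / n_lesions, n_lesions)
  }
}

# Perturb one total-load sample through the per-lesion ellipsoid model.
# Returns c(measured volume, first-order error bound), both cm^3.
perturb_sample <- function(total_cm3, noise, n_lesions = 1L) {
  if (total_cm3 <= 0 || noise$axis_err_mm == 0) {
    per <- split_lesions(total_cm3, noise, n_lesions)
    d <- (6 * per / pi)^(1 / 3)
    return(c(total_cm3, sum(pi / 6 * 3 * d^2 * noise$axis_err_mm / 10)))
  }
  delta <- noise$axis_err_mm / 10  # mm -> cm
  per <- split_lesions(total_cm3, noise, n_lesions)
  d <- (6 * per / pi)^(1 / 3)      # equivalent sphere diameter per lesion
  vol <- 0
  for (k in seq_along(d)) {
    ax <- pmax(d[k] + runif(noise$n_axes, -delta, delta), 0)
    # pad to three semi-axes if fewer are measured
    ax <- c(ax, rep(d[k], 3 - length(ax)))
    vol <- vol + pi / 6 * prod(ax[1:3])
  }
  err <- sum(pi / 6 * 3 * d^2 * delta)
  c(vol, err)
}

#' Generate a synthetic tumor-load series
#'
#' Simulates the model forward, samples the tumor load at the requested
#' weeks, and perturbs each sample through the per-lesion CT error model
#' (independent uniform error in each axis, bounded by `axis_err_mm`).
#'
#' @param sp,gp parameter sets.
#' @param schedule dosing schedule.
#' @param sample_weeks measurement times (weeks).
#' @param noise a [noise_model()].
#' @param tumor0_cm3 baseline tumor load (cm^3).
#' @param total_T initial T-cell pool spread uniformly over the grid.
#' @param n_lesions number of (equal) lesions the load is split across when
#'   `noise$lesion_diameters` is not given.
#' @param anchor_baseline if `TRUE`, report the first sample (the known
#'   baseline) without measurement noise.
#' @return an `icisim_series` with `err_cm3`.
#' @export
generate_series <- function(sp, gp, schedule = NULL, sample_weeks,
                            noise = noise_model(), tumor0_cm3 = 50,
                            total_T = 1e8, n_lesions = 1L,
                            anchor_baseline = FALSE) {
  stopifnot(length(sample_weeks) > 0)
  t_span <- max(sample_weeks) * 168
  if (is.null(schedule)) schedule <- q3w_schedule(t_span + 1)
  init <- initial_state(total_T, tumor0_cm3 * gp$cells_per_cm3, 0, m = gp$m)
  traj <- simulate(sp, gp, schedule, t_span, init = init)
  tl <- tumor_load(traj)
  truth <- vapply(sample_weeks, function(w)
    tl$load_cm3[which.min(abs(tl$week - w))], numeric(1))

  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(noise$seed)
  }
  meas <- t(vapply(truth, perturb_sample, numeric(2), noise = noise,
                   n_lesions = n_lesions))
  load <- meas[, 1]
  if (anchor_baseline) load[1] <- truth[1]
  tumor_load_series(sample_weeks, load, meas[, 2])
}

#' Synthetic stand-in for the reference patient's clinical series
#'
#' A deterministic tumor-load series generated from the package's best-fit
#' specific parameters and calibrated general defaults under 120 mg q3w
#' dosing, sampled on the package's clinical assessment schedule (every
#' 3 weeks during the first 12 weeks, every 6 weeks thereafter, out to
#' week 162) and perturbed with the 3 mm CT error model (noise seed 0).  The same series is shipped as a
#' plain-text fixture at `inst/extdata/patient_o_like_synthetic.csv`;
#' regeneration is bit-stable given the pinned seed.
#'
#' @param regenerate if `TRUE`, recompute the series from the model instead
#'   of reading the shipped fixture.
#' @return an `icisim_series`.
#' @export
patient_o_fixture <- function(regenerate = FALSE) {
  if (!regenerate) {
    path <- system.file("extdata", "patient_o_like_synthetic.csv",
                        package = "icisim")
    if (nzchar(path)) return(load_series(path))
  }
  generate_series(specific_parameters(), general_parameters(),
                  sample_weeks = c(seq(0, 9, by = 3), seq(12, 162, by = 6)),
                  noise = noise_model(axis_err_mm = 3, seed = 0),
                  tumor0_cm3 = 50, total_T = 1e8, n_lesions = 3L,
                  anchor_baseline = TRUE)
}
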