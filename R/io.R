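# Result export, parameter scans and run manifests.

#' Export a trajectory to CSV
#'
#' Writes the header `week,tumor_load_cm3,reinvigoration_pct,drug_mg_per_L`.
#'
#' @param traj an `icisim_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save an arbitrary result object as JSON
#' @param obj a list/data.frame of results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_results <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Geometric parameter scan
#'
#' Re-simulates the treated model over a geometric grid of one parameter:
#' `2 * n_steps + 1` values `base * step^k`, `k = -n_steps..n_steps`
#' (`step = 1.05`, `n_steps = 10` spans a `1.05^10 ~ 1.63`-fold range each
#' way, the sensitivity protocol around the reference patient).
#'
#' @param sp,gp parameter sets; `param_name` is looked up first among the
#'   specific parameters, then among scalar general parameters.
#' @param param_name parameter to scan.
#' @param n_steps grid half-width (0 gives the single baseline run).
#' @param step geometric step (> 1).
#' @param months simulated horizon (calendar months of 730.5 h).
#' @param schedule dosing schedule; default 120 mg q3w.
#' @param tumor0_cm3,total_T initial conditions.
#' @return data.frame of class `icisim_scan` with columns `fold`, `value`,
#'   `week`, `load_cm3`; failed grid points are dropped with a warning.
#' @export
scan_parameter <- function(sp, gp, param_name, n_steps = 10, step = 1.05,
                           months = 28, schedule = NULL,
                           tumor0_cm3 = 50, total_T = 1e8) {
  if (step <= 1) stop("'step' must be > 1")
  in_sp <- param_name %in% names(sp)
  gp_scalars <- setdiff(names(gp), c("m", "p_div", "mu"))
  if (!in_sp && !param_name %in% gp_scalars)
    stop("unknown scalar parameter: ", param_name)
  base_val <- if (in_sp) sp[[param_name]] else gp[[param_name]]
  t_span <- round(months * 730.5)
  if (is.null(schedule)) schedule <- q3w_schedule(t_span)
  init <- initial_state(total_T, tumor0_cm3 * gp$cells_per_cm3, 0, m = gp$m)
  folds <- step^seq(-n_steps, n_steps)
  out <- lapply(folds, function(f) {
    spi <- sp; gpi <- gp
    if (in_sp) spi[[param_name]] <- base_val * f
    else gpi[[param_name]] <- base_val * f
    tr <- tryCatch(simulate(spi, gpi, schedule, t_span, init = init),
                   error = function(e) {
                     warning("scan point fold=", signif(f, 4), " failed: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(tr)) return(NULL)
    tl <- tumor_load(tr, gpi)
    data.frame(fold = f, value = base_val * f, week = tl$week,
               load_cm3 = tl$load_cm3)
  })
  res <- do.call(rbind, Filter(Negate(is.null), out))
  attr(res, "param") <- param_name
  attr(res, "folds") <- folds
  class(res) <- c("icisim_scan", "data.frame")
  res
}

#' Write a reproducibility manifest next to an output file
#'
#' Records the package version, command, seed and parameters that produced
#' an output, sufficient to reproduce it.
#'
#' @param path manifest path (JSON).
#' @param command the command/subcommand that ran.
#' @param seed the seed used.
#' @param params any parameter list worth recording.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, params = list()) {
  save_results(list(
    package = "icisim",
    version = as.character(utils::packageVersion("icisim")),
    command = command, seed = seed, params = params,
    r_version = R.version.string), path)
}
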