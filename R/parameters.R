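# Parameter containers for the tumor--immune--drug model.
#
# Two tiers mirror how the model is calibrated: "specific" parameters are
# patient-level unknowns estimated from an individual tumor-load series;
# "general" parameters are physiology-scale constants shared across patients
# and only fine-tuned within narrow ranges.

COMPARTMENTS <- c("SCM", "CM", "EM", "EFF", "EXH")

#' Patient-specific model parameters
#'
#' The nine parameters treated as patient-specific: tumor growth and
#' immunogenicity, effector cytotoxicity, PD-1-mediated apoptosis
#' coefficients, and the self-renewal probabilities of the four dividing
#' CD8+ T-cell compartments.  Defaults are the best-fit values of the
#' reference melanoma patient.
#'
#' @param p_C tumor intrinsic growth coefficient (cells^(1/3)/h); the tumor
#'   grows as `dC/dt = p_C * C^(2/3)` before immune kill.
#' @param kE0 baseline cytotoxicity of effector cells (per effector cell,
#'   /h, saturating in tumor size).
#' @param rho_D tumor immunogenicity: maximal dendritic-cell activation
#'   rate (cells/h).
#' @param kC03,kC04 PD-1/PD-L1-driven apoptosis coefficients acting on
#'   effector-memory and effector cells respectively (/h).
#' @param a_SCM,a_CM,a_EM,a_EFF self-renewal probabilities: the chance that
#'   a daughter cell stays in its mother's differentiation compartment
#'   rather than advancing to the next one (dimensionless, in [0, 1]).
#' @return an object of class `icisim_specific` (a named list).
#' @export
#' @examples
#' sp <- specific_parameters()
#' sp$kE0
specific_parameters <- function(p_C = 1.828, kE0 = 0.00603, rho_D = 0.95,
                                kC03 = 0.0058, kC04 = 0.00535,
                                a_SCM = 0.05, a_CM = 0.9,
                                a_EM = 0.03, a_EFF = 0.92) {
  sp <- list(p_C = p_C, kE0 = kE0, rho_D = rho_D, kC03 = kC03, kC04 = kC04,
             a_SCM = a_SCM, a_CM = a_CM, a_EM = a_EM, a_EFF = a_EFF)
  for (nm in names(sp)) {
    v <- sp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("specific parameter '", nm, "' must be a single non-negative number")
  }
  for (nm in c("a_SCM", "a_CM", "a_EM", "a_EFF"))
    if (sp[[nm]] > 1)
      stop("self-renewal probability '", nm, "' must lie in [0, 1]")
  structure(sp, class = "icisim_specific")
}

#' General (shared) model parameters
#'
#' Physiology-scale constants of the immune arm, the dendritic-cell relay,
#' PD-1 ligation, drug pharmacokinetics and unit conversions.  Defaults were
#' calibrated once, together, so that the patient-specific defaults of
#' [specific_parameters()] reproduce the reference patient's biphasic
#' tumor-load course under 120 mg q3w dosing (see the package vignette).
#'
#' @param m maximal number of divisions in a lineage (replicative
#'   senescence ceiling); division stops at senescence index `j = m`.
#' @param p_div intrinsic division rates (/h) of the four dividing
#'   compartments, named SCM, CM, EM, EFF; must be strictly decreasing
#'   (differentiation trades replication for cytotoxicity).
#' @param mu death rates (/h) of all five compartments incl. EXH;
#'   non-decreasing with differentiation.
#' @param sigma_N naive-cell activation influx ceiling (cells/h) into the
#'   SCM compartment at senescence 0.
#' @param s_max maximal fold-boost of SCM/CM division by mature dendritic
#'   cells (dimensionless).
#' @param K_D mature-DC half-saturation of the naive-priming influx
#'   (cells); priming saturates at low DC numbers.
#' @param K_B mature-DC half-saturation of the SCM/CM division boost
#'   (cells); set well above typical DC counts so the proliferative boost
#'   keeps responding to antigen load after priming has saturated.
#' @param K_Cdc tumor half-saturation for DC activation (cells).
#' @param m_DC,d_act,d_m DC migration/maturation rate and death rates of
#'   activated and mature DCs (/h).
#' @param K_PD tumor half-saturation of PD-1/PD-L1 ligation (cells).
#' @param eps_kill,eps_div maximal fractional impairment of effector
#'   killing and of EM/EFF division by PD-1 signalling (each in [0, 1]).
#' @param phi_EM cytotoxicity of effector-memory cells as a fraction of
#'   `kE0` (in [0, 1]).
#' @param K_kill tumor half-saturation of the killing term (cells).
#' @param t_half drug elimination half-life (h).
#' @param V_d drug distribution volume (L).
#' @param EC50 drug concentration at half-maximal receptor blockade (mg/L).
#' @param tau reinvigoration time constant (h): average overall division
#'   time used to convert division flux into a Ki67+ percentage.
#' @param cells_per_cm3 tumor cell-to-volume conversion (cells/cm^3).
#' @return an object of class `icisim_general` (a named list).
#' @export
general_parameters <- function(m = 25L,
                               p_div = c(SCM = 0.014, CM = 0.011,
                                         EM = 0.009, EFF = 0.0075),
                               mu = c(SCM = 2e-4, CM = 2e-4, EM = 0.005,
                                      EFF = 0.01, EXH = 0.03),
                               sigma_N = 125,
                               s_max = 12,
                               K_D = 5,
                               K_B = 1500,
                               K_Cdc = 1e11,
                               m_DC = 0.05,
                               d_act = 0.01,
                               d_m = 0.01,
                               K_PD = 3e9,
                               eps_kill = 1,
                               eps_div = 1,
                               phi_EM = 0.5,
                               K_kill = 3e10,
                               t_half = 528,
                               V_d = 7.7,
                               EC50 = 1,
                               tau = 24,
                               cells_per_cm3 = 1e9) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1")
  p_div <- unlist(p_div)[c("SCM", "CM", "EM", "EFF")]
  mu <- unlist(mu)[COMPARTMENTS]
  if (anyNA(p_div)) stop("'p_div' must be named SCM, CM, EM, EFF")
  if (anyNA(mu)) stop("'mu' must be named SCM, CM, EM, EFF, EXH")
  gp <- list(m = m, p_div = p_div, mu = mu, sigma_N = sigma_N, s_max = s_max,
             K_D = K_D, K_B = K_B, K_Cdc = K_Cdc, m_DC = m_DC, d_act = d_act, d_m = d_m,
             K_PD = K_PD, eps_kill = eps_kill, eps_div = eps_div,
             phi_EM = phi_EM, K_kill = K_kill, t_half = t_half, V_d = V_d,
             EC50 = EC50, tau = tau, cells_per_cm3 = cells_per_cm3)
  scalars <- setdiff(names(gp), c("m", "p_div", "mu"))
  for (nm in scalars) {
    v <- gp[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("general parameter '", nm, "' must be a single positive number")
  }
  if (any(p_div <= 0) || any(mu <= 0))
    stop("rates in 'p_div' and 'mu' must be positive")
  if (any(diff(p_div) >= 0))
    stop("'p_div' must be strictly decreasing from SCM to EFF")
  for (nm in c("eps_kill", "eps_div", "phi_EM"))
    if (gp[[nm]] > 1) stop("'", nm, "' must lie in [0, 1]")
  structure(gp, class = "icisim_general")
}

#' Intravenous dosing schedule
#'
#' Bolus administrations of the checkpoint inhibitor.  The default is the
#' clinical regimen of the reference patient: 120 mg every 3 weeks.
#'
#' @param dose_times administration times (h), strictly increasing.
#' @param dose_amounts dose per administration (mg); recycled to the length
#'   of `dose_times`.
#' @return an object of class `icisim_schedule`.
#' @seealso [q3w_schedule()] for the standard every-3-weeks regimen.
#' @export
dose_schedule <- function(dose_times, dose_amounts = 120) {
  if (length(dose_times) == 0L)
    return(structure(list(dose_times = numeric(0),
                          dose_amounts = numeric(0)),
                     class = "icisim_schedule"))
  if (any(!is.finite(dose_times)) || any(dose_times < 0))
    stop("dose times must be finite and non-negative")
  if (is.unsorted(dose_times, strictly = TRUE))
    stop("dose times must be strictly increasing")
  dose_amounts <- rep_len(dose_amounts, length(dose_times))
  if (any(dose_amounts < 0)) stop("dose amounts must be >= 0")
  structure(list(dose_times = as.numeric(dose_times),
                 dose_amounts = as.numeric(dose_amounts)),
            class = "icisim_schedule")
}

#' Every-3-weeks dosing out to a horizon
#'
#' @param t_end_h end of the treatment window (h); doses are placed at 0,
#'   504, 1008, ... strictly before `t_end_h`.
#' @param dose_mg dose per administration (mg).
#' @param interval_h dosing interval (h); default 504 h = 3 weeks.
#' @return an `icisim_schedule`.
#' @export
q3w_schedule <- function(t_end_h, dose_mg = 120, interval_h = 504) {
  stopifnot(t_end_h > 0)
  times <- interval_h * seq(0L, ceiling(t_end_h / interval_h))
  dose_schedule(times[times < t_end_h], dose_mg)
}

#' No-treatment schedule
#' @return an empty `icisim_schedule`.
#' @export
no_treatment <- function() dose_schedule(numeric(0))

#' @export
print.icisim_specific <- function(x, ...) {
  cat("Patient-specific parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.icisim_general <- function(x, ...) {
  cat("General model parameters (m =", x$m, "senescence levels):\n")
  cat("  p_div:", paste(sprintf("%s=%g", names(x$p_div), x$p_div),
                        collapse = " "), "\n")
  cat("  mu:   ", paste(sprintf("%s=%g", names(x$mu), x$mu),
                        collapse = " "), "\n")
  sc <- setdiff(names(x), c("m", "p_div", "mu"))
  print(unlist(x[sc]))
  invisible(x)
}

# Read one parameter section from a flat key-value config list, rejecting
# unknown keys.  Used by the YAML/JSON loaders.
apply_overrides <- function(constructor, overrides, what) {
  if (is.null(overrides)) return(constructor())
  known <- names(formals(constructor))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown ", what, " parameter(s): ", paste(bad, collapse = ", "))
  do.call(constructor, overrides)
}

#' Read model parameters from a YAML or JSON file
#'
#' The file holds up to two sections, `specific` and `general`, each a flat
#' key-value map of constructor arguments.  Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list with elements `specific` and `general`.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("specific", "general"))
  if (length(bad))
    stop("unknown parameter section(s): ", paste(bad, collapse = ", "))
  list(specific = apply_overrides(specific_parameters, cfg$specific,
                                  "specific"),
       general = apply_overrides(general_parameters, cfg$general, "general"))
}
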