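# Virtual-patient populations and in-silico trials.
#
# Four populations mirror increasingly structured assumptions about
# inter-patient variation:
#   VP0  baseline tumor load and lesion count only
#   VP1  VP0 + patient-specific kE0 and p_C (independent draws)
#   VP2  VP1 but p_C strictly (rank-)tied to the baseline load
#   VP3  VP2 + independent scalings of the four T-cell division rates
# Every patient is first simulated untreated for the screening window; the
# treated trial continues from that end state (the untreated run doubles as
# the patient's disease history), and the response is classified by
# irRECIST on total tumor load.

#' Specification of a virtual population
#'
#' @param name one of "VP0", "VP1", "VP2", "VP3".
#' @param n_patients number of screened patients to retain.
#' @param seed RNG seed for the sampling stream.
#' @param load_range_cm3 baseline-load sampling range (log-uniform).
#' @param lesion_range integer range of lesion counts (uniform).
#' @param fold_range fold-range for patient-specific kE0 and p_C
#'   (log-uniform around the reference value).
#' @param pdiv_fold_range fold-range for the VP3 division-rate scalings.
#' @return an object of class `icisim_popspec`.
#' @export
population_spec <- function(name = c("VP0", "VP1", "VP2", "VP3"),
                            n_patients = 125, seed = 1,
                            load_range_cm3 = c(1, 300),
                            lesion_range = c(1L, 10L),
                            fold_range = c(0.28, 3.5),
                            pdiv_fold_range = c(0.5, 2)) {
  name <- match.arg(name)
  stopifnot(n_patients >= 0, all(load_range_cm3 > 0), all(fold_range > 0),
            all(pdiv_fold_range > 0))
  structure(list(name = name, n_patients = n_patients, seed = seed,
                 load_range_cm3 = load_range_cm3,
                 lesion_range = as.integer(lesion_range),
                 fold_range = fold_range,
                 pdiv_fold_range = pdiv_fold_range),
            class = "icisim_popspec")
}

# log-uniform draw
rlunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

# VP2/VP3 correlation rule: log p_C mapped linearly from log baseline load
# so that the rank order of p_C equals the rank order of the load exactly.
pc_fold_from_load <- function(load, spec) {
  lr <- log(spec$load_range_cm3); fr <- log(spec$fold_range)
  exp(fr[1] + (log(load) - lr[1]) / (lr[2] - lr[1]) * (fr[2] - fr[1]))
}

# Draw one virtual patient (uses the current RNG stream).
sample_one <- function(spec, base, id) {
  load <- rlunif(1, spec$load_range_cm3[1], spec$load_range_cm3[2])
  n_les <- sample(seq(spec$lesion_range[1], spec$lesion_range[2]), 1)
  sp <- base$sp
  pdiv_scale <- c(SCM = 1, CM = 1, EM = 1, EFF = 1)
  if (spec$name %in% c("VP1", "VP2", "VP3"))
    sp$kE0 <- base$sp$kE0 * rlunif(1, spec$fold_range[1], spec$fold_range[2])
  if (spec$name == "VP1")
    sp$p_C <- base$sp$p_C * rlunif(1, spec$fold_range[1], spec$fold_range[2])
  if (spec$name %in% c("VP2", "VP3"))
    sp$p_C <- base$sp$p_C * pc_fold_from_load(load, spec)
  if (spec$name == "VP3")
    pdiv_scale[] <- rlunif(4, spec$pdiv_fold_range[1],
                           spec$pdiv_fold_range[2])
  structure(list(id = id, sp = sp, pdiv_scale = pdiv_scale,
                 baseline_load_cm3 = load, n_lesions = n_les),
            class = "icisim_patient")
}

# General parameters for one patient (VP3 rescales p_div; the scaled rates
# may lose strict monotonicity, which is deliberate inter-patient noise, so
# the constructor ordering check is bypassed).
patient_gp <- function(patient, gp) {
  if (all(patient$pdiv_scale == 1)) return(gp)
  gp$p_div <- gp$p_div * patient$pdiv_scale[names(gp$p_div)]
  gp
}

#' Sample a virtual patient population
#'
#' Seeded log-uniform draws within each parameter's fold-range; see
#' [population_spec()] for what varies in each population.  No screening
#' is applied here -- see [screen_progressors()].
#'
#' @param spec a [population_spec()].
#' @param base reference parameters: list with elements `sp` and `gp`.
#' @return list of `icisim_patient` objects (length `spec$n_patients`).
#' @export
sample_population <- function(spec, base = list(sp = specific_parameters(),
                                                gp = general_parameters())) {
  set.seed(spec$seed)
  if (spec$n_patients == 0L) return(list())
  lapply(seq_len(spec$n_patients), function(i) sample_one(spec, base, i))
}

#' Screen virtual patients for untreated progression
#'
#' Simulates each patient untreated over the screening window (uniform
#' initial immune state) and keeps those whose tumor load grows to at
#' least `threshold` times baseline.  The untreated end state is attached
#' to each retained patient (`$lead_state`, `$treat_start_load_cm3`) and
#' seeds the treated trial.  If `spec` is supplied, rejected patients are
#' replaced by continuing the sampling stream until the target count is
#' retained.
#'
#' @param patients list of `icisim_patient`.
#' @param gp general parameters.
#' @param spec optional [population_spec()] used to resample replacements.
#' @param base reference parameters (needed when resampling).
#' @param weeks screening horizon (weeks).
#' @param threshold minimal untreated fold-growth counting as progression.
#' @param total_T initial T-cell pool per patient.
#' @return list of retained patients with lead-in state attached.
#' @export
screen_progressors <- function(patients, gp, spec = NULL,
                               base = list(sp = specific_parameters(),
                                           gp = gp),
                               weeks = 12, threshold = 1.2, total_T = 1e8) {
  screen1 <- function(p) {
    gpi <- patient_gp(p, gp)
    init <- initial_state(total_T, p$baseline_load_cm3 * gpi$cells_per_cm3,
                          0, m = gpi$m)
    lead <- tryCatch(
      simulate(p$sp, gpi, no_treatment(), weeks * 168, init = init,
               drug_off = TRUE),
      error = function(e) NULL)
    if (is.null(lead)) return(NULL)
    s_end <- state_at(lead, length(lead$times))
    if (s_end$C < threshold * p$baseline_load_cm3 * gpi$cells_per_cm3)
      return(NULL)
    p$lead_state <- s_end
    p$treat_start_load_cm3 <- s_end$C / gpi$cells_per_cm3
    p
  }
  kept <- Filter(Negate(is.null), lapply(patients, screen1))
  if (is.null(spec)) return(kept)

  target <- spec$n_patients
  tried <- length(patients)
  next_id <- if (length(patients))
    max(vapply(patients, `[[`, 1, "id")) else 0L
  while (length(kept) < target) {
    if (tried > max(200, 100 * target))
      stop("screening retention below 1%; check parameter ranges")
    next_id <- next_id + 1L
    cand <- screen1(sample_one(spec, base, next_id))
    tried <- tried + 1L
    if (!is.null(cand)) kept <- c(kept, list(cand))
  }
  kept[seq_len(target)]
}

#' irRECIST response classification on total tumor load
#'
#' Complete response below an absolute floor of 0.01 cm^3; partial
#' response at >= 30% shrinkage; progressive disease at >= 20% growth;
#' stable disease otherwise.
#'
#' @param baseline_cm3 tumor load at treatment start (> 0).
#' @param week12_cm3 tumor load at the assessment (>= 0).
#' @return factor with levels CR, PR, SD, PD.
#' @export
classify_irrecist <- function(baseline_cm3, week12_cm3) {
  if (any(baseline_cm3 <= 0)) stop("baseline load must be positive")
  if (any(week12_cm3 < 0)) stop("assessment load must be non-negative")
  cls <- ifelse(week12_cm3 < 0.01, "CR",
         ifelse(week12_cm3 <= 0.7 * baseline_cm3, "PR",
         ifelse(week12_cm3 >= 1.2 * baseline_cm3, "PD", "SD")))
  factor(cls, levels = c("CR", "PR", "SD", "PD"))
}

#' Run a treated trial on screened virtual patients
#'
#' Each patient is simulated under the dosing schedule for `weeks` weeks,
#' continuing from the untreated screening end state.  Records the
#' treatment-start (baseline) load, week-12 load, the maximal
#' reinvigoration level over the first `reinvig_weeks` weeks, the irRECIST
#' class and the responder flag (CR or PR).
#'
#' @param patients screened patients (from [screen_progressors()]).
#' @param gp general parameters.
#' @param schedule dosing schedule; default 120 mg q3w.
#' @param weeks trial duration.
#' @param reinvig_weeks window over which the reinvigoration maximum is
#'   taken.
#' @return data.frame of class `icisim_trial`, one row per patient.
#' @export
run_trial <- function(patients, gp, schedule = NULL, weeks = 12,
                      reinvig_weeks = 6) {
  t_span <- weeks * 168
  if (is.null(schedule)) schedule <- q3w_schedule(t_span)
  rows <- lapply(patients, function(p) {
    if (is.null(p$lead_state))
      stop("patient ", p$id, " has no screening state; run screen_progressors first")
    gpi <- patient_gp(p, gp)
    tr <- tryCatch(
      simulate(p$sp, gpi, schedule, t_span, init = p$lead_state),
      error = function(e) NULL)
    if (is.null(tr)) {
      warning("simulation failed for patient ", p$id, "; excluded")
      return(NULL)
    }
    base <- p$treat_start_load_cm3
    w12 <- tail(tumor_load(tr)$load_cm3, 1)
    idx <- which(tr$times <= reinvig_weeks * 168)
    ri <- max(vapply(idx, function(i)
      reinvigoration_percent(state_at(tr, i), p$sp, gpi), numeric(1)))
    data.frame(id = p$id, baseline_cm3 = base, n_lesions = p$n_lesions,
               reinvigoration_pct = ri, week12_cm3 = w12)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out$class <- classify_irrecist(out$baseline_cm3, out$week12_cm3)
  out$responder <- out$class %in% c("CR", "PR")
  class(out) <- c("icisim_trial", "data.frame")
  out
}

#' Best threshold and balanced accuracy of a ratio classifier
#'
#' Scans every midpoint between sorted ratio values (plus one threshold
#' below and above the data) and returns the threshold maximizing the
#' balanced accuracy (mean of sensitivity and specificity).  Both decision
#' directions are considered; ties resolve to the lowest threshold.
#'
#' @param ratios numeric predictor (reinvigoration / baseline load).
#' @param labels logical responder flags.
#' @return list with `threshold`, `accuracy`, `direction` (`">="` when
#'   high ratios predict response, `"<"` otherwise).
#' @export
weighted_accuracy <- function(ratios, labels) {
  stopifnot(length(ratios) == length(labels), length(ratios) >= 2)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("both responder classes must be present")
  o <- order(ratios)
  r <- ratios[o]; y <- labels[o]
  thr <- c(r[1] - 1, (r[-1] + r[-length(r)]) / 2, r[length(r)] + 1)
  n_pos <- sum(y); n_neg <- sum(!y)
  # for threshold thr[k], predictions "ratio >= thr[k]" miss the first
  # k-1 sorted observations; cumulative label counts give sens/spec
  below_pos <- c(0, cumsum(y))[seq_along(thr)]
  below_neg <- c(0, cumsum(!y))[seq_along(thr)]
  sens <- (n_pos - below_pos) / n_pos
  spec <- below_neg / n_neg
  ba <- (sens + spec) / 2
  ba2 <- pmax(ba, 1 - ba)              # both decision directions
  k <- which.max(ba2)                  # which.max takes the lowest tie
  list(threshold = thr[k], accuracy = ba2[k],
       direction = if (ba[k] >= 1 - ba[k]) ">=" else "<")
}

#' Sample, screen and run one virtual-population trial
#'
#' Convenience pipeline: draws the population, screens for untreated
#' progression (resampling to the target count), runs the 12-week treated
#' trial and attaches the reinvigoration-to-baseline ratio.
#'
#' @param spec a [population_spec()].
#' @param base reference parameters (list `sp`, `gp`).
#' @param ... passed to [run_trial()].
#' @return an `icisim_trial` data.frame with a `ratio` column.
#' @export
run_virtual_trial <- function(spec,
                              base = list(sp = specific_parameters(),
                                          gp = general_parameters()),
                              ...) {
  pats <- sample_population(spec, base)
  pats <- screen_progressors(pats, base$gp, spec = spec, base = base)
  res <- run_trial(pats, base$gp, ...)
  res$ratio <- res$reinvigoration_pct / res$baseline_cm3
  res
}

#' Scatter plot of a virtual trial (load vs reinvigoration)
#' @param x an `icisim_trial`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.icisim_trial <- function(x, ...) {
  cols <- c(CR = "forestgreen", PR = "blue", SD = "black", PD = "red")
  pch <- c(CR = 19, PR = 19, SD = 1, PD = 19)
  graphics::plot(x$baseline_cm3, x$reinvigoration_pct, log = "x",
                 col = cols[as.character(x$class)],
                 pch = pch[as.character(x$class)],
                 xlab = "baseline tumor load (cm³)",
                 ylab = "reinvigoration (% Ki67+)", ...)
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = pch, bty = "n")
  invisible(x)
}
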