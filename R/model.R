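# Right-hand side of the tumor--immune--drug ODE system and the stiff
# integrator wrapper.
#
# Dynamics, per state block:
#   tumor      dC/dt = p_C * C^(2/3) - saturating immune kill by EM/EFF
#   DC relay   activation saturating in C, maturation, death
#   T grid     division with senescence increment (both daughters at j+1,
#              self-renew w.p. a_i else advance one compartment), death,
#              PD-1-driven apoptosis of EM/EFF, naive influx into SCM[0]
#   drug       first-order elimination; IV boluses applied as events
# PD-1 pressure on a cell at senescence j is
#   g = (j/m) * C/(C+K_PD) * (1-B),  B = P/(P+EC50),
# i.e. inhibitory-receptor expression grows with the division count, is
# driven by tumor PD-L1 and is annulled by receptor blockade.

#' Fraction of PD-1 receptors blocked by the drug
#'
#' @param P plasma drug concentration (mg/L).
#' @param EC50 concentration at half-maximal blockade (mg/L).
#' @return `P / (P + EC50)`, in [0, 1).
#' @export
blocked_fraction <- function(P, EC50) {
  if (any(EC50 <= 0)) stop("'EC50' must be positive")
  if (any(P < 0)) stop("'P' must be non-negative")
  P / (P + EC50)
}

#' PD-1 signalling pressure on a T cell
#'
#' The dimensionless multiplier applied to every PD-1-mediated effect
#' (apoptosis of EM/EFF cells, impairment of their division and of
#' effector killing) for a cell at senescence index `j`.
#'
#' @param C tumor burden (cells).
#' @param B blocked receptor fraction, in [0, 1].
#' @param j senescence index (0..m); may be fractional (population mean).
#' @param gp [general_parameters()].
#' @return `(j/m) * C/(C+K_PD) * (1-B)`, in [0, 1].
#' @export
pd1_pressure <- function(C, B, j, gp) {
  if (any(C < 0)) stop("'C' must be non-negative")
  if (any(B < 0 | B > 1)) stop("'B' must lie in [0, 1]")
  if (any(j < 0 | j > gp$m)) stop("'j' must lie in [0, m]")
  (j / gp$m) * C / (C + gp$K_PD) * (1 - B)
}

# Effective division-rate grid (5 x (m+1)); EXH row and the j = m column
# are zero.  DCs boost SCM/CM division; PD-1 pressure impairs EM/EFF
# division.  `B` is the blocked receptor fraction.
division_rate_grid <- function(state, sp, gp, B) {
  m <- gp$m
  r <- matrix(0, nrow = 5L, ncol = m + 1L)
  boost <- 1 + gp$s_max * state$D_m / (gp$K_B + state$D_m)
  g <- pd1_pressure(state$C, B, 0:m, gp)
  r[1L, ] <- gp$p_div[["SCM"]] * boost
  r[2L, ] <- gp$p_div[["CM"]] * boost
  r[3L, ] <- gp$p_div[["EM"]] * (1 - gp$eps_div * g)
  r[4L, ] <- gp$p_div[["EFF"]] * (1 - gp$eps_div * g)
  r[, m + 1L] <- 0  # replicative senescence: no division at j = m
  r
}

#' Time derivative of the model state
#'
#' Assembles the full right-hand side.  The two ablation flags support
#' testing: `drug_off` forces the blocked fraction to zero (untreated
#' dynamics regardless of `P`), `killing_off` removes the immune kill term
#' from the tumor equation.
#'
#' @param t time (h); the system is autonomous, `t` is ignored.
#' @param state an `icisim_state`.
#' @param sp [specific_parameters()].
#' @param gp [general_parameters()].
#' @param drug_off,killing_off ablation flags.
#' @return an `icisim_state`-shaped list of derivatives (entries may be
#'   negative).
#' @export
rhs <- function(t, state, sp, gp, drug_off = FALSE, killing_off = FALSE) {
  y <- pack_state(state)
  if (any(!is.finite(y)) || any(y < 0))
    stop("state must be finite and non-negative")
  dy <- rhs_flat(t, y, sp, gp, drug_off, killing_off)
  out <- unpack_state(dy, gp$m)
  class(out) <- NULL
  out
}

# Flat-vector right-hand side used by the integrator (and by rhs() above).
rhs_flat <- function(t, y, sp, gp, drug_off, killing_off) {
  m <- gp$m
  nt <- 5L * (m + 1L)
  T_grid <- matrix(y[seq_len(nt)], nrow = 5L)
  D_act <- y[nt + 1L]; D_m <- y[nt + 2L]
  C <- max(y[nt + 3L], 0); P <- y[nt + 4L]

  B <- if (drug_off) 0 else P / (P + gp$EC50)
  g <- (0:m) / m * (C / (C + gp$K_PD)) * (1 - B)

  # division rates
  boost <- 1 + gp$s_max * D_m / (gp$K_B + D_m)
  imp <- 1 - gp$eps_div * g
  r <- rbind(gp$p_div[["SCM"]] * boost * rep(1, m + 1L),
             gp$p_div[["CM"]] * boost * rep(1, m + 1L),
             gp$p_div[["EM"]] * imp,
             gp$p_div[["EFF"]] * imp,
             0)
  r[, m + 1L] <- 0

  flux <- r * T_grid                       # division outflow per bin
  a <- c(sp$a_SCM, sp$a_CM, sp$a_EM, sp$a_EFF, 0)
  dT <- -flux - gp$mu * T_grid
  # both daughters land at senescence j+1: self-renew in-compartment with
  # probability a_i, otherwise advance one differentiation step
  dT[, 2:(m + 1L)] <- dT[, 2:(m + 1L)] + 2 * a * flux[, 1:m, drop = FALSE]
  adv <- 2 * (1 - a[1:4]) * flux[1:4, 1:m, drop = FALSE]
  dT[2:5, 2:(m + 1L)] <- dT[2:5, 2:(m + 1L)] + adv
  # PD-1-driven apoptosis of EM and EFF cells
  dT[3L, ] <- dT[3L, ] - sp$kC03 * g * T_grid[3L, ]
  dT[4L, ] <- dT[4L, ] - sp$kC04 * g * T_grid[4L, ]
  # naive activation influx
  dT[1L, 1L] <- dT[1L, 1L] + gp$sigma_N * D_m / (gp$K_D + D_m)

  # tumor: power-law growth minus saturating kill by EM/EFF
  kill <- 0
  if (!killing_off) {
    em <- T_grid[3L, ]; eff <- T_grid[4L, ]
    pool <- sum(eff) + gp$phi_EM * sum(em)
    if (pool > 0) {
      wj <- sum((0:m) * (em + eff)) / sum(em + eff)
      ghat <- (wj / m) * (C / (C + gp$K_PD)) * (1 - B)
      kill <- C / (C + gp$K_kill) * (1 - gp$eps_kill * ghat) * sp$kE0 * pool
    }
  }
  dC <- sp$p_C * C^(2 / 3) - kill

  dDact <- sp$rho_D * C / (C + gp$K_Cdc) - (gp$m_DC + gp$d_act) * D_act
  dDm <- gp$m_DC * D_act - gp$d_m * D_m
  dP <- -(log(2) / gp$t_half) * P

  c(dT, dDact, dDm, dC, dP)
}

#' Integrate the model
#'
#' Stiff-capable integration (`deSolve::ode`, lsoda) with IV boluses
#' applied as additive events on the drug state (`P` jumps by dose/V_d).
#' Output is sampled on a uniform grid.  Tiny negative solver excursions
#' (below `1e-9` of the largest state) are clipped to zero; anything larger
#' aborts with the last valid time.
#'
#' @param sp,gp parameter sets.
#' @param schedule an `icisim_schedule`; doses at or beyond `t_span` are
#'   ignored.
#' @param t_span simulation horizon (h).
#' @param init initial `icisim_state`; defaults to [initial_state()] with
#'   `total_T = 1e8`, `tumor0 = 5e10` (the reference patient) and no DCs.
#' @param drug_off,killing_off ablation flags (see [rhs()]).
#' @param dt output grid spacing (h).
#' @param rtol relative integration tolerance.
#' @return an object of class `icisim_trajectory`: times (h), a state
#'   matrix, and the inputs used (provenance).
#' @export
simulate <- function(sp, gp, schedule = q3w_schedule(t_span), t_span,
                     init = NULL, drug_off = FALSE, killing_off = FALSE,
                     dt = 6, rtol = 1e-6) {
  if (t_span <= 0) stop("'t_span' must be positive")
  if (is.null(init)) init <- initial_state(1e8, 5e10, 0, m = gp$m)
  if (ncol(init$T_grid) != gp$m + 1L)
    stop("initial state grid does not match gp$m")
  y0 <- pack_state(init)
  names(y0) <- c(paste0("y", seq_len(state_length(gp$m) - 4L)),
                 "Dact", "Dm", "C", "P")
  times <- seq(0, t_span, by = dt)
  if (times[length(times)] < t_span) times <- c(times, t_span)

  n <- state_length(gp$m)
  ip <- n  # index of P (last entry)
  events <- NULL
  if (!drug_off && length(schedule$dose_times)) {
    keep <- schedule$dose_times < t_span
    dt_times <- schedule$dose_times[keep]
    dt_amts <- schedule$dose_amounts[keep] / gp$V_d
    if (any(dt_times == 0)) {
      y0[ip] <- y0[ip] + sum(dt_amts[dt_times == 0])
      dt_amts <- dt_amts[dt_times > 0]
      dt_times <- dt_times[dt_times > 0]
    }
    if (length(dt_times))
      events <- list(data = data.frame(var = "P", time = dt_times,
                                       value = dt_amts, method = "add"))
  }

  atol <- rep(1e-3, n)          # cell-count states: sub-cell precision
  atol[(n - 3L):(n - 2L)] <- 1e-8  # DC pools live on a much smaller scale
  atol[ip] <- 1e-10             # drug concentration (mg/L)

  pvec <- c(gp$m, sp$p_C, sp$kE0, sp$rho_D, sp$kC03, sp$kC04,
            sp$a_SCM, sp$a_CM, sp$a_EM, sp$a_EFF,
            unname(gp$p_div), unname(gp$mu),
            gp$sigma_N, gp$s_max, gp$K_D, gp$K_B, gp$K_Cdc,
            gp$m_DC, gp$d_act, gp$d_m, gp$K_PD, gp$eps_kill, gp$eps_div,
            gp$phi_EM, gp$K_kill, gp$t_half, gp$EC50,
            as.numeric(drug_off), as.numeric(killing_off))
  sol <- suppressWarnings(deSolve::ode(
    y = y0, times = times, func = "icisim_derivs", parms = pvec,
    dllname = "icisim", initfunc = "icisim_initmod",
    method = "lsoda", rtol = rtol, atol = atol, events = events,
    maxsteps = 50000))
  st <- unname(sol[, -1, drop = FALSE])
  bad <- !is.finite(st)
  if (any(bad) || nrow(st) < length(times)) {
    t_last <- if (nrow(st)) sol[max(which(apply(is.finite(st), 1, all))), 1]
              else 0
    stop("integration failed; last valid time ", signif(t_last, 6), " h")
  }
  scale <- max(abs(st))
  neg_tol <- max(1e-9 * scale, 1e-2)  # never tighter than the solver atol
  if (min(st) < -neg_tol) {
    i_bad <- which(apply(st, 1, min) < -neg_tol)[1]
    stop("state went significantly negative at t = ",
         signif(sol[i_bad, 1], 6), " h")
  }
  st[st < 0] <- 0

  structure(list(times = sol[, 1], states = st, m = gp$m, sp = sp, gp = gp,
                 schedule = schedule,
                 flags = c(drug_off = drug_off, killing_off = killing_off),
                 solver = list(method = "lsoda", rtol = rtol, dt = dt)),
            class = "icisim_trajectory")
}

#' Extract the state at a trajectory grid point
#' @param traj an `icisim_trajectory`.
#' @param i row index into the time grid.
#' @return an `icisim_state`.
#' @export
state_at <- function(traj, i) unpack_state(traj$states[i, ], traj$m)

#' Tumor-load time series of a trajectory
#'
#' @param traj an `icisim_trajectory`.
#' @param gp general parameters (for the cell-to-volume conversion);
#'   defaults to the set stored in the trajectory.
#' @return data.frame with columns `week` and `load_cm3`.
#' @export
tumor_load <- function(traj, gp = traj$gp) {
  ic <- 5L * (traj$m + 1L) + 3L
  data.frame(week = traj$times / 168,
             load_cm3 = traj$states[, ic] / gp$cells_per_cm3)
}

#' Reinvigoration level of a state
#'
#' The Ki67+ (actively dividing) percentage of the CD8+ pool: every grid
#' bin's count is weighted by its current effective division rate, summed,
#' divided by the total T-cell count, and scaled by the average division
#' time `tau`.  Exhausted cells and cells at the senescence ceiling carry
#' rate zero but count in the denominator.  Capped at 100.
#'
#' @param state an `icisim_state`.
#' @param sp,gp parameter sets.
#' @param drug_off if `TRUE`, ignore the drug when forming division rates.
#' @return percentage in [0, 100].
#' @export
reinvigoration_percent <- function(state, sp, gp, drug_off = FALSE) {
  total <- sum(state$T_grid)
  if (total <= 0) stop("reinvigoration undefined: no T cells in the state")
  B <- if (drug_off) 0 else blocked_fraction(state$P, gp$EC50)
  r <- division_rate_grid(state, sp, gp, B)
  min(100, 100 * gp$tau * sum(r * state$T_grid) / total)
}

#' Reinvigoration time course of a trajectory
#'
#' @param traj an `icisim_trajectory`.
#' @return data.frame with columns `week` and `reinvigoration_pct`.
#' @export
reinvigoration_series <- function(traj) {
  pct <- vapply(seq_along(traj$times), function(i)
    reinvigoration_percent(state_at(traj, i), traj$sp, traj$gp,
                           drug_off = traj$flags[["drug_off"]]),
    numeric(1))
  data.frame(week = traj$times / 168, reinvigoration_pct = pct)
}

#' @export
print.icisim_trajectory <- function(x, ...) {
  tl <- tumor_load(x)
  cat(sprintf(paste0("Model trajectory: %d points over %.1f weeks; ",
                     "tumor load %.3g -> %.3g cm^3\n"),
              length(x$times), max(tl$week), tl$load_cm3[1],
              tl$load_cm3[nrow(tl)]))
  invisible(x)
}

#' @export
as.data.frame.icisim_trajectory <- function(x, ...) {
  tl <- tumor_load(x)
  ri <- reinvigoration_series(x)
  ip <- state_length(x$m)
  data.frame(week = tl$week,
             tumor_load_cm3 = tl$load_cm3,
             reinvigoration_pct = ri$reinvigoration_pct,
             drug_mg_per_L = x$states[, ip])
}

#' Plot the tumor-load course of a trajectory
#' @param x an `icisim_trajectory`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.icisim_trajectory <- function(x, ...) {
  tl <- tumor_load(x)
  graphics::plot(tl$week, tl$load_cm3, type = "l",
                 xlab = "time (weeks)", ylab = "tumor load (cm³)", ...)
  if (length(x$schedule$dose_times) && !x$flags[["drug_off"]])
    graphics::rug(x$schedule$dose_times / 168)
  invisible(x)
}
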