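# Independent forward-Euler cohort simulator used as an oracle for the
# T-cell grid routing rules.  Deliberately written as plain loops over
# cohorts, independent of the package's vectorized/compiled right-hand
# side.

# One Euler step of the grid rules (division with senescence increment,
# probabilistic routing, death, PD-1 apoptosis, influx).  `T_grid` is a
# 5 x (m+1) matrix; returns the updated matrix.
euler_step_grid <- function(T_grid, sp, gp, dt, D_m = 0, C = 0, B = 0) {
  m <- gp$m
  a <- c(sp$a_SCM, sp$a_CM, sp$a_EM, sp$a_EFF, 0)
  boost <- 1 + gp$s_max * D_m / (gp$K_B + D_m)
  csat <- C / (C + gp$K_PD)
  new <- T_grid
  for (i in 1:5) {
    for (jj in 0:m) {
      n_ij <- T_grid[i, jj + 1]
      if (n_ij == 0) next
      g <- (jj / m) * csat * (1 - B)
      r <- 0
      if (jj < m) {
        if (i <= 2) r <- gp$p_div[i] * boost
        if (i %in% c(3, 4)) r <- gp$p_div[i] * (1 - gp$eps_div * g)
      }
      flux <- r * n_ij * dt
      new[i, jj + 1] <- new[i, jj + 1] - flux - gp$mu[i] * n_ij * dt
      if (i == 3) new[i, jj + 1] <- new[i, jj + 1] - sp$kC03 * g * n_ij * dt
      if (i == 4) new[i, jj + 1] <- new[i, jj + 1] - sp$kC04 * g * n_ij * dt
      if (jj < m) {
        new[i, jj + 2] <- new[i, jj + 2] + 2 * a[i] * flux
        if (i < 5)
          new[i + 1, jj + 2] <- new[i + 1, jj + 2] + 2 * (1 - a[i]) * flux
      }
    }
  }
  new[1, 1] <- new[1, 1] + gp$sigma_N * D_m / (gp$K_D + D_m) * dt
  new
}

euler_run_grid <- function(T0, sp, gp, t_end, dt, ...) {
  T_grid <- T0
  for (s in seq_len(round(t_end / dt)))
    T_grid <- euler_step_grid(T_grid, sp, gp, dt, ...)
  T_grid
}

# Toy setup used by the routing-oracle tests: only SCM and CM populated,
# m = 3, negligible death and influx.
toy_gp <- function(m = 3L) {
  general_parameters(
    m = m,
    p_div = c(SCM = 0.02, CM = 0.015, EM = 0.01, EFF = 0.005),
    mu = c(SCM = 1e-15, CM = 1e-15, EM = 1e-15, EFF = 1e-15, EXH = 1e-15),
    sigma_N = 1e-15, s_max = 1e-15)
}

ref_gp <- function(...) general_parameters(...)
ref_sp <- function(...) specific_parameters(...)
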