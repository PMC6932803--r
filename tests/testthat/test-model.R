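# Unit tests of the model building blocks: receptor blockade, PD-1
# pressure, and the assembled right-hand side.

test_that("blocked fraction follows simple receptor occupancy", {
  expect_equal(blocked_fraction(0, 1), 0)
  expect_equal(blocked_fraction(2.5, 2.5), 0.5)
  expect_equal(blocked_fraction(9 * 0.7, 0.7), 0.9)
  expect_error(blocked_fraction(1, 0), "EC50")
  expect_error(blocked_fraction(-1, 1), "non-negative")
  # monotone in P
  p <- seq(0, 50, by = 0.5)
  expect_true(all(diff(blocked_fraction(p, 3)) > 0))
})

test_that("PD-1 pressure scales with senescence, tumor and blockade", {
  gp <- ref_gp()
  expect_equal(pd1_pressure(0, 0, 10, gp), 0)
  expect_equal(pd1_pressure(1e12, 1, 25, gp), 0)   # full blockade annuls
  expect_equal(pd1_pressure(gp$K_PD, 0, gp$m, gp), 0.5)
  expect_equal(pd1_pressure(gp$K_PD, 0.5, gp$m, gp), 0.25)
  expect_error(pd1_pressure(-1, 0, 0, gp), "non-negative")
  expect_error(pd1_pressure(1, 0, gp$m + 1, gp), "j")
})

test_that("with no cells, only the drug decays", {
  sp <- ref_sp(); gp <- ref_gp()
  s <- initial_state(0, 0, 0, m = gp$m)
  s$P <- 4
  d <- rhs(0, s, sp, gp)
  expect_equal(d$P, -log(2) / gp$t_half * 4)
  expect_true(all(d$T_grid == 0))
  expect_equal(d$C, 0)
  expect_equal(d$D_act, 0)
  expect_equal(d$D_m, 0)
})

test_that("immune-free tumor grows by the pure power law", {
  sp <- ref_sp(); gp <- ref_gp()
  s <- initial_state(0, 3e10, 0, m = gp$m)
  d <- rhs(0, s, sp, gp, killing_off = TRUE)
  expect_equal(d$C, sp$p_C * (3e10)^(2 / 3))
  # with killing on but an empty grid the kill term is still zero
  d2 <- rhs(0, s, sp, gp)
  expect_equal(d2$C, d$C)
})

test_that("a single dividing cohort routes 2a to self and 2(1-a) forward", {
  sp <- ref_sp(); gp <- ref_gp()
  N <- 1e6
  T_grid <- matrix(0, 5, gp$m + 1)
  T_grid[1, 1] <- N                       # all cells in (SCM, j = 0)
  s <- model_state(T_grid)                # no DCs, no tumor -> no boost/PD
  d <- rhs(0, s, sp, gp)
  r <- gp$p_div[["SCM"]]                  # boost = 1 without mature DCs
  expect_equal(d$T_grid[1, 2], 2 * sp$a_SCM * r * N)
  expect_equal(d$T_grid[2, 2], 2 * (1 - sp$a_SCM) * r * N)
  expect_equal(d$T_grid[1, 1], -(r + gp$mu[["SCM"]]) * N)
  expect_true(all(d$T_grid[3:5, ] == 0))
})

test_that("effector cohorts differentiate into the exhausted compartment", {
  sp <- ref_sp(); gp <- ref_gp()
  T_grid <- matrix(0, 5, gp$m + 1)
  T_grid[4, 3] <- 1000                    # (EFF, j = 2)
  s <- model_state(T_grid)
  d <- rhs(0, s, sp, gp)
  r <- gp$p_div[["EFF"]]                  # C = 0 -> no PD impairment
  expect_equal(d$T_grid[5, 4], 2 * (1 - sp$a_EFF) * r * 1000)
  expect_equal(d$T_grid[4, 4], 2 * sp$a_EFF * r * 1000)
})

test_that("full blockade annuls every PD-1-mediated term", {
  sp <- ref_sp(); gp <- ref_gp()
  set.seed(42)
  T_grid <- matrix(runif(5 * (gp$m + 1), 0, 1e7), 5)
  s <- model_state(T_grid, D_act = 10, D_m = 40, C = 5e10, P = 0)
  s_blocked <- s; s_blocked$P <- 1e12     # B -> 1
  d_blocked <- rhs(0, s_blocked, sp, gp)
  # reference: same state evaluated with PD-1 couplings removed by hand
  sp0 <- sp; sp0$kC03 <- 0; sp0$kC04 <- 0
  gp0 <- gp; gp0$eps_div <- 1e-300; gp0$eps_kill <- 1e-300
  d_ref <- rhs(0, s, sp0, gp0)
  expect_equal(d_blocked$T_grid, d_ref$T_grid, tolerance = 1e-10)
  # tumor equation: only the drug state differs
  expect_equal(d_blocked$C, d_ref$C, tolerance = 1e-10)
})

test_that("no division flux leaves the senescence ceiling", {
  sp <- ref_sp(); gp <- ref_gp()
  T_grid <- matrix(0, 5, gp$m + 1)
  T_grid[1:4, gp$m + 1] <- 1e6            # everything parked at j = m
  s <- model_state(T_grid)
  d <- rhs(0, s, sp, gp)
  # only death acts: derivative is -mu * T for each compartment, and no
  # mass appears anywhere else
  expect_equal(unname(d$T_grid[, gp$m + 1]),
               -unname(gp$mu) * T_grid[, gp$m + 1])
  expect_true(all(d$T_grid[, 1:gp$m] == 0))
})

test_that("compiled and reference right-hand sides agree", {
  sp <- ref_sp(); gp <- ref_gp()
  set.seed(7)
  for (rep in 1:5) {
    y <- runif(icisim:::state_length(gp$m), 0, 1e8)
    dR <- icisim:::rhs_flat(0, y, sp, gp, FALSE, FALSE)
    # evaluate the compiled derivative through one tiny Euler step
    pvec <- c(gp$m, sp$p_C, sp$kE0, sp$rho_D, sp$kC03, sp$kC04,
              sp$a_SCM, sp$a_CM, sp$a_EM, sp$a_EFF,
              unname(gp$p_div), unname(gp$mu),
              gp$sigma_N, gp$s_max, gp$K_D, gp$K_B, gp$K_Cdc,
              gp$m_DC, gp$d_act, gp$d_m, gp$K_PD, gp$eps_kill, gp$eps_div,
              gp$phi_EM, gp$K_kill, gp$t_half, gp$EC50, 0, 0)
    sol <- deSolve::ode(y = y, times = c(0, 1e-6), func = "icisim_derivs",
                        parms = pvec, dllname = "icisim",
                        initfunc = "icisim_initmod", method = "euler")
    dC <- (sol[2, -1] - sol[1, -1]) / 1e-6
    expect_equal(unname(dC), unname(dR), tolerance = 1e-6)
  }
})

test_that("grid routing matches the brute-force cohort oracle", {
  # 2 populated compartments (SCM, CM), m = 3, no death/influx/tumor
  gp <- toy_gp()
  sp <- ref_sp()
  T0 <- matrix(0, 5, 4)
  T0[1, 1] <- 1000; T0[2, 2] <- 500
  oracle <- euler_run_grid(T0, sp, gp, t_end = 200, dt = 0.01)
  tr <- simulate(sp, gp, dose_schedule(numeric(0)), t_span = 200,
                 init = model_state(T0), dt = 200, rtol = 1e-10)
  got <- icisim:::unpack_state(tr$states[nrow(tr$states), ], gp$m)$T_grid
  expect_equal(unname(got[1:2, ]), oracle[1:2, ], tolerance = 1e-4)
  expect_equal(sum(got), sum(oracle), tolerance = 1e-4)
})

test_that("division doubles cohort mass when death is off", {
  # with death ~ 0, each division multiplies cohort mass by exactly 2:
  # total cells after full traversal from j0 = 2^(m - j0) per seed cell
  gp <- toy_gp()
  sp <- ref_sp(a_SCM = 1)                 # pure self-renewal: stays in SCM
  T0 <- matrix(0, 5, 4)
  T0[1, 1] <- 100
  tr <- simulate(sp, gp, dose_schedule(numeric(0)), t_span = 3000,
                 init = model_state(T0), dt = 100, rtol = 1e-10)
  totals <- rowSums(tr$states[, 1:20])
  expect_true(all(diff(totals) > -1e-6 * max(totals)))  # non-decreasing
  final <- icisim:::unpack_state(tr$states[nrow(tr$states), ], gp$m)$T_grid
  # after long times everything sits at j = m = 3: 100 * 2^3 cells
  expect_equal(final[1, 4], 100 * 2^3, tolerance = 1e-4)
})
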