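# Integration-level checks against closed-form solutions.

test_that("a rate-free system stays at its fixed point", {
  gp <- general_parameters(
    p_div = c(SCM = 4e-15, CM = 3e-15, EM = 2e-15, EFF = 1e-15),
    mu = c(SCM = 1e-15, CM = 1e-15, EM = 1e-15, EFF = 1e-15, EXH = 1e-15),
    sigma_N = 1e-15, s_max = 1e-15,
    m_DC = 1e-15, d_act = 1e-15, d_m = 1e-15)
  sp <- specific_parameters(p_C = 0, kE0 = 0, rho_D = 0,
                            kC03 = 0, kC04 = 0)
  init <- initial_state(1000, 1e9, 5, m = gp$m)
  tr <- simulate(sp, gp, no_treatment(), t_span = 1000, init = init)
  expect_equal(tr$states[nrow(tr$states), ], tr$states[1, ],
               tolerance = 1e-9)
})

test_that("immune-free tumor follows the power-law closed form", {
  sp <- ref_sp(); gp <- ref_gp()
  C0 <- 5e9
  t_end <- 28 * 4 * 168                       # 28 months
  init <- initial_state(0, C0, 0, m = gp$m)
  tr <- simulate(sp, gp, no_treatment(), t_end, init = init,
                 killing_off = TRUE, drug_off = TRUE)
  tl <- tumor_load(tr)
  expected <- (C0^(1 / 3) + sp$p_C * tr$times / 3)^3 / gp$cells_per_cm3
  expect_equal(tl$load_cm3, expected, tolerance = 1e-6)
})

test_that("drug concentration halves over one half-life", {
  sp <- ref_sp(); gp <- ref_gp()
  D <- 120
  init <- initial_state(0, 0, 0, m = gp$m)
  tr <- simulate(sp, gp, dose_schedule(0, D), t_span = gp$t_half,
                 init = init)
  ip <- icisim:::state_length(gp$m)
  expect_equal(tr$states[1, ip], D / gp$V_d, tolerance = 1e-9)
  expect_equal(tr$states[nrow(tr$states), ip], D / gp$V_d / 2,
               tolerance = 1e-6)
})

test_that("later doses accumulate as additive boluses", {
  sp <- ref_sp(); gp <- ref_gp()
  init <- initial_state(0, 0, 0, m = gp$m)
  tr <- simulate(sp, gp, dose_schedule(c(0, 504), 120), t_span = 510,
                 init = init)
  ip <- icisim:::state_length(gp$m)
  i510 <- which(tr$times == 510)
  expected <- (120 / gp$V_d * 2^(-504 / gp$t_half) + 120 / gp$V_d) *
    2^(-6 / gp$t_half)
  expect_equal(tr$states[i510, ip], expected, tolerance = 1e-5)
})

test_that("tumor load at 12 weeks is non-increasing in dose", {
  sp <- ref_sp(); gp <- ref_gp()
  loads <- vapply(c(0, 60, 120, 240), function(dose) {
    sched <- if (dose == 0) no_treatment() else q3w_schedule(2016, dose)
    tr <- simulate(sp, gp, sched, 2016,
                   init = initial_state(1e8, 5e10, 0, m = gp$m))
    tail(tumor_load(tr)$load_cm3, 1)
  }, numeric(1))
  expect_true(all(diff(loads) <= 1e-8 * loads[1]))
})

test_that("trajectories are reproducible and well-formed", {
  sp <- ref_sp(); gp <- ref_gp()
  tr1 <- simulate(sp, gp, q3w_schedule(1000), 1000)
  tr2 <- simulate(sp, gp, q3w_schedule(1000), 1000)
  expect_identical(tr1$states, tr2$states)
  expect_true(all(diff(tr1$times) > 0))
  expect_true(all(tr1$states >= 0))
  df <- as.data.frame(tr1)
  expect_named(df, c("week", "tumor_load_cm3", "reinvigoration_pct",
                     "drug_mg_per_L"))
  expect_error(simulate(sp, gp, q3w_schedule(10), t_span = -5), "positive")
})

test_that("tumor load converts cells to volume linearly", {
  sp <- ref_sp(); gp <- ref_gp()
  init1 <- initial_state(0, 1e9, 0, m = gp$m)
  tr <- simulate(sp, gp, no_treatment(), 12, init = init1,
                 killing_off = TRUE)
  tl <- tumor_load(tr)
  expect_equal(tl$load_cm3[1], 1)
  # doubling the cell count doubles the reported load at every point
  tl2 <- tumor_load(tr, general_parameters(cells_per_cm3 = 5e8))
  expect_equal(tl2$load_cm3, 2 * tl$load_cm3)
})

test_that("reinvigoration summarises the division-rate-weighted pool", {
  m <- 25L
  # all occupied bins divide at 1/48 per hour: 100*24/48 = 50%
  gp <- general_parameters(
    p_div = c(SCM = 1 / 48, CM = 1 / 48 - 1e-9, EM = 1 / 48 - 2e-9,
              EFF = 1 / 48 - 3e-9),
    mu = c(SCM = 1e-3, CM = 1e-3, EM = 1e-3, EFF = 1e-3, EXH = 1e-3))
  sp <- ref_sp()
  T_grid <- matrix(0, 5, m + 1)
  T_grid[1:4, 1:10] <- 25                      # away from the j = m ceiling
  st <- model_state(T_grid)                    # no DCs -> no boost; C = 0
  expect_equal(reinvigoration_percent(st, sp, gp), 50, tolerance = 1e-4)

  # two bins, counts (90, 10), rates (0, 1/24): weighted level is 10%
  gp2 <- general_parameters(
    p_div = c(SCM = 1 / 24, CM = 1 / 24 - 1e-9, EM = 1 / 24 - 2e-9,
              EFF = 1 / 24 - 3e-9),
    mu = c(SCM = 1e-3, CM = 1e-3, EM = 1e-3, EFF = 1e-3, EXH = 1e-3))
  T2 <- matrix(0, 5, m + 1)
  T2[1, m + 1] <- 90                           # ceiling row: rate 0
  T2[1, 1] <- 10
  expect_equal(reinvigoration_percent(model_state(T2), sp, gp2), 10,
               tolerance = 1e-6)

  # exhausted cells never divide
  T3 <- matrix(0, 5, m + 1)
  T3[5, 1:5] <- 100
  expect_equal(reinvigoration_percent(model_state(T3), sp, gp2), 0)

  # empty pool is an explicit error
  expect_error(reinvigoration_percent(model_state(matrix(0, 5, m + 1)),
                                      sp, gp2), "no T cells")
  # capped at 100
  gp3 <- general_parameters(
    p_div = c(SCM = 1, CM = 0.9, EM = 0.8, EFF = 0.7),
    mu = c(SCM = 1e-3, CM = 1e-3, EM = 1e-3, EFF = 1e-3, EXH = 1e-3))
  T4 <- matrix(0, 5, m + 1); T4[1, 1] <- 10
  expect_equal(reinvigoration_percent(model_state(T4), sp, gp3), 100)
})
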