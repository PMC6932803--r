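# Population sampling, screening, response classification and the
# ratio-threshold classifier.  Population-level correlation signs and the
# accuracy reproduction run in test-acceptance.R.

test_that("population sampling respects the declared ranges", {
  spec0 <- population_spec("VP0", n_patients = 0, seed = 1)
  expect_length(sample_population(spec0), 0)

  spec <- population_spec("VP1", n_patients = 500, seed = 2)
  pats <- sample_population(spec)
  kf <- vapply(pats, function(p) p$sp$kE0 / 0.00603, numeric(1))
  pf <- vapply(pats, function(p) p$sp$p_C / 1.828, numeric(1))
  loads <- vapply(pats, function(p) p$baseline_load_cm3, numeric(1))
  les <- vapply(pats, function(p) p$n_lesions, integer(1))
  expect_true(all(kf >= 0.28 & kf <= 3.5))
  expect_true(all(pf >= 0.28 & pf <= 3.5))
  expect_true(all(loads >= 1 & loads <= 300))
  expect_true(all(les %in% 1:10))
  # same seed reproduces the same population
  pats2 <- sample_population(population_spec("VP1", 500, seed = 2))
  expect_identical(vapply(pats2, function(p) p$sp$kE0, numeric(1)),
                   vapply(pats, function(p) p$sp$kE0, numeric(1)))
})

test_that("VP2 ties tumor growth rank-perfectly to baseline load", {
  spec <- population_spec("VP2", n_patients = 200, seed = 3)
  pats <- sample_population(spec)
  pc <- vapply(pats, function(p) p$sp$p_C, numeric(1))
  loads <- vapply(pats, function(p) p$baseline_load_cm3, numeric(1))
  expect_equal(cor(pc, loads, method = "spearman"), 1)
  expect_true(all(pc / 1.828 >= 0.28 - 1e-12 & pc / 1.828 <= 3.5 + 1e-12))
})

test_that("VP3 additionally rescales the division rates", {
  spec <- population_spec("VP3", n_patients = 100, seed = 4)
  pats <- sample_population(spec)
  sc <- t(vapply(pats, function(p) p$pdiv_scale, numeric(4)))
  expect_true(all(sc >= 0.5 & sc <= 2))
  expect_gt(stats::sd(sc[, 1]), 0)
  # VP0-VP2 leave division rates untouched
  p0 <- sample_population(population_spec("VP0", 5, seed = 1))
  expect_true(all(vapply(p0, function(p) all(p$pdiv_scale == 1), logical(1))))
})

test_that("irRECIST classes follow the volume thresholds", {
  expect_equal(as.character(classify_irrecist(10, 10)), "SD")
  expect_equal(as.character(classify_irrecist(10, 5)), "PR")
  expect_equal(as.character(classify_irrecist(10, 15)), "PD")
  expect_equal(as.character(classify_irrecist(10, 0)), "CR")
  expect_equal(as.character(classify_irrecist(10, 7)), "PR")    # boundary
  expect_equal(as.character(classify_irrecist(10, 12)), "PD")   # boundary
  expect_equal(as.character(classify_irrecist(c(10, 2), c(8, 3))),
               c("SD", "PD"))
  expect_error(classify_irrecist(0, 1), "positive")
  expect_error(classify_irrecist(10, -1), "non-negative")
})

test_that("screening keeps growing tumors and drops controlled ones", {
  gp <- ref_gp()
  base <- list(sp = ref_sp(), gp = gp)
  mk <- function(id, fk, fp, load) {
    sp <- ref_sp(); sp$kE0 <- sp$kE0 * fk; sp$p_C <- sp$p_C * fp
    structure(list(id = id, sp = sp,
                   pdiv_scale = c(SCM = 1, CM = 1, EM = 1, EFF = 1),
                   baseline_load_cm3 = load, n_lesions = 2L),
              class = "icisim_patient")
  }
  expect_length(screen_progressors(list(), gp), 0)
  strong_immunity <- mk(1, 10, 0.28, 30)     # regresses untreated
  weak_immunity <- mk(2, 0.28, 3.5, 30)      # progresses untreated
  kept <- screen_progressors(list(strong_immunity, weak_immunity), gp)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$id, 2)
  expect_s3_class(kept[[1]]$lead_state, "icisim_state")
  expect_gt(kept[[1]]$treat_start_load_cm3, 1.2 * 30)
})

test_that("trial outcomes are deterministic and kE0 extremes classify", {
  gp <- ref_gp()
  mk <- function(id, fk, fp, load = 40) {
    sp <- ref_sp(); sp$kE0 <- sp$kE0 * fk; sp$p_C <- sp$p_C * fp
    structure(list(id = id, sp = sp,
                   pdiv_scale = c(SCM = 1, CM = 1, EM = 1, EFF = 1),
                   baseline_load_cm3 = load, n_lesions = 1L),
              class = "icisim_patient")
  }
  pats <- screen_progressors(list(mk(1, 1e-9, 1), mk(2, 1e-9, 1)), gp)
  expect_length(pats, 2)
  res <- run_trial(pats, gp)
  # identical patients give identical rows (determinism)
  expect_equal(res[1, -1], res[2, -1], ignore_attr = TRUE)
  # kE0 ~ 0: untreated-equivalent growth -> progressive disease
  expect_equal(as.character(res$class[1]), "PD")
  expect_true(all(res$week12_cm3 > 1.2 * res$baseline_cm3))

  # degenerate p_C = 0 with normal immunity: any killing shrinks the
  # tumor -> responder (screening bypassed by construction)
  p0 <- mk(3, 1, 0)
  p0$lead_state <- initial_state(1e8, 40 * gp$cells_per_cm3, 0, m = gp$m)
  p0$treat_start_load_cm3 <- 40
  res0 <- run_trial(list(p0), gp)
  expect_true(res0$responder)
})

test_that("the threshold scan maximizes balanced accuracy", {
  # perfectly separated ratios
  sep <- weighted_accuracy(c(1, 2, 10, 20), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$accuracy, 1)
  expect_gt(sep$threshold, 2); expect_lt(sep$threshold, 10)

  # orientation-free: separable with responders at LOW ratios too
  sep2 <- weighted_accuracy(c(1, 2, 10, 20), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep2$accuracy, 1)
  expect_equal(sep2$direction, "<")

  # 4-point toy set with one label flipped: best of the 5 thresholds
  # gives 3 of 4 right in the balanced sense
  toy <- weighted_accuracy(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(toy$accuracy, 0.75)

  expect_error(weighted_accuracy(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("label-independent ratios give chance-level accuracy", {
  set.seed(99)
  n <- 1000
  ratios <- rexp(n)
  accs <- vapply(1:100, function(i) {
    labels <- sample(rep(c(TRUE, FALSE), each = n / 2))
    weighted_accuracy(ratios, labels)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("the accuracy scan is invariant to common rescaling", {
  set.seed(5)
  ratios <- rlnorm(60)
  labels <- ratios * exp(rnorm(60)) > 1
  if (length(unique(labels)) < 2) labels[1:5] <- !labels[1:5]
  a1 <- weighted_accuracy(ratios, labels)
  a2 <- weighted_accuracy(ratios * 1e3, labels)
  expect_equal(a1$accuracy, a2$accuracy)
  expect_equal(a2$threshold, a1$threshold * 1e3, tolerance = 1e-6)
})
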