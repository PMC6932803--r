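# Calibration of model parameters to a tumor-load series.
#
# Cost = RMSE between simulated and observed load at the measurement weeks,
# plus a quadratic penalty for bound violations and a fixed penalty when the
# same patient simulated WITHOUT drug fails to progress (tumors that regress
# untreated are clinically infeasible for this cohort).  The optimizer is a
# seeded hybrid: annealed random restarts over the bounded box alternate
# with derivative-free local refinement (Nelder-Mead), keeping the best-ever
# point.

#' Calibration configuration
#'
#' @param free_specific names of patient-specific parameters to fit; bounds
#'   default to 0.28-3.5 times the reference value (wide, conceivable
#'   range).
#' @param free_general names of scalar general parameters to fit; bounds
#'   default to +/-20% of the reference value (narrow range around the
#'   literature-scale default).
#' @param reference list with elements `sp` and `gp` providing the
#'   reference parameter values (defaults to the package defaults).
#' @param lambda_bound weight of the quadratic out-of-bounds penalty.
#' @param lambda_trend weight of the untreated-progression penalty.
#' @param budget maximal number of cost evaluations for [fit()].
#' @param seed RNG seed; fits are bit-reproducible given the seed.
#' @param tumor0_cm3,total_T initial conditions used for every simulation
#'   (`NULL` tumor0 means: use the first observed load).
#' @param specific_fold,general_frac bound half-widths (fold range for
#'   specific parameters, relative range for general ones).
#' @return an object of class `icisim_fit_config`.
#' @export
fit_config <- function(free_specific = c("kE0", "p_C"),
                       free_general = character(),
                       reference = list(sp = specific_parameters(),
                                        gp = general_parameters()),
                       lambda_bound = 1e3, lambda_trend = 1e2,
                       budget = 400, seed = 1,
                       tumor0_cm3 = NULL, total_T = 1e8,
                       specific_fold = c(0.28, 3.5),
                       general_frac = 0.2) {
  stopifnot(budget >= 1)
  bad <- setdiff(free_specific, names(reference$sp))
  if (length(bad)) stop("unknown specific parameter(s): ",
                        paste(bad, collapse = ", "))
  gp_scalars <- setdiff(names(reference$gp), c("m", "p_div", "mu"))
  bad <- setdiff(free_general, gp_scalars)
  if (length(bad)) stop("unknown/non-scalar general parameter(s): ",
                        paste(bad, collapse = ", "))
  free <- c(free_specific, free_general)
  ref_vals <- c(unlist(reference$sp[free_specific]),
                unlist(reference$gp[free_general]))
  lower <- c(unlist(reference$sp[free_specific]) * specific_fold[1],
             unlist(reference$gp[free_general]) * (1 - general_frac))
  upper <- c(unlist(reference$sp[free_specific]) * specific_fold[2],
             unlist(reference$gp[free_general]) * (1 + general_frac))
  names(ref_vals) <- names(lower) <- names(upper) <- free
  structure(list(free_specific = free_specific,
                 free_general = free_general,
                 reference = reference,
                 ref_vals = ref_vals, lower = lower, upper = upper,
                 lambda_bound = lambda_bound, lambda_trend = lambda_trend,
                 budget = budget, seed = seed,
                 tumor0_cm3 = tumor0_cm3, total_T = total_T),
            class = "icisim_fit_config")
}

# Assemble full (sp, gp) from a named vector of free-parameter values.
assemble_params <- function(values, config) {
  sp <- config$reference$sp
  gp <- config$reference$gp
  for (nm in config$free_specific) sp[[nm]] <- unname(values[[nm]])
  for (nm in config$free_general) gp[[nm]] <- unname(values[[nm]])
  list(sp = sp, gp = gp)
}

#' Calibration cost of a candidate parameter set
#'
#' Root-mean-square error between simulated and observed tumor load at the
#' measurement weeks, plus `lambda_bound * sum(violation^2)` for parameters
#' outside their box and `lambda_trend` if the untreated counterpart of the
#' same patient fails to reach 1.2x baseline load by week 12.
#'
#' @param values named vector of free-parameter values.
#' @param data an `icisim_series`.
#' @param config a [fit_config()].
#' @return non-negative scalar cost; `Inf` if the simulation fails.
#' @export
cost <- function(values, data, config) {
  values <- unlist(values)[names(config$ref_vals)]
  pars <- assemble_params(values, config)
  tumor0 <- if (is.null(config$tumor0_cm3)) data$load_cm3[1]
            else config$tumor0_cm3
  t_span <- max(data$week) * 168
  init <- initial_state(config$total_T,
                        tumor0 * pars$gp$cells_per_cm3, 0, m = pars$gp$m)
  sim <- tryCatch(
    simulate(pars$sp, pars$gp, q3w_schedule(t_span + 1), t_span,
             init = init),
    error = function(e) NULL)
  if (is.null(sim)) return(Inf)
  tl <- tumor_load(sim)
  pred <- vapply(data$week, function(w)
    tl$load_cm3[which.min(abs(tl$week - w))], numeric(1))
  rmse <- sqrt(mean((pred - data$load_cm3)^2))

  viol <- pmax(0, config$lower - values) + pmax(0, values - config$upper)
  pen_b <- config$lambda_bound * sum(viol^2)

  pen_t <- 0
  if (config$lambda_trend > 0) {
    unt <- tryCatch(
      simulate(pars$sp, pars$gp, no_treatment(), 12 * 168, init = init,
               drug_off = TRUE),
      error = function(e) NULL)
    if (is.null(unt)) return(Inf)
    u12 <- tail(tumor_load(unt)$load_cm3, 1)
    if (u12 < 1.2 * tumor0) pen_t <- config$lambda_trend
  }
  rmse + pen_b + pen_t
}

#' Fit model parameters to a tumor-load series
#'
#' Seeded hybrid global/local search over the bounded box: an annealed
#' random-restart scheme proposes candidates in log-space (global moves
#' shrink as the temperature drops), and every improvement is refined with
#' a short Nelder-Mead descent.  The best-ever point is returned together
#' with the accepted-cost trace.
#'
#' @param data an `icisim_series` with at least 4 measurements.
#' @param config a [fit_config()].
#' @return an object of class `icisim_fit`: `best_params` (named vector),
#'   `best_cost`, `cost_trace`, `n_eval`, `converged`, and the config.
#' @export
fit <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "icisim_series"))
  if (nrow(data) < 4) stop("need at least 4 data points to fit")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  n_eval <- 0L
  budget <- config$budget
  f <- function(v) {
    if (n_eval >= budget) return(NULL)
    n_eval <<- n_eval + 1L
    cost(v, data, config)
  }
  llo <- log(config$lower); lhi <- log(config$upper)
  clamp <- function(lv) pmin(pmax(lv, llo), lhi)

  best <- config$ref_vals
  best_cost <- f(best)
  trace <- best_cost
  cur <- log(best); cur_cost <- best_cost

  while (n_eval < budget) {
    frac <- n_eval / budget
    temp <- max(0.05, 1 - frac)          # annealed proposal width
    width <- temp * (lhi - llo) / 2
    cand <- clamp(cur + runif(length(cur), -1, 1) * width)
    cc <- f(exp(cand))
    if (is.null(cc)) break
    if (cc < cur_cost || runif(1) < 0.1 * temp) {  # occasional uphill move
      cur <- cand; cur_cost <- cc
    }
    if (cc < best_cost) {
      best <- exp(cand); best_cost <- cc
      trace <- c(trace, best_cost)
      # local refinement around the new best
      if (n_eval + 5 < budget) {
        obj <- function(lv) {
          v <- f(exp(clamp(lv)))
          if (is.null(v)) best_cost else v
        }
        res <- tryCatch(
          if (length(best) == 1L)
            optim(log(best), obj, method = "Brent",
                  lower = llo, upper = lhi,
                  control = list(maxit = min(40, budget - n_eval)))
          else
            optim(log(best), obj, method = "Nelder-Mead",
                  control = list(maxit = min(40, budget - n_eval))),
          error = function(e) NULL)
        if (!is.null(res) && res$value < best_cost) {
          best <- exp(clamp(res$par)); best_cost <- res$value
          trace <- c(trace, best_cost)
          cur <- log(best); cur_cost <- best_cost
        }
      }
    }
    if (best_cost < 1e-12) break         # exact fit found
  }
  structure(list(best_params = best, best_cost = best_cost,
                 cost_trace = trace, n_eval = n_eval,
                 converged = n_eval < budget || best_cost < 1e-12,
                 n_obs = nrow(data), config = config),
            class = "icisim_fit")
}

#' @export
print.icisim_fit <- function(x, ...) {
  cat("Model fit:", x$n_eval, "cost evaluations, best cost",
      signif(x$best_cost, 5), "\n")
  print(signif(x$best_params, 5))
  invisible(x)
}

# Simulation residuals (predicted - observed load, cm^3) of a candidate
# free-parameter vector; NA on simulation failure.
residuals_cm3 <- function(values, data, config) {
  values <- unlist(values)[names(config$ref_vals)]
  pars <- assemble_params(values, config)
  tumor0 <- if (is.null(config$tumor0_cm3)) data$load_cm3[1]
            else config$tumor0_cm3
  t_span <- max(data$week) * 168
  init <- initial_state(config$total_T,
                        tumor0 * pars$gp$cells_per_cm3, 0, m = pars$gp$m)
  sim <- tryCatch(
    simulate(pars$sp, pars$gp, q3w_schedule(t_span + 1), t_span,
             init = init),
    error = function(e) NULL)
  if (is.null(sim)) return(rep(NA_real_, nrow(data)))
  tl <- tumor_load(sim)
  vapply(data$week, function(w)
    tl$load_cm3[which.min(abs(tl$week - w))], numeric(1)) - data$load_cm3
}

# Interval where a profiled objective stays below `threshold` above its
# minimum, found by bisection on each side of `theta_star` over
# [lower, upper].  Returns the interval plus per-side saturation flags
# (TRUE when the objective never crosses before hitting the box edge).
profile_interval <- function(objective, theta_star, lower, upper, threshold,
                             f_min = objective(theta_star), tol = 1e-6) {
  cross <- function(a, b) {            # f(a) <= thr < f(b) assumed
    for (i in 1:60) {
      mid <- (a + b) / 2
      if (objective(mid) - f_min <= threshold) a <- mid else b <- mid
      if (abs(b - a) <= tol * (abs(a) + tol)) break
    }
    (a + b) / 2
  }
  if (threshold <= 0) return(list(lower = theta_star, upper = theta_star,
                                  sat_lower = FALSE, sat_upper = FALSE))
  sat_lo <- objective(lower) - f_min <= threshold
  sat_hi <- objective(upper) - f_min <= threshold
  list(lower = if (sat_lo) lower else cross(theta_star, lower),
       upper = if (sat_hi) upper else cross(theta_star, upper),
       sat_lower = sat_lo, sat_upper = sat_hi)
}

#' Profile confidence interval for a fitted parameter
#'
#' Profiles the squared-error surface over one parameter (re-optimizing the
#' remaining free parameters at each value) and returns the region where
#' the profiled sum of squares stays within a chi-square threshold of the
#' minimum: `SSR(theta) <= SSR* + qchisq(level, 1) * SSR*/(n - p)` under a
#' Gaussian-error approximation.  If the profile never crosses the
#' threshold on one side (a saturated, flat likelihood), the interval is
#' extended to the box edge and flagged.
#'
#' @param fit_result an [fit()] result.
#' @param data the series that was fitted.
#' @param param_name one of the free parameters.
#' @param level coverage level (e.g. 0.90).
#' @param refit_budget cost evaluations per conditional re-optimization.
#' @param tol relative bisection tolerance on the interval endpoints.
#' @return list with `lower`, `upper`, `level`, `saturated_lower`,
#'   `saturated_upper`.
#' @export
profile_ci <- function(fit_result, data, param_name, level = 0.9,
                       refit_budget = 25, tol = 1e-3) {
  stopifnot(inherits(fit_result, "icisim_fit"))
  config <- fit_result$config
  free <- names(config$ref_vals)
  if (!param_name %in% free) stop("'", param_name, "' was not fitted")
  n <- fit_result$n_obs
  p <- length(free)
  if (n <= p) stop("not enough observations to form a profile interval")
  others <- setdiff(free, param_name)

  # Squared-error surface to profile.  With per-point measurement errors
  # the weighted sum of squares is chi-square distributed around the truth
  # (the uniform axis-error model implies sd ~ err/3, a conservative upper
  # bound for multi-lesion loads), so the threshold is the plain
  # chi-square quantile.  Without errors, fall back to the RMSE-based
  # surface with the variance estimated from the residuals.
  weighted <- !is.null(data$err_cm3) && all(data$err_cm3 > 0)
  if (weighted) {
    ssr_fn <- function(v) {
      r <- residuals_cm3(v, data, config)
      if (anyNA(r)) return(Inf)
      sum((r / (data$err_cm3 / 3))^2)
    }
    threshold <- qchisq(level, df = 1)
  } else {
    ssr_fn <- function(v) n * cost(v, data, config)^2
    sigma2 <- n * fit_result$best_cost^2 / (n - p)
    threshold <- qchisq(level, df = 1) * sigma2
  }
  ssr_min <- ssr_fn(fit_result$best_params)

  prof <- function(theta) {
    v <- fit_result$best_params
    v[param_name] <- theta
    if (!length(others)) return(ssr_fn(v))
    # conditional refit of the remaining parameters (log-space Nelder-Mead
    # from the joint optimum; 1-D uses optimize)
    obj <- function(lx) {
      v[others] <- exp(lx)
      ssr_fn(v)
    }
    if (length(others) == 1L) {
      o <- optimize(obj, interval = log(c(config$lower[others],
                                          config$upper[others])),
                    tol = 1e-2)
      o$objective
    } else {
      o <- optim(log(v[others]), obj, method = "Nelder-Mead",
                 control = list(maxit = refit_budget))
      o$value
    }
  }

  ssr_min <- min(ssr_min, prof(fit_result$best_params[[param_name]]))
  iv <- profile_interval(prof, fit_result$best_params[[param_name]],
                         config$lower[[param_name]],
                         config$upper[[param_name]], threshold,
                         f_min = ssr_min, tol = tol)
  list(parameter = param_name, lower = iv$lower, upper = iv$upper,
       level = level, saturated_lower = iv$sat_lower,
       saturated_upper = iv$sat_upper)
}
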