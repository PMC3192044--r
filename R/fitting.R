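#' Fit configuration
#'
#' Settings for nonlinear least-squares fitting.  The optimizer is bounded
#' Levenberg–Marquardt ([minpack.lm::nls.lm]) with multi-start: one start at
#' data-driven initial values and the rest at seeded log-uniform jitter
#' around them, because growth-curve likelihood surfaces are multimodal
#' enough that single-start `nls` style fitting can fail to converge.
#'
#' @param family One of `"logistic"`, `"brody"`, `"brody_offset"`,
#'   `"von_bertalanffy"`, `"linear"`, `"log_hyperbola"`, `"sj2p"`.
#' @param fix_j Optional fixed join age in months (SJ2P only); when set, the
#'   five remaining free parameters are estimated with `j` pinned.
#' @param j_grid Join-age profiling grid `c(lo, hi, n)` in months; default
#'   20 points over `[0.6, 1.8] * 7.392857` months (i.e. around the 207-day
#'   weaning prior).
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Integer seed for the start jitter.
#' @param max_iter,tol Levenberg–Marquardt iteration cap and convergence
#'   tolerance (`ftol`/`ptol`).
#' @return A `fit_config` object.
#' @export
fit_config <- function(family, fix_j = NULL, j_grid = NULL, n_starts = 8L,
                       seed = 1L, max_iter = 300L, tol = 1e-12) {
  families <- c("logistic", "brody", "brody_offset", "von_bertalanffy",
                "linear", "log_hyperbola", "sj2p")
  if (!family %in% families) {
    gs_stop(paste0("unknown family: ", family), "gs_param_error")
  }
  if (is.null(j_grid)) {
    j_prior <- days_to_months(207)
    j_grid <- c(0.6 * j_prior, 1.8 * j_prior, 20)
  }
  if (length(j_grid) != 3 || j_grid[1] >= j_grid[2] || j_grid[3] < 2) {
    gs_stop("j_grid must be c(lo, hi, n) with lo < hi and n >= 2",
            "gs_param_error")
  }
  if (n_starts < 1) gs_stop("n_starts must be >= 1", "gs_param_error")
  structure(list(family = family, fix_j = fix_j, j_grid = j_grid,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "fit_config")
}

# ---- family fitting specifications ----------------------------------------

# Each spec: parameter names, box bounds, data-driven init, a predictor
# pred(theta, age), a validity penalty for constraints a box cannot express,
# and a constructor for the fitted params object.
family_spec <- function(family) {
  eps <- 1e-8
  switch(family,
    logistic = list(
      pnames = c("A", "K", "L0", "r"),
      lower = c(-Inf, eps, eps, eps), upper = c(Inf, Inf, Inf, Inf),
      init = function(age, value) {
        span <- max(diff(range(value)), 1)
        c(A = min(value) - 0.02 * span, K = span, L0 = 0.05 * span,
          r = 2 / max(stats::median(age), 0.1))
      },
      pred = function(th, age) th[["A"]] +
        logistic_core(th[["K"]], th[["L0"]], th[["r"]], age),
      invalid = function(th) th[["L0"]] >= th[["K"]],
      make = function(th) logistic_params(th[["A"]], th[["K"]], th[["L0"]], th[["r"]])
    ),
    brody = list(
      pnames = c("B", "C", "k"),
      lower = c(eps, eps, eps), upper = c(Inf, 1 - eps, Inf),
      init = function(age, value) {
        B0 <- max(value) * 1.02
        C0 <- min(max(1 - min(value) / B0, 0.05), 0.9)
        c(B = B0, C = C0, k = 1 / max(stats::median(age), 0.1))
      },
      pred = function(th, age) th[["B"]] * (1 - th[["C"]] * exp(-th[["k"]] * age)),
      invalid = function(th) FALSE,
      make = function(th) brody_params(th[["B"]], th[["C"]], th[["k"]])
    ),
    brody_offset = list(
      pnames = c("a", "b", "k"),
      lower = c(-Inf, eps, eps), upper = c(Inf, Inf, Inf),
      init = function(age, value) {
        c(a = min(value), b = max(diff(range(value)), 1),
          k = 1 / max(stats::median(age), 0.1))
      },
      pred = function(th, age) th[["a"]] + th[["b"]] * (1 - exp(-th[["k"]] * age)),
      invalid = function(th) FALSE,
      make = function(th) brody_offset_params(th[["a"]], th[["b"]], th[["k"]])
    ),
    von_bertalanffy = list(
      pnames = c("L0", "a", "b"),
      lower = c(-Inf, eps, eps), upper = c(Inf, Inf, Inf),
      init = function(age, value) {
        b0 <- 1 / max(stats::median(age), 0.1)
        c(L0 = min(value), a = max(value) * 1.05 * b0, b = b0)
      },
      pred = function(th, age) {
        asy <- th[["a"]] / th[["b"]]
        asy - (asy - th[["L0"]]) * exp(-th[["b"]] * age)
      },
      invalid = function(th) th[["a"]] / th[["b"]] <= th[["L0"]],
      make = function(th) von_bertalanffy_params(th[["L0"]], th[["a"]], th[["b"]])
    ),
    gs_stop(paste0("no nonlinear spec for family: ", family), "gs_param_error")
  )
}

# penalized residuals: keep a gradient toward the feasible region
penalty_residuals <- function(n, size = 1e4) rep(size, n)

nls_multistart <- function(resid_fn, start, lower, upper, cfg,
                           jitter_abs = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = cfg$max_iter, ftol = cfg$tol,
                                     ptol = cfg$tol)
  starts <- with_sim_seed(cfg$seed, {
    lapply(seq_len(cfg$n_starts), function(i) {
      if (i == 1) return(start)
      th <- start
      for (nm in names(th)) {
        if (!is.null(jitter_abs) && nm %in% names(jitter_abs)) {
          th[[nm]] <- th[[nm]] + stats::rnorm(1, 0, jitter_abs[[nm]])
        } else if (th[[nm]] > 0) {
          th[[nm]] <- th[[nm]] * exp(stats::runif(1, -1.2, 1.2))
        } else {
          th[[nm]] <- th[[nm]] * exp(stats::runif(1, -0.5, 0.5))
        }
      }
      pmin(pmax(th, lower + 1e-10), ifelse(is.finite(upper), upper - 1e-10, th))
    })
  })
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  best
}

fit_result <- function(family, estimates, std_errors, rss, data, predicted,
                       converged, boundary, p, cfg, age_unit = "month28",
                       gof_phase = NULL, extra = list()) {
  res <- c(list(
    family = family, estimates = estimates, std_errors = std_errors,
    rss = rss, n = nrow(data), converged = converged, boundary = boundary,
    p = p, age_unit = age_unit,
    gof_overall = tryCatch(gof(data$value_mm, predicted, p),
                           error = function(e) NULL),
    gof_by_phase = gof_phase,
    residuals = data.frame(
      animal_id = data$animal_id, age_months = data$age_months,
      observed = data$value_mm, predicted = predicted,
      residual = data$value_mm - predicted
    ),
    config = cfg
  ), extra)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit> n=%d rss=%.4g converged=%s\n", x$family, x$n, x$rss,
              x$converged))
  est <- unlist(x$estimates)
  se <- unlist(x$std_errors)[names(est)]
  tab <- data.frame(estimate = est, std_error = se)
  print(round(tab, 5))
  if (!is.null(x$gof_overall)) { cat("overall: "); print(x$gof_overall) }
  invisible(x)
}

prep_fit_data <- function(data, p_free) {
  data <- morph_records(data)
  data <- data[!is.na(data$age_months), , drop = FALSE]
  if (nrow(data) < p_free + 2) {
    gs_stop(sprintf("need at least %d records with known age", p_free + 2),
            "gs_data_error")
  }
  if (diff(range(data$age_months)) <= 0) {
    gs_stop("ages must span a positive range", "gs_data_error")
  }
  data
}

se_from_hessian <- function(hessian, rss, n, p) {
  s2 <- rss / max(n - p, 1)
  tryCatch(sqrt(diag(solve(hessian)) * s2), error = function(e)
    rep(NA_real_, ncol(hessian)))
}

#' Fit a single-phase growth curve
#'
#' Least-squares fit of one curve family to morphometric records with known
#' ages.  The linear family is fitted by ordinary least squares (on age in
#' days); the log-hyperbola by least squares on the log measurement; all
#' other families by bounded multi-start Levenberg–Marquardt.  Standard
#' errors come from the Gauss–Newton approximation `(J'J)^-1 * s^2` at the
#' optimum.  Non-convergence is a reportable state (`converged = FALSE`),
#' not an exception; estimates pinned at a box bound set the `boundary`
#' flag so an unidentifiable fit is never reported silently as a clean one.
#'
#' @param data A [morph_records()] frame (rows with `NA` age are ignored).
#' @param cfg A [fit_config()].
#' @return A `fit_result`: estimates, standard errors, `rss`, `n`,
#'   `converged`, `boundary`, overall [gof()] (per-phase for SJ2P), and
#'   per-record residuals.
#' @export
fit_curve <- function(data, cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  switch(cfg$family,
    sj2p = fit_sj2p(data, cfg),
    linear = fit_linear(data, cfg),
    log_hyperbola = fit_log_hyperbola(data, cfg),
    fit_nls_family(data, cfg)
  )
}

fit_nls_family <- function(data, cfg) {
  spec <- family_spec(cfg$family)
  p <- length(spec$pnames)
  data <- prep_fit_data(data, p)
  age <- data$age_months
  value <- data$value_mm
  resid_fn <- function(th) {
    names(th) <- spec$pnames
    if (spec$invalid(th)) return(penalty_residuals(length(value)))
    r <- value - spec$pred(th, age)
    if (any(!is.finite(r))) return(penalty_residuals(length(value)))
    r
  }
  start <- spec$init(age, value)
  best <- nls_multistart(resid_fn, start, spec$lower, spec$upper, cfg)
  if (is.null(best)) {
    return(fit_result(cfg$family, stats::setNames(as.list(start), spec$pnames),
                      stats::setNames(as.list(rep(NA_real_, p)), spec$pnames),
                      Inf, data, rep(NA_real_, nrow(data)),
                      converged = FALSE, boundary = FALSE, p = p, cfg = cfg))
  }
  th <- stats::setNames(stats::coef(best$fit), spec$pnames)
  on_bound <- (is.finite(spec$lower) & th <= spec$lower + 1e-6) |
              (is.finite(spec$upper) & th >= spec$upper - 1e-6)
  se <- se_from_hessian(best$fit$hessian, best$rss, nrow(data), p)
  converged <- best$fit$info %in% 1:3 && is.finite(best$rss)
  fit_result(cfg$family, as.list(th),
             stats::setNames(as.list(se), spec$pnames), best$rss, data,
             spec$pred(th, age), converged, any(on_bound), p, cfg,
             extra = list(params = tryCatch(spec$make(th),
                                            error = function(e) NULL)))
}

fit_linear <- function(data, cfg) {
  data <- prep_fit_data(data, 2)
  age_days <- months_to_days(data$age_months)
  fit <- stats::lm(data$value_mm ~ age_days)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers a perfect-fit warning
  est <- list(intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]))
  se <- list(intercept = sm$coefficients[1, 2], slope = sm$coefficients[2, 2])
  pred <- unname(stats::fitted(fit))
  fit_result("linear", est, se, sum(stats::resid(fit)^2), data, pred,
             converged = TRUE, boundary = FALSE, p = 2, cfg,
             age_unit = "day",
             extra = list(params = linear_params(est$intercept, est$slope)))
}

# The hyperbola's join age j is confounded with its level: the predictor is
# (b4 - b3/j) + b3/age, so only b3 and the combination b4 - b3/j are
# identifiable from post-pouch data alone.  j is therefore always pinned
# (cfg$fix_j in months, default the 207-day weaning age), as in its original
# use, and the remaining model is linear in 1/age - 1/j: fit by OLS on the
# log measurement.
fit_log_hyperbola <- function(data, cfg) {
  data <- prep_fit_data(data, 2)
  age_days <- months_to_days(data$age_months)
  j <- if (!is.null(cfg$fix_j)) months_to_days(cfg$fix_j) else 207
  if (any(age_days <= j)) {
    gs_stop(sprintf("log-hyperbola needs all ages > j = %g days", j),
            "gs_data_error")
  }
  logv <- log(data$value_mm)
  x <- 1 / age_days - 1 / j
  fit <- stats::lm(logv ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers a perfect-fit warning
  th <- c(b3 = unname(stats::coef(fit)[2]), b4 = unname(stats::coef(fit)[1]),
          j = j)
  se <- list(b3 = sm$coefficients[2, 2], b4 = sm$coefficients[1, 2],
             j = NA_real_)
  fit_result("log_hyperbola", as.list(th), se,
             sum(stats::resid(fit)^2), data, exp(unname(stats::fitted(fit))),
             converged = TRUE, boundary = FALSE, p = 2, cfg, age_unit = "day",
             extra = list(params = log_hyperbola_params(th[["b3"]], th[["b4"]],
                                                        th[["j"]]),
                          note = "rss and residuals are on the log scale",
                          rss_scale = "log"))
}

# ---- SJ2P fitting ----------------------------------------------------------

sj2p_pnames5 <- c("C", "K", "L0", "k", "r")

sj2p_pred_factory <- function(age, value, j_of_theta) {
  function(th) {
    f <- tryCatch(
      sj2p_free_params(C = th[["C"]], K = th[["K"]], L0 = th[["L0"]],
                       k = th[["k"]], j = j_of_theta(th), r = th[["r"]]),
      error = function(e) NULL
    )
    if (is.null(f)) return(penalty_residuals(length(value)))
    m <- tryCatch(derive_joined(f), error = function(e) NULL)
    if (is.null(m)) return(penalty_residuals(length(value)))
    r <- value - eval_sj2p(m, age)
    if (any(!is.finite(r))) return(penalty_residuals(length(value)))
    r
  }
}

sj2p_init <- function(age, value, j) {
  pre <- age <= j
  post <- !pre
  span <- if (any(pre)) max(diff(range(value[pre])), 1) else
    max(diff(range(value)), 1)
  k0 <- if (any(post)) 1 / max(stats::median(age[post]), 1) else 0.05
  c(C = 0.5, K = span * 1.1, L0 = 0.05 * span, k = k0,
    r = 4 / max(j, 0.5))
}

sj2p_bounds <- function() {
  eps <- 1e-6
  list(lower = c(C = eps, K = eps, L0 = eps, k = eps, r = eps),
       upper = c(C = 1 - eps, K = Inf, L0 = Inf, k = Inf, r = Inf))
}

fit_sj2p_fixed <- function(data, cfg, j, start = NULL, n_starts = cfg$n_starts) {
  age <- data$age_months
  value <- data$value_mm
  resid_fn <- sj2p_pred_factory(age, value, function(th) j)
  if (is.null(start)) start <- sj2p_init(age, value, j)
  b <- sj2p_bounds()
  cfg2 <- cfg
  cfg2$n_starts <- as.integer(n_starts)
  nls_multistart(resid_fn, start[sj2p_pnames5], b$lower, b$upper, cfg2)
}

#' Profile the SJ2P join age by residual sum of squares
#'
#' For each candidate join age `j` on a grid, fits the five remaining free
#' parameters with `j` pinned and records the residual sum of squares; the
#' estimate `j_star` is the grid minimiser refined by a local 1-D
#' minimisation between its grid neighbours.  Ties are broken toward smaller
#' `j` (the earlier pouch-exit reading).  Consecutive grid fits are
#' warm-started from the previous optimum.
#'
#' @param data A [morph_records()] frame; must contain ages both below the
#'   grid's lower and above its upper bound, otherwise a data error is
#'   raised.
#' @param cfg A [fit_config()] (`j_grid` supplies the grid).
#' @return List with `profile` (data frame of `j`, `rss`, ascending in `j`)
#'   and `j_star` (months).
#' @export
profile_join <- function(data, cfg = fit_config("sj2p")) {
  data <- prep_fit_data(data, 6)
  grid <- seq(cfg$j_grid[1], cfg$j_grid[2], length.out = cfg$j_grid[3])
  if (!any(data$age_months < grid[1]) || !any(data$age_months > grid[length(grid)])) {
    gs_stop("data must span ages on both sides of the j grid", "gs_data_error")
  }
  rss <- numeric(length(grid))
  fits <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    best <- fit_sj2p_fixed(data, cfg, grid[i], start = warm,
                           n_starts = if (i == 1) cfg$n_starts else 2L)
    if (is.null(best)) {
      rss[i] <- Inf
    } else {
      rss[i] <- best$rss
      fits[[i]] <- best
      warm <- stats::setNames(stats::coef(best$fit), sj2p_pnames5)
    }
  }
  if (all(!is.finite(rss))) {
    gs_stop("no join-age candidate produced a feasible fit", "gs_data_error")
  }
  i_star <- which.min(rss)  # first minimum: tie toward smaller j
  lo <- grid[max(i_star - 1, 1)]
  hi <- grid[min(i_star + 1, length(grid))]
  warm_star <- stats::setNames(stats::coef(fits[[i_star]]$fit), sj2p_pnames5)
  obj <- function(j) {
    best <- fit_sj2p_fixed(data, cfg, j, start = warm_star, n_starts = 1L)
    if (is.null(best)) Inf else best$rss
  }
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-4)
  j_star <- if (opt$objective <= rss[i_star]) opt$minimum else grid[i_star]
  list(profile = data.frame(j = grid, rss = rss), j_star = j_star)
}

#' Fit the SJ2P model
#'
#' Estimates the six free SJ2P parameters `(C, K, L0, k, j, r)` by least
#' squares; every candidate parameter vector is passed through
#' [derive_joined()], so value and slope continuity at the join hold at
#' every optimizer iterate (an infeasible join is rejected with a penalty).
#' With `cfg$fix_j` set (months), `j` is pinned and only the other five are
#' estimated — the "fixed 207-day weaning age" mode.  Otherwise
#' [profile_join()] supplies the starting join age and all six parameters
#' are then optimized jointly.
#'
#' @inheritParams fit_curve
#' @return A `fit_result`; `estimates` holds all six free parameters plus
#'   the derived `A` and `B`, `gof_by_phase` the pouch/post split at the
#'   fitted join age, and `model` the fitted `sj2p_model`.
#' @export
fit_sj2p <- function(data, cfg = fit_config("sj2p")) {
  stopifnot(inherits(cfg, "fit_config"))
  data <- prep_fit_data(data, if (is.null(cfg$fix_j)) 6 else 5)
  age <- data$age_months
  value <- data$value_mm

  if (!is.null(cfg$fix_j)) {
    j <- cfg$fix_j
    if (!any(age <= j) || !any(age > j)) {
      gs_stop("data must include ages on both sides of the fixed join age",
              "gs_data_error")
    }
    best <- fit_sj2p_fixed(data, cfg, j)
    p <- 5
    if (is.null(best)) {
      return(fit_result("sj2p", list(), list(), Inf, data,
                        rep(NA_real_, nrow(data)), FALSE, FALSE, p, cfg))
    }
    th5 <- stats::setNames(stats::coef(best$fit), sj2p_pnames5)
    free <- sj2p_free_params(C = th5[["C"]], K = th5[["K"]], L0 = th5[["L0"]],
                             k = th5[["k"]], j = j, r = th5[["r"]])
    se5 <- se_from_hessian(best$fit$hessian, best$rss, nrow(data), p)
    se <- as.list(stats::setNames(se5, sj2p_pnames5))
    se$j <- NA_real_
    info_ok <- best$fit$info %in% 1:3
    b <- sj2p_bounds()
    on_bound <- any((is.finite(b$lower) & th5 <= b$lower + 1e-6) |
                    (is.finite(b$upper) & th5 >= b$upper - 1e-6))
    rss <- best$rss
  } else {
    cfg_prof <- cfg
    prof <- profile_join(data, cfg_prof)
    warm5 <- fit_sj2p_fixed(data, cfg, prof$j_star, n_starts = cfg$n_starts)
    th5 <- if (is.null(warm5)) sj2p_init(age, value, prof$j_star)[sj2p_pnames5]
           else stats::setNames(stats::coef(warm5$fit), sj2p_pnames5)
    start6 <- c(th5, j = prof$j_star)
    resid_fn <- sj2p_pred_factory(age, value, function(th) th[["j"]])
    b <- sj2p_bounds()
    lower <- c(b$lower, j = 1e-4)
    upper <- c(b$upper, j = Inf)
    pn <- c(sj2p_pnames5, "j")
    best <- nls_multistart(function(th) { names(th) <- pn; resid_fn(th) },
                           start6, lower, upper, cfg)
    p <- 6
    if (is.null(best)) {
      return(fit_result("sj2p", list(), list(), Inf, data,
                        rep(NA_real_, nrow(data)), FALSE, FALSE, p, cfg,
                        extra = list(profile = prof$profile)))
    }
    th6 <- stats::setNames(stats::coef(best$fit), pn)
    free <- sj2p_free_params(C = th6[["C"]], K = th6[["K"]], L0 = th6[["L0"]],
                             k = th6[["k"]], j = th6[["j"]], r = th6[["r"]])
    se6 <- se_from_hessian(best$fit$hessian, best$rss, nrow(data), p)
    se <- as.list(stats::setNames(se6, pn))
    info_ok <- best$fit$info %in% 1:3
    on_bound <- any((is.finite(lower) & th6 <= lower + 1e-6) |
                    (is.finite(upper) & th6 >= upper - 1e-6))
    rss <- best$rss
  }

  model <- derive_joined(free)
  predicted <- eval_sj2p(model, age)
  estimates <- c(unclass(free)[], list(A = model$A, B = model$B))
  se$A <- NA_real_; se$B <- NA_real_
  phase <- tryCatch(gof_by_phase(data, model, p), error = function(e) NULL)
  fit_result("sj2p", estimates, se[names(estimates)], rss, data, predicted,
             converged = info_ok && is.finite(rss), boundary = on_bound,
             p = p, cfg = cfg, gof_phase = phase,
             extra = c(list(model = model),
                       if (is.null(cfg$fix_j)) list(profile = prof$profile)))
}

# ---- reporting -------------------------------------------------------------

#' Serialize a fit result to a JSON report
#'
#' Writes (or returns) the versioned JSON report for a fit: schema tag,
#' family, parameter table (estimate and standard error), fit statistics,
#' per-phase goodness of fit where applicable, convergence state, and a
#' config echo (including seed) so the fit is reproducible from the report
#' alone.
#'
#' @param res A `fit_result`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_report_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "fit_result"))
  gof_list <- function(g) if (is.null(g)) NULL else unclass(g)
  cfg <- res$config
  rep <- list(
    schema = "growthseam/1",
    family = res$family,
    age_unit = res$age_unit,
    n = res$n,
    converged = res$converged,
    boundary = res$boundary,
    rss = res$rss,
    parameters = lapply(stats::setNames(names(res$estimates), names(res$estimates)),
                        function(nm) list(estimate = res$estimates[[nm]],
                                          std_error = res$std_errors[[nm]])),
    gof_overall = gof_list(res$gof_overall),
    gof_by_phase = if (!is.null(res$gof_by_phase)) list(
      pouch = gof_list(res$gof_by_phase$pouch),
      post = gof_list(res$gof_by_phase$post)
    ),
    config = list(family = cfg$family, fix_j = cfg$fix_j, j_grid = cfg$j_grid,
                  n_starts = cfg$n_starts, seed = cfg$seed,
                  max_iter = cfg$max_iter, tol = cfg$tol)
  )
  if (res$family == "sj2p" && !is.null(res$model)) {
    rep$model <- jsonlite::fromJSON(sj2p_to_json(res$model))
  }
  txt <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
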