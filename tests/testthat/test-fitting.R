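noiseless_fit_check <- function(truth, family, ages, tol = 1e-4) {
  d <- exact_records(truth, ages)
  res <- fit_curve(d, fit_config(family, seed = 4, n_starts = 4))
  expect_true(res$converged, label = paste(family, "converged"))
  truth_vals <- unlist(unclass(truth)[])
  est <- unlist(res$estimates)[names(truth_vals)]
  expect_equal(est, truth_vals, tolerance = tol,
               label = paste(family, "estimates"))
  # the optimum cannot be worse than the generating parameters
  expect_lte(res$rss, 1e-8)
  invisible(res)
}

test_that("noiseless data recovers the generating parameters per family", {
  ages <- seq(0.3, 30, length.out = 30)
  noiseless_fit_check(tbl_logistic_pouch(), "logistic",
                      seq(0.3, 12, length.out = 30))
  noiseless_fit_check(tbl_brody_male_pp(), "brody", ages)
  noiseless_fit_check(brody_offset_params(10, 137, 0.12), "brody_offset", ages)
  noiseless_fit_check(von_bertalanffy_params(2.42, 13.79, 0.022),
                      "von_bertalanffy", seq(1, 120, length.out = 40))
  noiseless_fit_check(linear_params(0.8643, 0.2452), "linear",
                      seq(0.7, 7.4, length.out = 20))
})

test_that("log-hyperbola recovers its coefficients with the join pinned", {
  # j is confounded with the level (only b4 - b3/j and b3 are identifiable),
  # so the fit pins it, defaulting to the 207-day weaning age
  truth <- log_hyperbola_params(b3 = -150, b4 = 5, j = 207)
  ages_days <- seq(215, 2000, length.out = 25)
  d <- data.frame(animal_id = as.character(seq_along(ages_days)), sex = "M",
                  age_months = days_to_months(ages_days), measure = "pes",
                  value_mm = exp(eval_log_hyperbola(truth, ages_days)))
  res <- fit_curve(d, fit_config("log_hyperbola", seed = 4))
  expect_true(res$converged)
  expect_equal(unlist(res$estimates)[c("b3", "b4", "j")],
               c(b3 = -150, b4 = 5, j = 207), tolerance = 1e-6)
  expect_true(is.na(res$std_errors$j))
  # a pre-join record is a data error, not a silent drop
  d2 <- rbind(d, data.frame(animal_id = "young", sex = "M",
                            age_months = days_to_months(100),
                            measure = "pes", value_mm = 50))
  expect_error(fit_curve(d2, fit_config("log_hyperbola")),
               class = "gs_data_error")
})

test_that("noiseless SJ2P data recovers all six free parameters", {
  truth <- tbl_sj2p_male()
  m <- derive_joined(truth)
  ages <- c(seq(0.7, 7.4, length.out = 34), seq(9, 80, length.out = 40))
  d <- exact_records(m, ages)
  res <- fit_sj2p(d, fit_config("sj2p", seed = 4, n_starts = 4))
  expect_true(res$converged)
  truth_vals <- unlist(unclass(truth)[])
  est <- unlist(res$estimates)[names(truth_vals)]
  expect_equal(est, truth_vals, tolerance = 1e-4)
  rss_truth <- sum((d$value_mm - eval_sj2p(m, d$age_months))^2)
  expect_lte(res$rss, rss_truth + 1e-8)
})

test_that("join-age profiling finds the true join on noiseless data", {
  m <- derive_joined(tbl_sj2p_male())
  ages <- c(seq(0.7, 7.4, length.out = 34), seq(9, 40, length.out = 30))
  d <- exact_records(m, ages)
  pr <- profile_join(d, fit_config("sj2p", seed = 4, n_starts = 4))
  expect_equal(pr$j_star, 7.85, tolerance = 1e-3)
  expect_false(is.unsorted(pr$profile$j))
  rss_at_star <- sum((fit_sj2p(d, fit_config("sj2p", fix_j = pr$j_star,
                                             seed = 4))$residuals$residual)^2)
  expect_true(all(pr$profile$rss >= rss_at_star - 1e-6))
})

test_that("profiling demands data on both sides of the grid", {
  m <- derive_joined(tbl_sj2p_male())
  d <- exact_records(m, seq(0.5, 40, length.out = 40))
  cfg <- fit_config("sj2p", j_grid = c(50, 60, 5))
  expect_error(profile_join(d, cfg), class = "gs_data_error")
})

test_that("fixed-join mode pins j and reports no standard error for it", {
  m <- derive_joined(tbl_sj2p_male())
  ages <- c(seq(0.7, 7.3, length.out = 30), seq(8, 60, length.out = 30))
  d <- exact_records(m, ages)
  j_fix <- days_to_months(207)
  res <- fit_sj2p(d, fit_config("sj2p", fix_j = j_fix, seed = 4))
  expect_identical(res$estimates$j, j_fix)
  expect_true(is.na(res$std_errors$j))
  expect_equal(sum(!is.na(unlist(res$std_errors[c("C", "K", "L0", "k", "r")]))), 5)
  expect_equal(res$p, 5)
})

test_that("estimates are invariant to record order and relabeling", {
  set.seed(41)
  truth <- tbl_brody_male_pp()
  cfg <- sim_config(truth, list(list(n = 60, age_range = c(17, 80), sd = 9.85)),
                    seed = 42)
  d <- simulate_cross_sectional(cfg)
  r1 <- fit_curve(d, fit_config("brody", seed = 4))
  d2 <- d[sample(nrow(d)), ]
  d2$animal_id <- paste0("relabeled_", seq_len(nrow(d2)))
  r2 <- fit_curve(d2, fit_config("brody", seed = 4))
  expect_equal(unlist(r1$estimates), unlist(r2$estimates), tolerance = 1e-6)
})

test_that("fitted-model RMSE approaches the generating noise sd", {
  truth <- tbl_logistic_pouch()
  cfg <- sim_config(truth, list(list(n = 2000, age_range = c(0.2, 12), sd = 5)),
                    seed = 43)
  d <- simulate_cross_sectional(cfg)
  res <- fit_curve(d, fit_config("logistic", seed = 4))
  expect_equal(res$gof_overall$rmse, 5, tolerance = 0.05)
})

test_that("constant data is never reported as a clean converged fit", {
  d <- data.frame(animal_id = as.character(1:20), sex = "M",
                  age_months = seq(1, 20), measure = "pes", value_mm = 50)
  res <- fit_curve(d, fit_config("logistic", seed = 4, n_starts = 2))
  expect_true(!res$converged || res$boundary ||
                isTRUE(res$gof_overall$constant_response))
})

test_that("insufficient or degenerate data raises a data error", {
  d <- data.frame(animal_id = c("a", "b", "c"), sex = "M",
                  age_months = c(1, 2, 3), measure = "pes",
                  value_mm = c(10, 20, 30))
  expect_error(fit_curve(d, fit_config("logistic")), class = "gs_data_error")
  same_age <- data.frame(animal_id = as.character(1:10), sex = "M",
                         age_months = 5, measure = "pes",
                         value_mm = rnorm(10, 50, 1))
  expect_error(fit_curve(same_age, fit_config("brody")),
               class = "gs_data_error")
  # all data on one side of a fixed join
  one_side <- data.frame(animal_id = as.character(1:30), sex = "M",
                         age_months = seq(10, 40, length.out = 30),
                         measure = "pes", value_mm = seq(100, 140, length.out = 30))
  expect_error(fit_sj2p(one_side, fit_config("sj2p", fix_j = 7.4)),
               class = "gs_data_error")
})

test_that("fit reports serialize to versioned JSON with a config echo", {
  m <- derive_joined(tbl_sj2p_male())
  ages <- c(seq(0.7, 7.3, length.out = 30), seq(8, 60, length.out = 30))
  d <- exact_records(m, ages)
  res <- fit_sj2p(d, fit_config("sj2p", fix_j = days_to_months(207), seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  fit_report_json(res, path)
  rep <- jsonlite::fromJSON(path)
  expect_identical(rep$schema, "growthseam/1")
  expect_identical(rep$config$seed, 9L)
  expect_equal(rep$parameters$j$estimate, days_to_months(207))
  expect_false(is.null(rep$gof_by_phase$pouch))
  m2 <- sj2p_from_json(rep$model)
  expect_equal(m2$B, res$model$B, tolerance = 1e-9)
})
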