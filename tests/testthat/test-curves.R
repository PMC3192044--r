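test_that("logistic evaluation matches its closed-form anchors", {
  p <- tbl_logistic_pouch()
  expect_equal(eval_logistic(p, 0), 16.06 + 1.11)
  expect_equal(curve_asymptote(p), 109.98)
  # algebraic limit A + K reached numerically at large age
  expect_equal(eval_logistic(p, 1e3), 109.98, tolerance = 1e-8)
  v <- eval_logistic(p, seq(0, 40, length.out = 1000))
  expect_true(all(diff(v) >= 0))         # saturates to the asymptote
  expect_true(all(diff(v[1:500]) > 0))   # strictly rising before saturation
})

test_that("logistic inflection sits at half-span with maximum slope rK/4", {
  p <- tbl_logistic_pouch()
  # numeric argmax of the finite-difference slope is the independent oracle
  opt <- optimize(function(t) fd_slope(function(x) eval_logistic(p, x), t),
                  interval = c(0.1, 30), maximum = TRUE)
  t_inf <- log((p$K - p$L0) / p$L0) / p$r
  expect_equal(opt$maximum, t_inf, tolerance = 1e-4)
  expect_equal(eval_logistic(p, t_inf), p$A + p$K / 2, tolerance = 1e-9)
  expect_equal(curve_slope(p, t_inf), p$r * p$K / 4, tolerance = 1e-9)
})

test_that("Brody evaluation: start value, C = 0 flatness, asymptote", {
  p <- tbl_brody_male_pp()
  expect_equal(eval_brody(p, 0), 154.91 * (1 - 0.567))
  expect_equal(eval_brody(p, 0), 67.08, tolerance = 1e-4)
  flat <- brody_params(B = 120, C = 0, k = 0.3)
  expect_equal(eval_brody(flat, c(0, 5, 50)), rep(120, 3))
  expect_equal(curve_slope(flat, c(0, 5, 50)), rep(0, 3))
  expect_equal(eval_brody(p, 1e3), curve_asymptote(p), tolerance = 1e-6)
})

test_that("offset-Brody evaluation: endpoints and half-span age", {
  p <- brody_offset_params(a = 10, b = 137, k = 0.12)
  expect_equal(eval_brody_offset(p, 0), 10)
  expect_equal(curve_asymptote(p), 147)
  expect_equal(eval_brody_offset(p, log(2) / 0.12), 10 + 137 / 2)
})

test_that("von Bertalanffy solves dL/dt = a - bL with the stated limits", {
  p <- von_bertalanffy_params(L0 = 2.42, a = 13.79, b = 0.022)
  expect_equal(eval_von_bertalanffy(p, 0), 2.42)
  expect_equal(curve_asymptote(p), 13.79 / 0.022)
  expect_equal(eval_von_bertalanffy(p, log(2) / 0.022),
               (2.42 + 13.79 / 0.022) / 2)
})

test_that("linear family is exact and homogeneous in age", {
  p <- linear_params(0.8643, 0.2452)
  expect_equal(eval_linear(p, 0), 0.8643)
  expect_equal(eval_linear(p, 100), 25.3843)
  inc1 <- eval_linear(p, 50) - eval_linear(p, 0)
  inc2 <- eval_linear(p, 100) - eval_linear(p, 0)
  expect_equal(inc2, 2 * inc1)
})

test_that("post-pouch log hyperbola: join value, limit, domain", {
  p <- log_hyperbola_params(b3 = -5, b4 = 5, j = 207)
  expect_equal(eval_log_hyperbola(p, 207 + 1e-9), 5, tolerance = 1e-9)
  expect_equal(curve_asymptote(p), 5 + 5 / 207)
  expect_equal(eval_log_hyperbola(p, 1e9), 5 + 5 / 207, tolerance = 1e-6)
  expect_error(eval_log_hyperbola(p, 207 / 2), class = "gs_domain_error")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(logistic_params(0, -1, 0.5, 1), class = "gs_param_error")
  expect_error(logistic_params(0, 10, 11, 1), class = "gs_param_error")
  expect_error(logistic_params(0, 10, 1, -1), class = "gs_param_error")
  expect_error(brody_params(100, 1.2, 0.1), class = "gs_param_error")
  expect_error(brody_params(-5, 0.5, 0.1), class = "gs_param_error")
  expect_error(brody_offset_params(1, -2, 0.1), class = "gs_param_error")
  expect_error(von_bertalanffy_params(100, 1, 0.5), class = "gs_param_error")
  expect_error(log_hyperbola_params(1, 1, -3), class = "gs_param_error")
  expect_error(eval_logistic(tbl_logistic_pouch(), -1),
               class = "gs_domain_error")
})

test_that("all families are increasing with the stated asymptote", {
  set.seed(11)
  grid <- seq(0, 60, length.out = 1000)
  for (fam in c("logistic", "brody", "brody_offset", "von_bertalanffy")) {
    for (rep in 1:10) {
      p <- random_curve_params(fam)
      v <- eval_curve(p, grid)
      # non-decreasing everywhere, strictly rising before float saturation
      expect_true(all(diff(v) >= 0), label = paste(fam, "monotone"))
      expect_true(all(diff(v[grid < 5]) > 0),
                  label = paste(fam, "strictly increasing early"))
      asy <- curve_asymptote(p)
      expect_lt(abs(eval_curve(p, 1e3) - asy), 1e-3 * abs(asy))
    }
  }
})

test_that("analytic slopes agree with central finite differences", {
  set.seed(12)
  ages <- c(0.5, 2, 5, 12, 30)
  for (fam in c("logistic", "brody", "brody_offset", "von_bertalanffy")) {
    for (rep in 1:20) {
      p <- random_curve_params(fam)
      fd <- fd_slope(function(t) eval_curve(p, t), ages)
      expect_equal(curve_slope(p, ages), fd, tolerance = 1e-4,
                   label = paste(fam, "slope"))
    }
  }
  pl <- linear_params(2, 0.3)
  expect_equal(curve_slope(pl, c(1, 10)), rep(0.3, 2))
  ph <- log_hyperbola_params(-5, 5, 207)
  expect_equal(curve_slope(ph, 300),
               fd_slope(function(t) eval_log_hyperbola(ph, t), 300),
               tolerance = 1e-4)
})

test_that("closed-form inverses round-trip through evaluation", {
  set.seed(13)
  for (fam in c("logistic", "brody", "brody_offset", "von_bertalanffy")) {
    for (rep in 1:10) {
      p <- random_curve_params(fam)
      ages <- c(0.3, 1, 4, 8)  # clear of the asymptote's float plateau
      expect_equal(curve_inverse(p, eval_curve(p, ages)), ages,
                   tolerance = 1e-6, label = paste(fam, "inverse"))
    }
  }
  p <- tbl_brody_male_pp()
  expect_error(curve_inverse(p, p$B), class = "gs_range_error")
  expect_error(curve_inverse(p, 0.5 * p$B * (1 - p$C)),
               class = "gs_range_error")
})

test_that("curve parameters serialize to flat JSON and back", {
  for (p in list(tbl_logistic_pouch(), tbl_brody_male_pp(),
                 linear_params(0.8643, 0.2452),
                 log_hyperbola_params(-5, 5, 207))) {
    q <- params_from_json(params_to_json(p))
    expect_identical(attr(q, "family"), attr(p, "family"))
    expect_equal(unclass(q)[], unclass(p)[])
  }
  expect_error(params_from_json('{"family":"nope","params":{}}'),
               class = "gs_param_error")
})
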