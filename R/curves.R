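#' Single-phase growth-curve families
#'
#' Constructors for the parameter sets of each single-phase curve family used
#' in two-phase macropod growth modelling.  Parameters are validated eagerly:
#' an invalid value raises a parameter-domain error at construction time, so
#' evaluation functions can assume a valid object.
#'
#' The families and their closed forms (age `t`):
#' \describe{
#'   \item{logistic}{`A + K*L0 / ((K - L0)*exp(-r*t) + L0)`.  `A` is the lower
#'     asymptote offset (may be negative), `K` the span of the logistic core,
#'     `L0` the core value at birth, `r` the intrinsic growth rate (per
#'     month).  Upper asymptote `A + K`; inflection at core value `K/2`
#'     where the slope attains its maximum `r*K/4`.}
#'   \item{brody}{`B * (1 - C*exp(-k*t))`.  Monomolecular approach to the
#'     mature asymptote `B`; `C` is an adjustment parameter for a non-zero
#'     starting value, `k` the maturing rate index (per month).}
#'   \item{brody_offset}{`a + b*(1 - exp(-k*t))`: the Brody shape
#'     re-parameterised by value at age zero `a` and growth span `b`.}
#'   \item{von_bertalanffy}{solution of `dL/dt = a - b*L` with `L(0) = L0`,
#'     i.e. `a/b - (a/b - L0)*exp(-b*t)`; asymptote `a/b`, no inflection.}
#'   \item{linear}{`intercept + slope*t` with `t` in days; used for
#'     pouch-phase head length, whose growth is very nearly linear.}
#'   \item{log_hyperbola}{`log m = b4 + b3/t - b3/j` for `t > j` (days); the
#'     legacy post-pouch hyperbola retained as a comparator.  `b4` is the
#'     fitted log-measurement at the join age `j`.}
#' }
#'
#' All families except `linear` and `log_hyperbola` take age in months
#' (1 month = 28 days exactly); those two take age in days, recorded in the
#' object's `age_unit` attribute.
#'
#' @param A,K,L0,r,B,C,k,a,b,intercept,slope,b3,b4,j Scalar parameters, see
#'   Details.
#' @return An object of class `c("<family>_params", "curve_params")`.
#' @seealso [eval_curve()], [curve_slope()], [curve_inverse()],
#'   [curve_asymptote()]
#' @name curve_families
NULL

new_curve_params <- function(family, params, age_unit) {
  structure(params,
    class = c(paste0(family, "_params"), "curve_params"),
    family = family, age_unit = age_unit
  )
}

check_param <- function(ok, what) {
  if (!isTRUE(ok)) gs_stop(paste0("invalid parameters: ", what), "gs_param_error")
}

check_scalar <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      gs_stop(paste0("parameter '", nm[i], "' must be a finite numeric scalar"),
              "gs_param_error")
    }
  }
}

#' @rdname curve_families
#' @export
logistic_params <- function(A, K, L0, r) {
  check_scalar(A = A, K = K, L0 = L0, r = r)
  check_param(K > 0, "K must be > 0")
  # guard tolerance keeps the core away from the degenerate L0 -> K limit
  check_param(L0 > 0 && L0 < K * (1 - 1e-9), "L0 must satisfy 0 < L0 < K")
  check_param(r > 0, "r must be > 0")
  new_curve_params("logistic", list(A = A, K = K, L0 = L0, r = r), "month28")
}

#' @rdname curve_families
#' @export
brody_params <- function(B, C, k) {
  check_scalar(B = B, C = C, k = k)
  check_param(B > 0, "B must be > 0")
  check_param(C >= 0 && C < 1, "C must satisfy 0 <= C < 1")
  check_param(k > 0, "k must be > 0")
  new_curve_params("brody", list(B = B, C = C, k = k), "month28")
}

#' @rdname curve_families
#' @export
brody_offset_params <- function(a, b, k) {
  check_scalar(a = a, b = b, k = k)
  check_param(b > 0, "b must be > 0")
  check_param(k > 0, "k must be > 0")
  new_curve_params("brody_offset", list(a = a, b = b, k = k), "month28")
}

#' @rdname curve_families
#' @export
von_bertalanffy_params <- function(L0, a, b) {
  check_scalar(L0 = L0, a = a, b = b)
  check_param(a > 0, "a must be > 0")
  check_param(b > 0, "b must be > 0")
  check_param(a / b > L0, "asymptote a/b must exceed L0")
  new_curve_params("von_bertalanffy", list(L0 = L0, a = a, b = b), "month28")
}

#' @rdname curve_families
#' @export
linear_params <- function(intercept, slope) {
  check_scalar(intercept = intercept, slope = slope)
  new_curve_params("linear", list(intercept = intercept, slope = slope), "day")
}

#' @rdname curve_families
#' @export
log_hyperbola_params <- function(b3, b4, j) {
  check_scalar(b3 = b3, b4 = b4, j = j)
  check_param(j > 0, "join age j must be > 0")
  new_curve_params("log_hyperbola", list(b3 = b3, b4 = b4, j = j), "day")
}

# ---- evaluation ------------------------------------------------------------

logistic_core <- function(K, L0, r, age) {
  K * L0 / ((K - L0) * exp(-r * age) + L0)
}

#' Evaluate a growth curve
#'
#' `eval_curve()` evaluates a curve family at the given ages (in the family's
#' own age unit: months for the nonlinear families, days for the linear and
#' log-hyperbola families).  The per-family wrappers (`eval_logistic()` etc.)
#' are convenience aliases.  `log_hyperbola` returns the *log* measurement
#' and is only defined for ages strictly greater than its join age `j`.
#'
#' @param p A `curve_params` object.
#' @param age Numeric vector of ages, `>= 0`.
#' @return Numeric vector of measurements (mm), or log-mm for
#'   `log_hyperbola`.
#' @examples
#' p <- logistic_params(A = 16.06, K = 93.92, L0 = 1.11, r = 0.96)
#' eval_curve(p, c(0, 3, 6))
#' @export
eval_curve <- function(p, age) {
  UseMethod("eval_curve")
}

#' @export
eval_curve.logistic_params <- function(p, age) {
  check_nonnegative_age(age)
  p$A + logistic_core(p$K, p$L0, p$r, age)
}

#' @export
eval_curve.brody_params <- function(p, age) {
  check_nonnegative_age(age)
  p$B * (1 - p$C * exp(-p$k * age))
}

#' @export
eval_curve.brody_offset_params <- function(p, age) {
  check_nonnegative_age(age)
  p$a + p$b * (1 - exp(-p$k * age))
}

#' @export
eval_curve.von_bertalanffy_params <- function(p, age) {
  check_nonnegative_age(age)
  asy <- p$a / p$b
  asy - (asy - p$L0) * exp(-p$b * age)
}

#' @export
eval_curve.linear_params <- function(p, age) {
  check_nonnegative_age(age)
  p$intercept + p$slope * age
}

#' @export
eval_curve.log_hyperbola_params <- function(p, age) {
  if (any(age <= p$j)) {
    gs_stop(sprintf("log-hyperbola is defined for age > j = %g days", p$j),
            "gs_domain_error")
  }
  p$b4 + p$b3 / age - p$b3 / p$j
}

#' @rdname eval_curve
#' @export
eval_logistic <- function(p, age) eval_curve.logistic_params(p, age)

#' @rdname eval_curve
#' @export
eval_brody <- function(p, age) eval_curve.brody_params(p, age)

#' @rdname eval_curve
#' @export
eval_brody_offset <- function(p, age) eval_curve.brody_offset_params(p, age)

#' @rdname eval_curve
#' @export
eval_von_bertalanffy <- function(p, age) eval_curve.von_bertalanffy_params(p, age)

#' @rdname eval_curve
#' @export
eval_linear <- function(p, age) eval_curve.linear_params(p, age)

#' @rdname eval_curve
#' @export
eval_log_hyperbola <- function(p, age) eval_curve.log_hyperbola_params(p, age)

# ---- analytic slope --------------------------------------------------------

#' Analytic first derivative of a growth curve
#'
#' Returns `dL/d age` in mm per age unit (log-mm per day for the
#' log-hyperbola).  For the logistic the slope is `r*core*(1 - core/K)` where
#' `core = L - A`; at the inflection this equals the maximum growth rate
#' `r*K/4`.  For the Brody it is `B*C*k*exp(-k*age)`.
#'
#' @inheritParams eval_curve
#' @return Numeric vector of slopes.
#' @export
curve_slope <- function(p, age) {
  UseMethod("curve_slope")
}

#' @export
curve_slope.logistic_params <- function(p, age) {
  check_nonnegative_age(age)
  core <- logistic_core(p$K, p$L0, p$r, age)
  p$r * core * (1 - core / p$K)
}

#' @export
curve_slope.brody_params <- function(p, age) {
  check_nonnegative_age(age)
  p$B * p$C * p$k * exp(-p$k * age)
}

#' @export
curve_slope.brody_offset_params <- function(p, age) {
  check_nonnegative_age(age)
  p$b * p$k * exp(-p$k * age)
}

#' @export
curve_slope.von_bertalanffy_params <- function(p, age) {
  check_nonnegative_age(age)
  (p$a - p$b * p$L0) * exp(-p$b * age)
}

#' @export
curve_slope.linear_params <- function(p, age) {
  check_nonnegative_age(age)
  rep_len(p$slope, length(age))
}

#' @export
curve_slope.log_hyperbola_params <- function(p, age) {
  if (any(age <= p$j)) {
    gs_stop(sprintf("log-hyperbola is defined for age > j = %g days", p$j),
            "gs_domain_error")
  }
  -p$b3 / age^2
}

# ---- asymptote and inverse -------------------------------------------------

#' Asymptote of a growth curve
#'
#' The large-age limit of the curve: `A + K` (logistic), `B` (Brody),
#' `a + b` (offset Brody), `a/b` (von Bertalanffy), `b4 - b3/j` on the log
#' scale (log-hyperbola).  The linear family is unbounded and raises a
#' domain error.
#'
#' @param p A `curve_params` object.
#' @return Scalar asymptote.
#' @export
curve_asymptote <- function(p) {
  UseMethod("curve_asymptote")
}

#' @export
curve_asymptote.logistic_params <- function(p) p$A + p$K

#' @export
curve_asymptote.brody_params <- function(p) p$B

#' @export
curve_asymptote.brody_offset_params <- function(p) p$a + p$b

#' @export
curve_asymptote.von_bertalanffy_params <- function(p) p$a / p$b

#' @export
curve_asymptote.linear_params <- function(p) {
  gs_stop("the linear family has no asymptote", "gs_domain_error")
}

#' @export
curve_asymptote.log_hyperbola_params <- function(p) p$b4 - p$b3 / p$j

#' Analytic inverse of a monotone growth curve
#'
#' Solves `eval_curve(p, age) = value` for age, in closed form.  Defined on
#' the half-open interval from the value at the lower end of the age domain
#' up to (but excluding) the asymptote; values outside raise an out-of-range
#' error naming the valid interval.  For `log_hyperbola`, `value` is the log
#' measurement and the returned age is in days.
#'
#' @param p A `curve_params` object.
#' @param value Measurement (mm; log-mm for `log_hyperbola`).
#' @return Age in the family's age unit.
#' @export
curve_inverse <- function(p, value) {
  UseMethod("curve_inverse")
}

check_invert_range <- function(value, lo, hi, lo_closed = TRUE) {
  bad <- if (lo_closed) value < lo | value >= hi else value <= lo | value >= hi
  if (any(bad)) {
    gs_stop(sprintf(
      "value outside invertible range %s%.6g, %.6g)",
      if (lo_closed) "[" else "(", lo, hi
    ), "gs_range_error")
  }
}

#' @export
curve_inverse.logistic_params <- function(p, value) {
  check_invert_range(value, p$A + p$L0, p$A + p$K)
  core <- value - p$A
  log((p$K - p$L0) / (p$K / core - 1) / p$L0) / p$r
}

#' @export
curve_inverse.brody_params <- function(p, value) {
  if (p$C == 0) gs_stop("constant Brody curve (C = 0) is not invertible",
                        "gs_domain_error")
  check_invert_range(value, p$B * (1 - p$C), p$B)
  -log((1 - value / p$B) / p$C) / p$k
}

#' @export
curve_inverse.brody_offset_params <- function(p, value) {
  check_invert_range(value, p$a, p$a + p$b)
  -log(1 - (value - p$a) / p$b) / p$k
}

#' @export
curve_inverse.von_bertalanffy_params <- function(p, value) {
  asy <- p$a / p$b
  check_invert_range(value, p$L0, asy)
  -log((asy - value) / (asy - p$L0)) / p$b
}

#' @export
curve_inverse.linear_params <- function(p, value) {
  if (p$slope == 0) gs_stop("flat linear curve is not invertible",
                            "gs_domain_error")
  (value - p$intercept) / p$slope
}

#' @export
curve_inverse.log_hyperbola_params <- function(p, value) {
  if (p$b3 == 0) gs_stop("constant log-hyperbola is not invertible",
                         "gs_domain_error")
  asy <- p$b4 - p$b3 / p$j
  # b3 < 0: increasing from b4 at age j towards asy
  if (p$b3 < 0) check_invert_range(value, p$b4, asy, lo_closed = FALSE)
  else check_invert_range(-value, -p$b4, -asy, lo_closed = FALSE)
  p$b3 / (value - p$b4 + p$b3 / p$j)
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("<%s growth curve> (age unit: %s)\n", attr(x, "family"),
              attr(x, "age_unit")))
  print(unlist(x, use.names = TRUE))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Serialize curve parameters to/from JSON
#'
#' Flat JSON object `{family, params:{...}, age_unit}` used in fit reports
#' and scenario files.
#'
#' @param p A `curve_params` object, or for `params_from_json` a JSON string
#'   or parsed list.
#' @return `params_to_json`: a JSON string; `params_from_json`: a
#'   `curve_params` object.
#' @export
params_to_json <- function(p) {
  jsonlite::toJSON(
    list(family = attr(p, "family"), params = unclass(p)[],
         age_unit = attr(p, "age_unit")),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname params_to_json
#' @export
params_from_json <- function(p) {
  x <- if (is.character(p)) jsonlite::fromJSON(p) else p
  ctor <- switch(x$family,
    logistic = logistic_params,
    brody = brody_params,
    brody_offset = brody_offset_params,
    von_bertalanffy = von_bertalanffy_params,
    linear = linear_params,
    log_hyperbola = log_hyperbola_params,
    gs_stop(paste0("unknown curve family: ", x$family), "gs_param_error")
  )
  do.call(ctor, as.list(x$params))
}
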