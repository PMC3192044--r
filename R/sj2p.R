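#' Smoothly-joining two-phase (SJ2P) growth model
#'
#' The SJ2P model describes lifetime growth of an animal with two distinct
#' growth phases — e.g. a macropod's pouch and post-pouch phases — as a
#' single curve: a Verhulst logistic up to the join age `j` (pouch vacation),
#' continuing as a Brody curve beyond it.  Six parameters are free:
#'
#' \describe{
#'   \item{C}{Brody adjustment parameter, `0 < C < 1`.}
#'   \item{K}{logistic span (mm).}
#'   \item{L0}{logistic core value at birth (mm), `0 < L0 < K`.}
#'   \item{k}{Brody maturing rate (per month).}
#'   \item{j}{join age (months; 1 month = 28 days).}
#'   \item{r}{logistic intrinsic growth rate (per month).}
#' }
#'
#' The remaining two parameters — the logistic lower-asymptote offset `A` and
#' the Brody mature asymptote `B` — are not free: they are determined by
#' requiring the two branches to agree in both value and slope at `age = j`,
#' so the composite curve is continuous and once-differentiable everywhere.
#'
#' @param C,K,L0,k,j,r Scalar free parameters, see Details.
#' @return `sj2p_free_params()` returns the validated free-parameter set
#'   (class `sj2p_free_params`).
#' @seealso [derive_joined()], [eval_sj2p()], [invert_sj2p()]
#' @export
sj2p_free_params <- function(C, K, L0, k, j, r) {
  check_scalar(C = C, K = K, L0 = L0, k = k, j = j, r = r)
  check_param(K > 0, "K must be > 0")
  check_param(L0 > 0 && L0 < K * (1 - 1e-9), "L0 must satisfy 0 < L0 < K")
  check_param(C > 0 && C < 1, "C must satisfy 0 < C < 1")
  check_param(k > 0, "k must be > 0")
  check_param(r > 0, "r must be > 0")
  check_param(j > 0, "j must be > 0")
  structure(list(C = C, K = K, L0 = L0, k = k, j = j, r = r),
            class = "sj2p_free_params")
}

#' Derive the smoothly-joined SJ2P model from its free parameters
#'
#' Solves the two continuity constraints for the derived parameters.  With
#' `core(t) = K*L0 / ((K - L0)*exp(-r*t) + L0)` and `s = d core/dt` at
#' `t = j` (which does not involve `A`), slope continuity with the Brody
#' branch `B*(1 - C*exp(-k*t))` gives
#' `B = s * exp(k*j) / (C*k)`, and value continuity then gives
#' `A = B*(1 - C*exp(-k*j)) - core(j)`.  The system is triangular, so both
#' derived parameters are closed-form.
#'
#' @param free An [sj2p_free_params()] object.
#' @return An object of class `sj2p_model`: list with elements `free`, `A`
#'   (derived logistic offset, mm) and `B` (derived Brody asymptote, mm).
#' @section Errors: if the logistic slope at `j` underflows to zero, or the
#'   implied asymptote `B` is non-positive, the join is infeasible and a
#'   join error is raised.
#' @examples
#' free <- sj2p_free_params(C = 0.57, K = 95.21, L0 = 1.22,
#'                          k = 0.078, j = 7.85, r = 0.78)
#' m <- derive_joined(free)
#' eval_sj2p(m, c(0, 7.85, 24))
#' @export
derive_joined <- function(free) {
  if (!inherits(free, "sj2p_free_params")) free <- do.call(sj2p_free_params, free)
  core_j <- logistic_core(free$K, free$L0, free$r, free$j)
  s <- free$r * core_j * (1 - core_j / free$K)
  if (!is.finite(s) || s <= 0) {
    gs_stop("infeasible join: logistic slope at j is not positive", "gs_join_error")
  }
  B <- s * exp(free$k * free$j) / (free$C * free$k)
  if (!is.finite(B) || B <= 0) {
    gs_stop("infeasible join: implied Brody asymptote is not positive",
            "gs_join_error")
  }
  A <- B * (1 - free$C * exp(-free$k * free$j)) - core_j
  structure(list(free = free, A = A, B = B), class = "sj2p_model")
}

#' Evaluate an SJ2P model
#'
#' Logistic branch `A + core(age)` for `age <= j`, Brody branch
#' `B*(1 - C*exp(-k*age))` for `age > j`.  By construction the composite is
#' continuous, once-differentiable and strictly increasing, bounded above by
#' the derived asymptote `B`.
#'
#' @param m An `sj2p_model` from [derive_joined()].
#' @param age Ages in months, `>= 0`.
#' @return Measurement (mm).
#' @export
eval_sj2p <- function(m, age) {
  stopifnot(inherits(m, "sj2p_model"))
  check_nonnegative_age(age)
  f <- m$free
  out <- numeric(length(age))
  pre <- age <= f$j
  out[pre] <- m$A + logistic_core(f$K, f$L0, f$r, age[pre])
  out[!pre] <- m$B * (1 - f$C * exp(-f$k * age[!pre]))
  out
}

#' Slope of an SJ2P model
#'
#' Analytic first derivative of the composite curve (mm per month).
#'
#' @inheritParams eval_sj2p
#' @return Slope (mm/month).
#' @export
slope_sj2p <- function(m, age) {
  stopifnot(inherits(m, "sj2p_model"))
  check_nonnegative_age(age)
  f <- m$free
  out <- numeric(length(age))
  pre <- age <= f$j
  core <- logistic_core(f$K, f$L0, f$r, age[pre])
  out[pre] <- f$r * core * (1 - core / f$K)
  out[!pre] <- m$B * f$C * f$k * exp(-f$k * age[!pre])
  out
}

#' Invert an SJ2P model: age from a measurement
#'
#' Inverse prediction — the practical ageing use of the model: given a
#' measurement (e.g. pes length in mm), return the unique age at which the
#' fitted curve attains it.  Uses derivative-free bisection on the bracket
#' `[0, j]` or `[j, j + 50/k]` chosen by comparing the measurement with the
#' curve value at the join, so the search is robust near the asymptote.
#'
#' @param m An `sj2p_model`.
#' @param value Measurement (mm); must lie in `[eval_sj2p(m, 0), B)` where
#'   `B` is the derived asymptote.
#' @param tol Absolute convergence tolerance on the measurement (mm).
#' @return Age in months.
#' @export
invert_sj2p <- function(m, value, tol = 1e-8) {
  stopifnot(inherits(m, "sj2p_model"))
  if (length(value) > 1L) {
    return(vapply(value, function(v) invert_sj2p(m, v, tol), numeric(1)))
  }
  f <- m$free
  at0 <- eval_sj2p(m, 0)
  if (!is.finite(value) || value < at0 || value >= m$B) {
    gs_stop(sprintf(
      "measurement %.6g mm outside invertible range [%.6g, %.6g)",
      value, at0, m$B
    ), "gs_range_error")
  }
  at_j <- eval_sj2p(m, f$j)
  if (value <= at_j) {
    lo <- 0; hi <- f$j
  } else {
    lo <- f$j; hi <- f$j + 50 / f$k
    # the Brody branch is within exp(-50) of its asymptote at hi, so any
    # admissible value is bracketed
  }
  root <- stats::uniroot(function(t) eval_sj2p(m, t) - value,
                         lower = lo, upper = hi, tol = 1e-12,
                         extendInt = "no")$root
  # polish with one bisection pass on the measurement scale if needed
  if (abs(eval_sj2p(m, root) - value) > tol) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (eval_sj2p(m, mid) < value) lo <- mid else hi <- mid
      if (abs(eval_sj2p(m, mid) - value) <= tol) break
    }
    root <- (lo + hi) / 2
  }
  root
}

#' @export
print.sj2p_model <- function(x, ...) {
  f <- x$free
  cat("<SJ2P growth model> logistic -> Brody, smooth join\n")
  cat(sprintf("  free:    C=%.4g K=%.4g L0=%.4g k=%.4g j=%.4g mo r=%.4g\n",
              f$C, f$K, f$L0, f$k, f$j, f$r))
  cat(sprintf("  derived: A=%.4g mm  B=%.4g mm (asymptote)\n", x$A, x$B))
  invisible(x)
}

#' Serialize an SJ2P model to/from JSON
#'
#' `{free:{C,K,L0,k,j,r}, derived:{A,B}, age_unit:"month28"}`.  On reading,
#' the derived parameters are recomputed from the free ones and checked
#' against the stored values.
#'
#' @param m An `sj2p_model`, or for `sj2p_from_json` a JSON string/list.
#' @return A JSON string, or an `sj2p_model`.
#' @export
sj2p_to_json <- function(m) {
  stopifnot(inherits(m, "sj2p_model"))
  jsonlite::toJSON(
    list(free = unclass(m$free)[], derived = list(A = m$A, B = m$B),
         age_unit = "month28"),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname sj2p_to_json
#' @export
sj2p_from_json <- function(m) {
  x <- if (is.character(m)) jsonlite::fromJSON(m) else m
  mod <- derive_joined(do.call(sj2p_free_params, as.list(x$free)))
  if (!is.null(x$derived)) {
    ok <- isTRUE(all.equal(c(x$derived$A, x$derived$B), c(mod$A, mod$B),
                           tolerance = 1e-6))
    if (!ok) gs_stop("stored derived parameters disagree with the join solve",
                     "gs_format_error")
  }
  mod
}
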