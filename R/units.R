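#' Age unit conversions
#'
#' The package's canonical internal age unit is the month, defined as exactly
#' 28 days.  Pouch-young ages are usually recorded in days, join ages and
#' post-pouch ages in months; these helpers convert between the two exactly.
#'
#' @param age_months,age_days Numeric vector of non-negative ages.
#' @return Numeric vector of converted ages.
#' @examples
#' months_to_days(7.86)   # 220.08
#' days_to_months(207)    # 7.392857...
#' @export
months_to_days <- function(age_months) {
  check_nonnegative_age(age_months)
  age_months * DAYS_PER_MONTH
}

#' @rdname months_to_days
#' @export
days_to_months <- function(age_days) {
  check_nonnegative_age(age_days)
  age_days / DAYS_PER_MONTH
}

DAYS_PER_MONTH <- 28

check_nonnegative_age <- function(age) {
  if (!is.numeric(age) || anyNA(age) || any(age < 0)) {
    gs_stop("ages must be non-negative numbers", "gs_domain_error")
  }
  invisible(age)
}

# Structured condition helper; `class` selects the error family used by the
# CLI to pick exit codes.
gs_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gs_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
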