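#' Goodness-of-fit summary
#'
#' Sum-of-squares based fit statistics for a set of observations and model
#' predictions.  SST measures how far the observations are from their mean,
#' SSE how far they are from the predictions; `r2 = 1 - SSE/SST`,
#' `r2_adjusted = 1 - (1 - r2)*(n - 1)/(n - p - 1)` and
#' `rmse = sqrt(SSE/n)` (divisor `n`, i.e. the biased standard deviation of
#' the residuals; the divisor is recorded in the summary so comparisons are
#' explicit).  RMSE is in the units of the response.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param p Number of free model parameters; must satisfy `n > p + 1`.
#' @return A `gof_summary`: list with `n`, `p`, `sst`, `sse`, `r2`,
#'   `r2_adjusted`, `rmse`, `rmse_divisor`, and `constant_response` flag
#'   (when SST is zero, `r2` is undefined and returned as `NA`).
#' @examples
#' gof(c(10, 20), c(7, 24), p = 0)$rmse  # sqrt(12.5)
#' @export
gof <- function(observed, predicted, p) {
  if (length(observed) != length(predicted)) {
    gs_stop("observed and predicted must have equal length", "gs_data_error")
  }
  n <- length(observed)
  if (n <= p + 1) {
    gs_stop("need n > p + 1 observations for a goodness-of-fit summary",
            "gs_data_error")
  }
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  constant <- sst == 0
  r2 <- if (constant) NA_real_ else 1 - sse / sst
  r2_adj <- if (constant) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(
    list(n = n, p = p, sst = sst, sse = sse, r2 = r2, r2_adjusted = r2_adj,
         rmse = sqrt(sse / n), rmse_divisor = "n",
         constant_response = constant),
    class = "gof_summary"
  )
}

#' Per-phase goodness of fit for an SJ2P model
#'
#' Because post-pouch measurements are far more variable than pouch-phase
#' ones, pooled fit statistics are misleading; they are therefore computed
#' separately for the two growth phases.  Records are partitioned by the
#' model's own join age: `age <= j` is the pouch side (a record at exactly
#' `j` goes to the pouch side), `age > j` the post-pouch side.
#'
#' @param data A morph-record data frame (see [morph_records()]) with known
#'   ages in months.
#' @param model An `sj2p_model`.
#' @param p Free-parameter count charged to each phase's adjusted R².
#' @return List with elements `pouch` and `post`: each a [gof()] summary, or
#'   `NULL` if that side has no usable records (an empty side is reported as
#'   absent, never fabricated).
#' @export
gof_by_phase <- function(data, model, p) {
  stopifnot(inherits(model, "sj2p_model"))
  data <- morph_records(data)
  data <- data[!is.na(data$age_months), , drop = FALSE]
  if (nrow(data) == 0) gs_stop("no records with known age", "gs_data_error")
  j <- model$free$j
  side <- function(rows) {
    if (nrow(rows) <= p + 1) return(NULL)
    gof(rows$value_mm, eval_sj2p(model, rows$age_months), p)
  }
  list(
    pouch = side(data[data$age_months <= j, , drop = FALSE]),
    post = side(data[data$age_months > j, , drop = FALSE])
  )
}

#' @export
print.gof_summary <- function(x, ...) {
  cat(sprintf("n=%d p=%d  r2=%.4f adj=%.4f  rmse=%.4f (SSE/%s)\n",
              x$n, x$p, x$r2, x$r2_adjusted, x$rmse, x$rmse_divisor))
  invisible(x)
}
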