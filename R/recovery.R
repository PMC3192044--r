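#' Parameter-recovery simulation study
#'
#' Repeatedly simulates a dataset from a [sim_config()] and refits it,
#' collecting the per-replicate parameter estimates.  This is the standard
#' check that the fitting machinery returns the generating parameters on
#' average under a given study design, and the basis of the package's
#' stochastic validation: for each free parameter the replicate mean should
#' sit within Monte-Carlo error of the truth.
#'
#' Replicate `i` uses simulation seed `seed + i`; the fit configuration's
#' own seed (start jitter) is held fixed, so the whole study is reproducible
#' from `seed`.  A replicate whose fit fails outright is recorded as a row
#' of `NA`s with `converged = FALSE`, never dropped silently.
#'
#' @param sim_cfg A [sim_config()] describing the generating truth/design.
#' @param fit_cfg A [fit_config()]; its `family` selects the fitter.
#' @param n_reps Number of replicates.
#' @param seed Base integer seed for the replicate simulations.
#' @return A data frame with one row per replicate: the estimate columns for
#'   the family, plus `rss` and `converged`.
#' @examples
#' \donttest{
#' sc <- default_scenarios()$male_pp_brody
#' st <- recovery_study(sc, fit_config("brody", seed = 1), n_reps = 20, seed = 7)
#' colMeans(st[st$converged, c("B", "C", "k")])
#' }
#' @export
recovery_study <- function(sim_cfg, fit_cfg, n_reps, seed = 1L) {
  stopifnot(inherits(sim_cfg, "sim_config"), inherits(fit_cfg, "fit_config"))
  seed <- as.integer(seed)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- sim_cfg
    cfg_i$seed <- seed + i
    res <- tryCatch({
      d <- simulate_cross_sectional(cfg_i)
      fit_curve(d, fit_cfg)
    }, gs_error = function(e) NULL)
    if (is.null(res) || length(res$estimates) == 0) {
      rows[[i]] <- data.frame(rss = NA_real_, converged = FALSE)
    } else {
      rows[[i]] <- data.frame(as.list(unlist(res$estimates)),
                              rss = res$rss, converged = res$converged)
    }
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nm, names(r))) r[[m]] <- NA_real_
    r[nm]
  })
  do.call(rbind, rows)
}

#' Monte-Carlo summary of a recovery study
#'
#' Mean, Monte-Carlo standard error of the mean, and replicate count for one
#' estimate column of a [recovery_study()] result, restricted to converged
#' replicates.
#'
#' @param study A [recovery_study()] data frame.
#' @param param Column name.
#' @return List with `mean`, `mc_se`, `n`.
#' @export
recovery_summary <- function(study, param) {
  x <- study[[param]][study$converged & !is.na(study[[param]])]
  if (length(x) == 0) gs_stop("no converged replicates", "gs_data_error")
  list(mean = mean(x), mc_se = stats::sd(x) / sqrt(length(x)), n = length(x))
}
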