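# Visual predictive checks: simulated prediction percentiles with residual
# error over the observed covariate grid.  The model has no between-subject
# variability, so VPC variability is residual-only and the bands admit a
# closed-form lognormal cross-check: median = CL_pred, 2.5th/97.5th
# percentiles = CL_pred * exp(-/+ 1.96 * sigma).

#' Simulate visual-predictive-check bands
#'
#' For each record's covariates, draws `n_sim` replicates
#' `CL_pred * exp(eps)`, `eps ~ N(0, sigma2_hat)`, and takes the 2.5th,
#' 50th and 97.5th percentiles.  No binning: bands are computed at every
#' observed covariate point.  Deterministic under `seed`.
#'
#' @param fit a converged `cl_fit`.
#' @param records covariate/observation data frame (default: the fitted
#'   records).
#' @param n_sim simulation replicates per point (minimum 40; percentile
#'   estimates are unstable below that).
#' @param seed integer seed.
#' @return object of class `cl_vpc`: data frame with `wt`, `pna`, `pma`
#'   (as available), `cl_obs`, `pred`, `lo`, `med`, `hi`, plus attributes
#'   `n_sim` and `seed`.
#' @export
simulate_vpc <- function(fit, records = NULL, n_sim = 1000, seed = 1) {
  stopifnot(inherits(fit, "cl_fit"), fit$converged)
  if (n_sim < 40) stop("n_sim must be >= 40 for stable percentile bands",
                       call. = FALSE)
  if (is.null(records)) records <- fit$records
  stopifnot(nrow(records) > 0)
  pred <- evaluate_cl(fit$model, fit$theta, records)
  sims <- simulate(fit, nsim = n_sim, seed = seed, newdata = records)
  qs <- t(apply(sims, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE, type = 7))
  out <- data.frame(wt = records$wt,
                    pna = if ("pna" %in% names(records)) records$pna else NA,
                    pma = if ("pma" %in% names(records)) records$pma else NA,
                    cl_obs = if ("cl" %in% names(records)) records$cl else NA,
                    pred = as.numeric(pred),
                    lo = qs[, 1], med = qs[, 2], hi = qs[, 3])
  structure(out, class = c("cl_vpc", "data.frame"),
            n_sim = n_sim, seed = seed, model_id = fit$model$id)
}

#' Export VPC plot data
#'
#' Tidy table of axis value, observed clearance and band values, optionally
#' log10-transformed on both axes (the log-log view spreads out the
#' neonatal weight range).  Non-positive values that cannot be
#' log-transformed are flagged rather than dropped.
#'
#' @param bands a `cl_vpc`.
#' @param log_log apply log10 to weight and all clearance columns.
#' @return data frame with columns `wt`, `cl_obs`, `pred`, `lo`, `med`,
#'   `hi` and (when `log_log`) `flagged_nonpositive`.
#' @export
vpc_plotdata <- function(bands, log_log = FALSE) {
  stopifnot(inherits(bands, "cl_vpc"))
  out <- as.data.frame(bands)[c("wt", "cl_obs", "pred", "lo", "med", "hi")]
  if (log_log) {
    num <- c("wt", "cl_obs", "pred", "lo", "med", "hi")
    flagged <- rowSums(sapply(out[num], function(v) !is.na(v) & v <= 0)) > 0
    for (cc in num) out[[cc]] <- ifelse(out[[cc]] > 0, log10(out[[cc]]),
                                        NA_real_)
    out$flagged_nonpositive <- flagged
  }
  out
}

#' Plot VPC bands with observations
#'
#' @param x a `cl_vpc`.
#' @param log_log log-log axes (default TRUE).
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cl_vpc <- function(x, log_log = TRUE, xlab = "body weight (kg)",
                        ylab = "clearance (L/h)",
                        main = paste("VPC, model", attr(x, "model_id")),
                        ...) {
  d <- as.data.frame(x)
  d <- d[order(d$wt), ]
  lg <- if (log_log) "xy" else ""
  keep <- if (log_log) d$cl_obs > 0 & d$lo > 0 else rep(TRUE, nrow(d))
  graphics::plot(d$wt[keep], d$cl_obs[keep], log = lg, pch = 1,
                 col = "grey50", xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(d$wt, d$med, col = "blue", lwd = 2)
  graphics::lines(d$wt, d$lo, col = "blue", lty = 3)
  graphics::lines(d$wt, d$hi, col = "blue", lty = 3)
  invisible(x)
}
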