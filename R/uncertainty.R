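# Parametric-uncertainty simulation of typical clearance and steady-state
# dose-rate prediction.

#' Reference individuals for typical-clearance reporting
#'
#' The four archetypes used throughout: a 1-day-old term neonate (3.5 kg),
#' a 1-year-old infant (9 kg), a 5-year-old child (18 kg) and a 12-year-old
#' adolescent (39 kg).  PMA assumes term gestation (40 weeks plus postnatal
#' age in weeks).
#'
#' @return data frame with columns `label`, `pna` (years), `wt` (kg),
#'   `pma` (weeks).
#' @export
reference_children <- function() {
  pna <- c(1 / 365.25, 1, 5, 12)
  data.frame(label = c("neonate", "infant", "child", "adolescent"),
             pna = pna, wt = c(3.5, 9, 18, 39),
             pma = 40 + pna * WEEKS_PER_YEAR,
             stringsAsFactors = FALSE)
}

#' Sample parameter vectors from a fit's uncertainty
#'
#' Draws from the multivariate normal distribution of the estimates on the
#' estimation scale (log scale for positivity-constrained parameters, where
#' the covariance was computed), then back-transforms, so positivity
#' constraints survive sampling.  Deterministic under `seed`.
#'
#' @param fit a converged `cl_fit` with a usable covariance.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix `n` x (npar + 1); columns are the structural parameters
#'   (natural scale) and `sigma2`.
#' @export
sample_parameters <- function(fit, n = 1000, seed = 1) {
  stopifnot(inherits(fit, "cl_fit"), n >= 1)
  if (is.null(fit$cov_est))
    stop("fit has no usable covariance; refit or use an SE-only diagonal ",
         "covariance explicitly", call. = FALSE)
  tr <- fit$model$transform
  mu <- c(.to_est(fit$theta, tr), log(fit$sigma2))
  rng <- .local_rng(seed)
  draws <- MASS::mvrnorm(n, mu = mu, Sigma = fit$cov_est)
  .restore_rng(rng)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n)
  k <- fit$model$npar
  out <- draws
  for (j in seq_len(k)) if (tr[j] == "log") out[, j] <- exp(draws[, j])
  out[, k + 1] <- exp(draws[, k + 1])
  colnames(out) <- c(fit$model$par_names, "sigma2")
  out
}

#' Typical clearance with simulated 95% confidence interval
#'
#' Evaluates the model at each sampled parameter vector for one individual's
#' covariates.  The point value is the plug-in prediction at the estimates;
#' `median` is the simulated median reported alongside.  Draws giving
#' undefined or non-positive clearance (e.g. a negative base raised to a
#' fractional power when an uncertain parameter changes sign) are counted
#' invalid; when more than `invalid_threshold` of draws are invalid the
#' interval is declared not constructible, mirroring the reporting
#' behaviour of heavily parameterised exponent models.
#'
#' @param fit a converged `cl_fit`.
#' @param individual one-row data frame (`wt`, `pna`, `pma`) or a row of
#'   [reference_children()].
#' @param samples parameter matrix from [sample_parameters()]; drawn
#'   internally when `NULL`.
#' @param n,seed used when `samples` is `NULL` (defaults 1000, 1).
#' @param invalid_threshold maximum tolerated invalid-draw fraction
#'   (default 0.025: beyond that a 2.5th percentile is undefined).
#' @return list of class `cl_ci`: `point`, `median`, `lo`, `hi` (2.5th and
#'   97.5th percentiles, linear interpolation between order statistics),
#'   `n_valid`, `n_total`, `constructible`.
#' @export
typical_cl_ci <- function(fit, individual, samples = NULL, n = 1000,
                          seed = 1, invalid_threshold = 0.025) {
  stopifnot(inherits(fit, "cl_fit"))
  individual <- as.data.frame(individual)
  stopifnot(nrow(individual) == 1)
  if (is.null(samples)) samples <- sample_parameters(fit, n = n, seed = seed)
  k <- fit$model$npar
  point <- unname(evaluate_cl(fit$model, fit$theta, individual))
  cv <- .get_covariates(fit$model, individual)
  vals <- suppressWarnings(apply(samples[, seq_len(k), drop = FALSE], 1,
                                 function(th)
                                   fit$model$predict(th, cv$wt, cv$pna,
                                                     cv$pma)))
  valid <- is.finite(vals) & vals > 0
  frac_invalid <- 1 - mean(valid)
  constructible <- frac_invalid <= invalid_threshold
  qs <- if (any(valid))
    stats::quantile(vals[valid], c(0.025, 0.5, 0.975), names = FALSE,
                    type = 7)
  else c(NA_real_, NA_real_, NA_real_)
  structure(list(point = point, median = qs[2],
                 lo = if (constructible) qs[1] else NA_real_,
                 hi = if (constructible) qs[3] else NA_real_,
                 n_valid = sum(valid), n_total = length(vals),
                 constructible = constructible),
            class = "cl_ci")
}

#' @export
print.cl_ci <- function(x, ...) {
  if (x$constructible)
    cat(sprintf("typical CL %.3g L/h (95%% CI %.3g, %.3g; simulated median %.3g)\n",
                x$point, x$lo, x$hi, x$median))
  else
    cat(sprintf("typical CL %.3g L/h (95%% CI not constructible: %d/%d draws invalid)\n",
                x$point, x$n_total - x$n_valid, x$n_total))
  invisible(x)
}

#' Typical-clearance table over fitted models and reference individuals
#'
#' @param fits named list of `cl_fit` objects.
#' @param individuals data frame of individuals (default
#'   [reference_children()]).
#' @param n,seed simulation size and seed per model.
#' @return data frame: `model`, `group`, `point`, `median`, `lo`, `hi`,
#'   `constructible`.
#' @export
typical_cl_table <- function(fits, individuals = reference_children(),
                             n = 1000, seed = 1) {
  rows <- list()
  for (id in names(fits)) {
    fit <- fits[[id]]
    if (!fit$converged || is.null(fit$cov_est)) next
    samples <- sample_parameters(fit, n = n, seed = seed)
    for (i in seq_len(nrow(individuals))) {
      ci <- typical_cl_ci(fit, individuals[i, , drop = FALSE],
                          samples = samples)
      rows[[length(rows) + 1]] <-
        data.frame(model = id, group = individuals$label[i],
                   point = ci$point, median = ci$median,
                   lo = ci$lo, hi = ci$hi,
                   constructible = ci$constructible,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steady-state infusion dose rate from clearance
#'
#' At steady state the infusion rate balancing elimination is
#' `CL * Css`; scaled by body weight this gives the weight-normalised dose
#' rate `CL * Css / WT` in ug/kg/h (with `Css` in ug/L and `CL` in L/h).
#'
#' @param cl clearance, L/h (>= 0).
#' @param css_target target steady-state concentration, ug/L (default 250,
#'   the lower end of the midazolam sedation target).
#' @param wt body weight, kg (> 0).
#' @param round_result round to the nearest integer for reporting
#'   (default TRUE).
#' @return dose rate, ug/kg/h.
#' @examples
#' dose_rate(7.02, 250, 9)   # 195
#' dose_rate(0.62, 250, 3.5) # 44
#' @export
dose_rate <- function(cl, css_target = 250, wt, round_result = TRUE) {
  stopifnot(all(cl >= 0), all(css_target > 0), all(wt > 0))
  d <- cl * css_target / wt
  if (round_result) round(d) else d
}

#' Round a dose rate to the clinical titration step
#'
#' Neonatal midazolam infusions are titrated in 25 ug/kg/h steps, older
#' children in 50 ug/kg/h steps; an exact midpoint rounds up.
#'
#' @param dose dose rate, ug/kg/h (>= 0).
#' @param group age-group label(s) (`"neonate"` uses the 25 step).
#' @return dose rounded to the nearest titration multiple.
#' @examples
#' round_to_titration(44, "neonate")  # 50
#' round_to_titration(195, "infant")  # 200
#' @export
round_to_titration <- function(dose, group) {
  stopifnot(all(dose >= 0))
  step <- ifelse(as.character(group) == "neonate", 25, 50)
  floor(dose / step + 0.5) * step
}

#' Dose-rate report over a typical-clearance table
#'
#' @param cl_table output of [typical_cl_table()] (or any data frame with
#'   `model`, `group`, `point`).
#' @param css_target target concentration, ug/L.
#' @param individuals individuals supplying weights per group (default
#'   [reference_children()]).
#' @return data frame with raw and titration-rounded dose-rate columns.
#' @export
dose_table <- function(cl_table, css_target = 250,
                       individuals = reference_children()) {
  wt <- individuals$wt[match(cl_table$group, individuals$label)]
  out <- cl_table[c("model", "group", "point")]
  out$dose <- dose_rate(cl_table$point, css_target, wt)
  out$dose_titrated <- round_to_titration(out$dose, cl_table$group)
  out
}
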