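# Maximum-likelihood fitting under the exponential (log-normal) residual
# error model  CL_obs = CL_pred * exp(eps),  eps ~ N(0, sigma2).
#
# Estimation is on a transformed scale: positivity-constrained structural
# parameters and sigma2 are log-transformed, genuinely sign-free parameters
# (linear slopes, the weight exponent of the exponent in model 16) stay
# untransformed.  -2LL includes the full log-density constant log(2*pi);
# constants cancel in every AIC difference.

.SIGMA2_FLOOR <- 1e-12

# transform helpers: estimation scale <-> natural scale
.to_est <- function(x, tr) ifelse(tr == "log", log(x), x)
.to_nat <- function(x, tr) ifelse(tr == "log", exp(x), x)

#' -2 log-likelihood of a model on clearance records
#'
#' Computes
#' \deqn{-2LL = \sum_i \log(2\pi) + \log\sigma^2 +
#'   (\log CL_{obs,i} - \log CL_{pred,i})^2 / \sigma^2}
#' under the exponential residual error model.  Parameter points at which
#' any structural prediction is non-positive (possible for the linear
#' maturation structures on preterm covariates) score `Inf`, so the
#' optimiser rejects them rather than the evaluation raising an error.
#'
#' @param model a `cl_model` or model id.
#' @param theta structural parameter vector.
#' @param sigma2 residual variance on the log scale (> 0).
#' @param records canonical records data frame with column `cl` and the
#'   model's covariates.
#' @return scalar -2LL (possibly `Inf`).
#' @export
neg2ll <- function(model, theta, sigma2, records) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  stopifnot(sigma2 > 0, all(records$cl > 0))
  contrib <- neg2ll_contributions(model, theta, sigma2, records)
  sum(contrib)
}

# per-record -2LL contributions (used for the age-group decomposition)
neg2ll_contributions <- function(model, theta, sigma2, records) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  cv <- .get_covariates(model, records)
  pred <- model$predict(theta, cv$wt, cv$pna, cv$pma)
  out <- rep(Inf, nrow(records))
  ok <- is.finite(pred) & pred > 0
  res <- log(records$cl[ok]) - log(pred[ok])
  out[ok] <- log(2 * pi) + log(sigma2) + res^2 / sigma2
  out
}

# objective in estimation scale; x = (transformed theta, log sigma2)
.make_objective <- function(model, records) {
  tr <- model$transform
  function(x) {
    theta <- .to_nat(x[seq_len(model$npar)], tr)
    sigma2 <- exp(x[model$npar + 1])
    if (!all(is.finite(theta)) || !is.finite(sigma2)) return(Inf)
    v <- neg2ll(model, theta, sigma2, records)
    if (!is.finite(v)) Inf else v
  }
}

# central finite-difference Hessian, relative step `rel`, halving the step
# for rows/cols that come out non-finite
.fd_hessian <- function(f, x, rel = 1e-4, max_halvings = 6) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  h0 <- rel * pmax(abs(x), 1)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      h <- c(h0[i], h0[j])
      for (try in 0:max_halvings) {
        if (i == j) {
          xp <- x; xp[i] <- x[i] + h[1]
          xm <- x; xm[i] <- x[i] - h[1]
          val <- (f(xp) - 2 * f0 + f(xm)) / h[1]^2
        } else {
          xpp <- x; xpp[i] <- x[i] + h[1]; xpp[j] <- x[j] + h[2]
          xpm <- x; xpm[i] <- x[i] + h[1]; xpm[j] <- x[j] - h[2]
          xmp <- x; xmp[i] <- x[i] - h[1]; xmp[j] <- x[j] + h[2]
          xmm <- x; xmm[i] <- x[i] - h[1]; xmm[j] <- x[j] - h[2]
          val <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[1] * h[2])
        }
        if (is.finite(val)) break
        h <- h / 2
      }
      H[i, j] <- H[j, i] <- val
    }
  }
  H
}

# data-driven starting value for CL70: back-allometrise observed CL with
# exponent 0.75 and take the typical value among the most mature records
.start_cl70 <- function(records) {
  ratio <- records$cl / (records$wt / 70)^0.75
  mature <- !is.na(records$pna) & records$pna >= 2
  stats::median(if (any(mature)) ratio[mature] else ratio)
}

#' Fit a clearance-scaling model by maximum likelihood
#'
#' Jointly minimises [neg2ll()] over the structural parameters and the
#' residual variance, using multistart `nlminb` on the transformed
#' (positivity-enforcing) scale.  Standard errors come from the numerical
#' Hessian of -2LL at the optimum: the covariance of the estimates is
#' `2 * solve(H)` on the estimation scale, delta-method-transformed to the
#' natural scale for reporting.  A non-invertible Hessian yields a
#' converged fit with `se` marked unavailable rather than an error.
#'
#' @param records canonical records data frame (columns `cl`, `wt` and the
#'   model's age covariates; see [read_cl_data()] / [simulate_cl_study()]).
#' @param model model id or `cl_model` (default `"1"`, the standard model).
#' @param n_starts number of multistart launches (default 20).  Starts are
#'   the catalogue defaults (with a data-driven CL70) jittered by
#'   U(0.5, 2) multiplicatively on positive parameters and +/-0.5
#'   additively on unconstrained ones.
#' @param seed integer seed making the jitter (and hence the fit)
#'   deterministic.
#' @param start optional named or positional structural start overriding the
#'   catalogue default.
#' @return object of class `cl_fit`: list with `model`, `theta` (natural
#'   scale), `sigma2`, `se`, `se_sigma2`, `cov_est` (estimation-scale
#'   covariance over (theta, sigma2)), `cov_nat`, `transform`, `neg2ll`,
#'   `n`, `converged`, `n_starts_used`, `sigma2_boundary`, `records`.
#' @examples
#' set.seed(1)
#' dat <- simulate_cl_study(cl_study_config(n_per_group = c(
#'   neonate = 10, infant = 5, child = 5, adolescent = 5, adult = 5)))
#' fit <- fit_cl(dat, model = "1", n_starts = 5)
#' coef(fit)
#' @export
fit_cl <- function(records, model = "1", n_starts = 20, seed = 1,
                   start = NULL) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  stopifnot(is.data.frame(records), nrow(records) >= model$npar + 1,
            all(records$cl > 0))
  tr <- model$transform
  obj <- .make_objective(model, records)

  base_start <- model$start
  if (!is.null(start)) {
    stopifnot(length(start) == model$npar)
    base_start <- as.numeric(start)
  } else {
    base_start[1] <- .start_cl70(records)
  }
  x0 <- c(.to_est(base_start, tr), log(0.1))

  rng <- .local_rng(seed)
  starts <- list(x0)
  k <- length(x0)
  for (s in seq_len(max(0, n_starts - 1))) {
    jit <- x0
    mult <- c(tr == "log", TRUE)   # sigma2 is log-transformed too
    jit[mult] <- jit[mult] + log(stats::runif(sum(mult), 0.5, 2))
    jit[!mult] <- jit[!mult] + stats::runif(sum(!mult), -0.5, 0.5)
    starts[[s + 1]] <- jit
  }
  .restore_rng(rng)

  best <- NULL
  n_ok <- 0L
  for (x in starts) {
    res <- tryCatch(stats::nlminb(x, obj,
                                  control = list(iter.max = 500,
                                                 eval.max = 1000)),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  if (is.null(best)) {
    return(structure(list(model = model, theta = rep(NA_real_, model$npar),
                          sigma2 = NA_real_, se = NULL, se_sigma2 = NA_real_,
                          cov_est = NULL, cov_nat = NULL, transform = tr,
                          neg2ll = Inf, n = nrow(records), converged = FALSE,
                          n_starts_used = length(starts),
                          sigma2_boundary = FALSE, records = records),
                     class = "cl_fit"))
  }

  xhat <- best$par
  theta <- .to_nat(xhat[seq_len(model$npar)], tr)
  sigma2 <- exp(xhat[model$npar + 1])
  sigma2_boundary <- sigma2 < .SIGMA2_FLOOR
  if (sigma2_boundary) {
    sigma2 <- .SIGMA2_FLOOR
    xhat[model$npar + 1] <- log(sigma2)
  }

  # covariance: 2 * H^-1 on the estimation scale, delta-method to natural
  cov_est <- cov_nat <- NULL
  se <- rep(NA_real_, model$npar)
  se_sigma2 <- NA_real_
  if (!sigma2_boundary) {
    H <- .fd_hessian(obj, xhat)
    cov_try <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_try) && all(is.finite(cov_try)) &&
        all(diag(cov_try) > 0)) {
      cov_est <- cov_try
      jac <- c(ifelse(tr == "log", theta, 1), sigma2)  # d natural / d est
      cov_nat <- cov_est * tcrossprod(jac)
      se <- sqrt(diag(cov_nat))[seq_len(model$npar)]
      se_sigma2 <- sqrt(diag(cov_nat))[model$npar + 1]
    }
  }

  nm <- c(model$par_names, "sigma2")
  if (!is.null(cov_est)) dimnames(cov_est) <- list(nm, nm)
  if (!is.null(cov_nat)) dimnames(cov_nat) <- list(nm, nm)
  names(theta) <- model$par_names
  names(se) <- model$par_names

  structure(list(model = model, theta = theta, sigma2 = sigma2,
                 se = se, se_sigma2 = se_sigma2,
                 cov_est = cov_est, cov_nat = cov_nat, transform = tr,
                 neg2ll = best$objective, n = nrow(records),
                 converged = best$convergence == 0 || is.finite(best$objective),
                 n_starts_used = n_ok, sigma2_boundary = sigma2_boundary,
                 records = records),
            class = "cl_fit")
}

# run code under a locally seeded RNG, restoring the caller's state
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Akaike information criterion of a fit
#'
#' `AIC = -2LL + 2p`.  The parameter count `p` includes the residual
#' variance by default (`"structural+ruv"`); the `"structural"` convention
#' counts only the structural parameters, mirroring reports that quote the
#' standard model as a three-parameter model.  Differences between models
#' are identical under either convention applied uniformly.
#'
#' @param fit a `cl_fit`.
#' @param convention `"structural+ruv"` (default) or `"structural"`.
#' @return scalar AIC.
#' @export
cl_aic <- function(fit, convention = c("structural+ruv", "structural")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "cl_fit"))
  p <- fit$model$npar + (convention == "structural+ruv")
  fit$neg2ll + 2 * p
}

#' Age-group decomposition of a fit's AIC
#'
#' Splits the global -2LL into the sum of per-record contributions at the
#' global parameter estimates, grouped by [assign_age_group()], and adds
#' `2p` to each group's term.  Groups with no records are omitted.  The
#' per-group -2LL values sum to the global -2LL exactly.
#'
#' @inheritParams cl_aic
#' @return named numeric vector of per-group AIC-style values, with
#'   attribute `"neg2ll"` (the per-group -2LL values).
#' @export
aic_by_age_group <- function(fit, convention = c("structural+ruv",
                                                 "structural")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fit, "cl_fit"), fit$converged)
  contrib <- neg2ll_contributions(fit$model, fit$theta, fit$sigma2,
                                  fit$records)
  grp <- assign_age_group(fit$records$pna)
  by_grp <- tapply(contrib, grp, sum)
  by_grp <- by_grp[!is.na(by_grp)]
  p <- fit$model$npar + (convention == "structural+ruv")
  out <- by_grp + 2 * p
  attr(out, "neg2ll") <- by_grp
  out
}

#' Fit several models to the same records
#'
#' @param records canonical records data frame.
#' @param models character vector of model ids (default: full catalogue).
#' @param ... passed to [fit_cl()].
#' @return named list of `cl_fit` objects; models that fail to fit are kept
#'   as non-converged results and reported with a message.
#' @export
fit_all_models <- function(records, models = cl_model_ids(), ...) {
  fits <- lapply(models, function(id) {
    f <- tryCatch(fit_cl(records, model = id, ...),
                  error = function(e) {
                    message("model ", id, " failed: ", conditionMessage(e))
                    NULL
                  })
    f
  })
  names(fits) <- models
  fits[!vapply(fits, is.null, logical(1))]
}

#' Global and per-age-group AIC differences relative to a reference model
#'
#' For each fitted model, `dAIC = AIC(model) - AIC(reference)` globally and
#' within each age group (per-group -2LL at the global estimates plus `2p`).
#' Negative values indicate a better fit than the reference.  All fits must
#' be on the identical record set.
#'
#' @param fits named list of `cl_fit` objects (as from [fit_all_models()]).
#' @param reference id of the reference model (default `"1"`).
#' @return data frame: `model`, `dAIC` (global) and one column per age
#'   group present in the data.
#' @export
delta_aic_table <- function(fits, reference = "1") {
  reference <- as.character(reference)
  stopifnot(reference %in% names(fits))
  n0 <- fits[[reference]]$n
  same <- vapply(fits, function(f)
    f$n == n0 && isTRUE(all.equal(f$records$cl, fits[[reference]]$records$cl)),
    logical(1))
  if (!all(same))
    stop("all fits must be on identical records", call. = FALSE)
  ref_g <- cl_aic(fits[[reference]])
  ref_by <- aic_by_age_group(fits[[reference]])
  groups <- names(ref_by)
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    by <- aic_by_age_group(f)
    row <- data.frame(model = id, dAIC = cl_aic(f) - ref_g,
                      stringsAsFactors = FALSE)
    for (g in groups) row[[g]] <- unname(by[g] - ref_by[g])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fit to JSON
#'
#' Full-precision JSON dump of the estimates, standard errors, covariance,
#' -2LL/AIC and metadata of a fit.
#'
#' @param fit a `cl_fit`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cl_fit"))
  obj <- list(model_id = fit$model$id, theta = as.list(fit$theta),
              sigma2 = fit$sigma2, se = as.list(fit$se),
              se_sigma2 = fit$se_sigma2,
              cov_est = fit$cov_est, cov_nat = fit$cov_nat,
              neg2ll = fit$neg2ll, aic = cl_aic(fit), n = fit$n,
              converged = fit$converged, n_starts_used = fit$n_starts_used,
              sigma2_boundary = fit$sigma2_boundary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.cl_fit <- function(x, ...) {
  cat("Clearance model fit (model ", x$model$id, ": ", x$model$name, ")\n",
      sep = "")
  cat("  ", x$model$equation, "\n", sep = "")
  if (!x$converged) {
    cat("  DID NOT CONVERGE (", x$n_starts_used, " usable starts)\n",
        sep = "")
    return(invisible(x))
  }
  est <- c(x$theta, sigma2 = x$sigma2)
  se <- c(x$se, x$se_sigma2)
  cat("  n = ", x$n, " records,  -2LL = ", format(x$neg2ll, digits = 6),
      ",  AIC = ", format(cl_aic(x), digits = 6), "\n", sep = "")
  tab <- data.frame(estimate = signif(est, 4),
                    se = signif(se, 3))
  print(tab)
  if (x$sigma2_boundary)
    cat("  note: residual variance at boundary (near-perfect fit)\n")
  invisible(x)
}

#' @export
coef.cl_fit <- function(object, ...) object$theta

#' @export
vcov.cl_fit <- function(object, ...) {
  if (is.null(object$cov_nat)) stop("covariance unavailable", call. = FALSE)
  object$cov_nat
}

#' @export
logLik.cl_fit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = object$model$npar + 1,
            nobs = object$n, class = "logLik")
}

#' @export
summary.cl_fit <- function(object, ...) {
  by_grp <- if (object$converged) aic_by_age_group(object) else NULL
  structure(list(fit = object, by_group = by_grp), class = "summary.cl_fit")
}

#' @export
print.summary.cl_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$by_group)) {
    cat("\n  -2LL by age group (at global estimates):\n")
    print(signif(attr(x$by_group, "neg2ll"), 5))
  }
  invisible(x)
}

#' Predict typical clearance from a fit
#'
#' @param object a `cl_fit`.
#' @param newdata data frame of covariates (`wt`, and `pna`/`pma` as the
#'   model requires); default: the fitted records.
#' @param ... unused.
#' @return numeric vector of typical clearances, L/h.
#' @export
predict.cl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$records
  evaluate_cl(object$model, object$theta, newdata)
}

#' Log-scale residuals of a fit
#'
#' @param object a `cl_fit`.
#' @param ... unused.
#' @return `log(cl_obs) - log(cl_pred)` per record.
#' @export
residuals.cl_fit <- function(object, ...) {
  pred <- predict(object)
  log(object$records$cl) - log(pred)
}

#' Simulate observed clearances from a fit
#'
#' Draws `cl_pred * exp(eps)`, `eps ~ N(0, sigma2_hat)`, per record.
#'
#' @param object a `cl_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (deterministic draws; caller's RNG state is
#'   preserved).
#' @param newdata optional covariate data frame.
#' @param ... unused.
#' @return matrix (`nrow(newdata)` x `nsim`) of simulated clearances.
#' @export
simulate.cl_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (is.null(newdata)) newdata <- object$records
  pred <- evaluate_cl(object$model, object$theta, newdata)
  rng <- if (!is.null(seed)) .local_rng(seed) else NULL
  eps <- matrix(stats::rnorm(length(pred) * nsim, 0, sqrt(object$sigma2)),
                nrow = length(pred))
  if (!is.null(seed)) .restore_rng(rng)
  pred * exp(eps)
}

#' Plot a fit as a visual predictive check
#'
#' @param x a `cl_fit`.
#' @param n_sim simulation replicates for the bands.
#' @param seed simulation seed.
#' @param log_log plot on log-log axes (default TRUE, which aids the
#'   neonatal weight range).
#' @param ... passed to [plot.cl_vpc()].
#' @export
plot.cl_fit <- function(x, n_sim = 500, seed = 1, log_log = TRUE, ...) {
  bands <- simulate_vpc(x, n_sim = n_sim, seed = seed)
  plot(bands, log_log = log_log, ...)
}
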