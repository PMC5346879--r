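# Catalogue of structural clearance-scaling models.
#
# Every model predicts typical clearance (L/h) from body weight (kg) and,
# where it uses age, postnatal age PNA (years) or postmenstrual age PMA
# (weeks).  All models are normalised to a 70 kg adult so that theta1 is the
# typical clearance of a fully mature 70 kg individual.

# sigmoid-Emax (Hill) maturation: fraction of mature clearance at age x
.hill <- function(x, hill, x50) x^hill / (x50^hill + x^hill)

# weeks of PMA per year of PNA
WEEKS_PER_YEAR <- 365.25 / 7

#' Model catalogue entry
#'
#' Look up one of the 19 structural clearance-scaling models (models 1-18
#' plus variant 9b).  Each entry records the parameter roles, the fixed
#' constants of the structure, the covariates the model uses, and the
#' evaluable prediction function.
#'
#' Model families:
#' \itemize{
#'   \item 1: allometric weight^0.75 with sigmoid PMA maturation (the
#'     standard model); 3 parameters (CL70, Hill, PMA50).
#'   \item 2-4: pure size models, exponent estimated / fixed 0.75 / fixed 0.667.
#'   \item 5-8: size plus linear or exponential age terms.
#'   \item 9: standard model with estimated allometric exponent; 9b: all
#'     structure fixed to a glomerular-filtration maturation study
#'     (exponent 0.632, Hill 3.33, PMA50 55.4), only CL70 estimated.
#'   \item 10-12: asymptotic-exponential or PNA-driven sigmoid maturation.
#'   \item 13-15: stepwise allometric exponent by age band or weight band.
#'   \item 16-18: allometric exponent a continuous function of weight or age.
#' }
#'
#' @param id model identifier: one of `"1"`..`"18"` or `"9b"` (numeric 1-18
#'   accepted).
#' @return an object of class `cl_model`: a list with elements `id`, `name`,
#'   `equation` (display string), `npar` (estimated structural parameters,
#'   excluding residual variance), `par_names`, `fixed` (named numeric of
#'   fixed constants), `covariates` (subset of `"WT"`, `"PNA"`, `"PMA"`),
#'   `transform` (per-parameter estimation transform, `"log"` or `"identity"`),
#'   `start` (default starting values) and `predict(theta, wt, pna, pma)`.
#' @examples
#' m <- cl_model("1")
#' m$predict(c(5.97, 4.19, 45.1), wt = 3.5, pna = 1 / 365.25, pma = 40 + 1 / 7)
#' @export
cl_model <- function(id) {
  id <- as.character(id)
  if (!id %in% names(.cl_models))
    stop("unknown model id: ", id, call. = FALSE)
  .cl_models[[id]]
}

#' @export
print.cl_model <- function(x, ...) {
  cat("Clearance scaling model ", x$id, ": ", x$name, "\n", sep = "")
  cat("  ", x$equation, "\n", sep = "")
  cat("  parameters: ", paste(x$par_names, collapse = ", "),
      "  (", x$npar, " estimated)\n", sep = "")
  if (length(x$fixed))
    cat("  fixed constants: ",
        paste(names(x$fixed), signif(x$fixed, 4), sep = " = ", collapse = ", "),
        "\n", sep = "")
  cat("  covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.mk_model <- function(id, name, equation, par_names, fixed, covariates,
                      transform, start, predict, b = NULL, mat = NULL) {
  structure(list(id = id, name = name, equation = equation,
                 npar = length(par_names), par_names = par_names,
                 fixed = fixed, covariates = covariates,
                 transform = transform, start = start,
                 predict = predict, b = b, mat = mat),
            class = "cl_model")
}

# stepwise exponent schedules (age bands in years; weight bands in kg);
# boundary ties take the lower band, matching the printed "<=" inequalities
.b_step13 <- function(pna) {
  ifelse(pna <= 0.25, 1.2, ifelse(pna <= 2, 1.0, ifelse(pna <= 5, 0.9, 0.75)))
}
.b_step14 <- function(wt) ifelse(wt <= 9, 1.25, 0.76)

.cl_models <- local({
  m <- list()

  m[["1"]] <- .mk_model(
    "1", "allometric 0.75 + sigmoid PMA maturation (standard model)",
    "CL = th1*(WT/70)^0.75 * PMA^th2/(th3^th2 + PMA^th2)",
    c("CL70", "Hill", "PMA50"), c(b = 0.75), c("WT", "PMA"),
    c("log", "log", "log"), c(10, 3, 50),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 * .hill(pma, theta[2], theta[3]),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma) .hill(pma, theta[2], theta[3]))

  m[["2"]] <- .mk_model(
    "2", "allometric, estimated exponent",
    "CL = th1*(WT/70)^th2",
    c("CL70", "b"), numeric(), "WT",
    c("log", "log"), c(10, 0.75),
    function(theta, wt, pna, pma) theta[1] * (wt / 70)^theta[2],
    b = function(theta, wt, pna) rep_len(theta[2], length(wt)))

  m[["3"]] <- .mk_model(
    "3", "allometric, exponent fixed 0.75",
    "CL = th1*(WT/70)^0.75",
    "CL70", c(b = 0.75), "WT",
    "log", 10,
    function(theta, wt, pna, pma) theta[1] * (wt / 70)^0.75,
    b = function(theta, wt, pna) 0.75)

  m[["4"]] <- .mk_model(
    "4", "allometric, exponent fixed 0.667 (body surface area)",
    "CL = th1*(WT/70)^0.667",
    "CL70", c(b = 0.667), "WT",
    "log", 10,
    function(theta, wt, pna, pma) theta[1] * (wt / 70)^0.667,
    b = function(theta, wt, pna) 0.667)

  m[["5"]] <- .mk_model(
    "5", "allometric + multiplicative linear PNA",
    "CL = th1*(WT/70)^th2 * (1 + th3*PNA)",
    c("CL70", "b", "slope"), numeric(), c("WT", "PNA"),
    c("log", "log", "identity"), c(10, 0.75, 0.01),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^theta[2] * (1 + theta[3] * pna),
    b = function(theta, wt, pna) rep_len(theta[2], length(wt)),
    mat = function(theta, wt, pna, pma) 1 + theta[3] * pna)

  m[["6"]] <- .mk_model(
    "6", "allometric + additive linear PNA",
    "CL = th1*(WT/70)^th2 + th3*PNA",
    c("CL70", "b", "slope"), numeric(), c("WT", "PNA"),
    c("log", "log", "identity"), c(10, 0.75, 0.01),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^theta[2] + theta[3] * pna,
    b = function(theta, wt, pna) rep_len(theta[2], length(wt)),
    # multiplicative age factor relative to the pure size part, so that
    # CL = th1*(WT/70)^b * mat still holds for this additive structure
    mat = function(theta, wt, pna, pma)
      1 + theta[3] * pna / (theta[1] * (wt / 70)^theta[2]))

  m[["7"]] <- .mk_model(
    "7", "allometric 0.75 + linear PMA from term",
    "CL = th1*(WT/70)^0.75 * (1 + th2*(PMA - 40))",
    c("CL70", "slope"), c(b = 0.75, PMA_ref = 40), c("WT", "PMA"),
    c("log", "identity"), c(10, 0.01),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 * (1 + theta[2] * (pma - 40)),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma) 1 + theta[2] * (pma - 40))

  m[["8"]] <- .mk_model(
    "8", "allometric 0.75 + exponential PMA from term",
    "CL = th1*(WT/70)^0.75 * exp(th2*(PMA - 40))",
    c("CL70", "rate"), c(b = 0.75, PMA_ref = 40), c("WT", "PMA"),
    c("log", "identity"), c(10, 0.001),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 * exp(theta[2] * (pma - 40)),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma) exp(theta[2] * (pma - 40)))

  m[["9"]] <- .mk_model(
    "9", "estimated exponent + sigmoid PMA maturation",
    "CL = th1*(WT/70)^th2 * PMA^th3/(th4^th3 + PMA^th3)",
    c("CL70", "b", "Hill", "PMA50"), numeric(), c("WT", "PMA"),
    c("log", "log", "log", "log"), c(10, 0.75, 3, 50),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^theta[2] * .hill(pma, theta[3], theta[4]),
    b = function(theta, wt, pna) rep_len(theta[2], length(wt)),
    mat = function(theta, wt, pna, pma) .hill(pma, theta[3], theta[4]))

  m[["9b"]] <- .mk_model(
    "9b", "fixed GFR-maturation structure (exponent 0.632)",
    "CL = th1*(WT/70)^0.632 * PMA^3.33/(55.4^3.33 + PMA^3.33)",
    "CL70", c(b = 0.632, Hill = 3.33, PMA50 = 55.4), c("WT", "PMA"),
    "log", 10,
    function(theta, wt, pna, pma)
      m[["9"]]$predict(c(theta[1], 0.632, 3.33, 55.4), wt, pna, pma),
    b = function(theta, wt, pna) 0.632,
    mat = function(theta, wt, pna, pma) .hill(pma, 3.33, 55.4))

  m[["10"]] <- .mk_model(
    "10", "allometric 0.75 + asymptotic-exponential PMA maturation",
    "CL = th1*(WT/70)^0.75 * (1 - th2*exp(-(PMA - 40)*log(2)/th3))",
    c("CL70", "frac", "Thalf"), c(b = 0.75, PMA_ref = 40), c("WT", "PMA"),
    c("log", "log", "log"), c(10, 0.5, 20),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 *
        (1 - theta[2] * exp(-(pma - 40) * log(2) / theta[3])),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma)
      1 - theta[2] * exp(-(pma - 40) * log(2) / theta[3]))

  m[["11"]] <- .mk_model(
    "11", "allometric 0.75 + saturating-exponential PNA maturation",
    "CL = th1*(WT/70)^0.75 * (th2 + (1 - th2)*(1 - exp(-PNA*th3)))",
    c("CL70", "birth_frac", "rate"), c(b = 0.75), c("WT", "PNA"),
    c("log", "log", "log"), c(10, 0.2, 2),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 *
        (theta[2] + (1 - theta[2]) * (1 - exp(-pna * theta[3]))),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma)
      theta[2] + (1 - theta[2]) * (1 - exp(-pna * theta[3])))

  m[["12"]] <- .mk_model(
    "12", "allometric 0.75 + sigmoid PNA maturation with birth fraction",
    "CL = th1*(WT/70)^0.75 * (th4 + (1 - th4)*PNA^th2/(th3^th2 + PNA^th2))",
    c("CL70", "Hill", "PNA50", "birth_frac"), c(b = 0.75), c("WT", "PNA"),
    c("log", "log", "log", "log"), c(10, 1.5, 0.5, 0.2),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^0.75 *
        (theta[4] + (1 - theta[4]) * .hill(pna, theta[2], theta[3])),
    b = function(theta, wt, pna) 0.75,
    mat = function(theta, wt, pna, pma)
      theta[4] + (1 - theta[4]) * .hill(pna, theta[2], theta[3]))

  m[["13"]] <- .mk_model(
    "13", "stepwise exponent by age band",
    "CL = th1*(WT/70)^b; b = 1.2 (<=3 mo), 1.0 (>3 mo-2 y), 0.9 (>2-5 y), 0.75 (>5 y)",
    "CL70", c(b_0_3mo = 1.2, b_3mo_2y = 1.0, b_2_5y = 0.9, b_over5y = 0.75),
    c("WT", "PNA"),
    "log", 10,
    function(theta, wt, pna, pma) theta[1] * (wt / 70)^.b_step13(pna),
    b = function(theta, wt, pna) .b_step13(pna))

  m[["14"]] <- .mk_model(
    "14", "stepwise exponent by weight band",
    "CL = th1*(WT/70)^b; b = 1.25 (<=9 kg), 0.76 (>9 kg)",
    "CL70", c(b_le9kg = 1.25, b_gt9kg = 0.76), "WT",
    "log", 10,
    function(theta, wt, pna, pma) theta[1] * (wt / 70)^.b_step14(wt),
    b = function(theta, wt, pna) .b_step14(wt))

  m[["15"]] <- .mk_model(
    "15", "estimated two-band exponent, 16.5 kg cut",
    "CL = th1*(WT/70)^b; b = th2 (<=16.5 kg), th3 (>16.5 kg)",
    c("CL70", "b_low", "b_high"), c(wt_cut = 16.5), "WT",
    c("log", "log", "log"), c(10, 1.2, 1.0),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^ifelse(wt <= 16.5, theta[2], theta[3]),
    b = function(theta, wt, pna) ifelse(wt <= 16.5, theta[2], theta[3]))

  m[["16"]] <- .mk_model(
    "16", "exponent a power function of weight",
    "CL = th1*(WT/70)^b, b = th2*WT^th3",
    c("CL70", "b_coef", "b_exp"), numeric(), "WT",
    c("log", "log", "identity"), c(10, 1.2, -0.1),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^(theta[2] * wt^theta[3]),
    b = function(theta, wt, pna) theta[2] * wt^theta[3])

  m[["17"]] <- .mk_model(
    "17", "exponent a sigmoid function of weight",
    "CL = th1*(WT/70)^b, b = th3 - th5*WT^th2/(th4^th2 + WT^th2)",
    c("CL70", "Hill", "b_max", "WT50", "b_drop"), numeric(), "WT",
    c("log", "log", "log", "log", "log"), c(10, 1, 1.2, 15, 0.5),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^(theta[3] - theta[5] * .hill(wt, theta[2], theta[4])),
    b = function(theta, wt, pna)
      theta[3] - theta[5] * .hill(wt, theta[2], theta[4]))

  m[["18"]] <- .mk_model(
    "18", "exponent a sigmoid function of postnatal age",
    "CL = th1*(WT/70)^b, b = th3 - th5*PNA^th2/(th4^th2 + PNA^th2)",
    c("CL70", "Hill", "b_max", "PNA50", "b_drop"), numeric(), c("WT", "PNA"),
    c("log", "log", "log", "log", "log"), c(10, 1, 1.2, 2, 0.5),
    function(theta, wt, pna, pma)
      theta[1] * (wt / 70)^(theta[3] - theta[5] * .hill(pna, theta[2], theta[4])),
    b = function(theta, wt, pna)
      theta[3] - theta[5] * .hill(pna, theta[2], theta[4]))

  m
})

#' All model identifiers in the catalogue
#' @return character vector of model ids.
#' @export
cl_model_ids <- function() names(.cl_models)

.cov_cols <- c(WT = "wt", PNA = "pna", PMA = "pma")

# pull required covariate vectors out of `data`, erroring on missing ones
.get_covariates <- function(model, data) {
  need <- .cov_cols[model$covariates]
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("model ", model$id, " requires covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in need)
    if (anyNA(data[[cc]]))
      stop("model ", model$id, ": missing values in covariate '", cc, "'",
           call. = FALSE)
  list(wt = if ("wt" %in% names(data)) data$wt else NA_real_,
       pna = if ("pna" %in% names(data)) data$pna else NA_real_,
       pma = if ("pma" %in% names(data)) data$pma else NA_real_)
}

#' Evaluate typical clearance under a catalogue model
#'
#' Computes the structural (noise-free) clearance prediction for each row of
#' `data`.  Linear maturation structures (models 6 and 7) can predict
#' non-positive clearance for very preterm covariates; such values are
#' returned as-is with a warning and marked in the `"nonpositive"` attribute,
#' never silently clipped, so that model comparison sees the published
#' behaviour of those structures.
#'
#' @param model a `cl_model` or a model id.
#' @param theta numeric parameter vector (see `cl_model(id)$par_names`;
#'   `theta[1]` is always CL70, the typical clearance of a 70 kg adult, L/h).
#' @param data data frame with columns `wt` (kg) and, as the model requires,
#'   `pna` (years) and/or `pma` (weeks).
#' @return numeric vector of clearances (L/h), with attribute `"nonpositive"`
#'   (integer indices) when any prediction is <= 0.
#' @examples
#' evaluate_cl("1", c(5.97, 4.19, 45.1),
#'             data.frame(wt = 3.5, pma = 40 + 1 / 7))
#' @export
evaluate_cl <- function(model, theta, data) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  v <- validate_params(model, theta)
  if (length(v)) stop("invalid parameters for model ", model$id, ": ",
                      paste(v, collapse = "; "), call. = FALSE)
  cv <- .get_covariates(model, data)
  cl <- model$predict(theta, cv$wt, cv$pna, cv$pma)
  bad <- which(!is.na(cl) & cl <= 0)
  if (length(bad)) {
    warning("model ", model$id, ": non-positive clearance predicted for ",
            length(bad), " record(s); returned unclipped and flagged",
            call. = FALSE)
    attr(cl, "nonpositive") <- bad
  }
  cl
}

#' Maturation fraction of a model with a separable age factor
#'
#' Returns the multiplicative age factor `mat` such that
#' `CL = CL70 * (WT/70)^b * mat`.  For the sigmoid structures (models 1, 9,
#' 9b, and the Hill part of 12) the fraction lies in (0, 1), is monotone
#' non-decreasing in age, and equals 0.5 at the half-maturation age.
#' Pure-size models (2-4) and exponent-varying models (13-18) have no
#' separable maturation factor and raise an error.
#'
#' @inheritParams evaluate_cl
#' @return numeric vector of dimensionless maturation factors.
#' @export
maturation_fraction <- function(model, theta, data) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  if (is.null(model$mat))
    stop("model ", model$id, " has no separable maturation factor",
         call. = FALSE)
  v <- validate_params(model, theta)
  if (length(v)) stop("invalid parameters for model ", model$id, ": ",
                      paste(v, collapse = "; "), call. = FALSE)
  cv <- .get_covariates(model, data)
  model$mat(theta, cv$wt, cv$pna, cv$pma)
}

#' Allometric exponent applied to (WT/70)
#'
#' The exponent may be a fixed constant (models 1, 3, 4, 7, 8, 9b, 10-12),
#' an estimated constant (2, 5, 6, 9), a step schedule in age or weight
#' (13-15), or a continuous function of weight or age (16-18).  For models
#' 17 and 18 the exponent decreases monotonically from `b_max` towards
#' `b_max - b_drop` as weight (resp. age) grows.
#'
#' @inheritParams evaluate_cl
#' @return numeric vector of dimensionless exponents (recycled to the number
#'   of rows of `data` when constant).
#' @export
allometric_exponent <- function(model, theta, data) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  if (is.null(model$b))
    stop("model ", model$id, " has no single allometric exponent",
         call. = FALSE)
  v <- validate_params(model, theta)
  if (length(v)) stop("invalid parameters for model ", model$id, ": ",
                      paste(v, collapse = "; "), call. = FALSE)
  cv <- .get_covariates(model, data)
  b <- model$b(theta, cv$wt, cv$pna)
  rep_len(b, nrow(data))
}

#' Validate a parameter vector against a model's structure
#'
#' Checks arity and the positivity constraints implied by the estimation
#' transforms (CL70 > 0 always; Hill and half-maturation parameters > 0
#' where the structure requires them).
#'
#' @inheritParams evaluate_cl
#' @return character vector of violations; `character(0)` when valid.
#' @export
validate_params <- function(model, theta) {
  if (!inherits(model, "cl_model")) model <- cl_model(model)
  out <- character()
  if (length(theta) != model$npar) {
    return(sprintf("expected %d parameter(s) (%s), got %d", model$npar,
                   paste(model$par_names, collapse = ", "), length(theta)))
  }
  if (anyNA(theta)) return("parameter vector contains NA")
  pos <- model$transform == "log"
  bad <- which(pos & theta <= 0)
  if (length(bad))
    out <- c(out, sprintf("parameter %s must be > 0 (got %g)",
                          model$par_names[bad], theta[bad]))
  out
}

#' Export the model catalogue as a table
#'
#' One row per model: id, name, equation string, number of estimated
#' structural parameters, parameter names, fixed constants and covariates
#' used.  Suitable for writing to CSV or JSON.
#'
#' @return a data frame.
#' @export
model_catalogue <- function() {
  rows <- lapply(.cl_models, function(m) {
    data.frame(model_id = m$id, name = m$name, equation = m$equation,
               n_params = m$npar,
               parameters = paste(m$par_names, collapse = ";"),
               fixed_constants = if (length(m$fixed))
                 paste(names(m$fixed), m$fixed, sep = "=", collapse = ";")
               else "",
               covariates = paste(m$covariates, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published parameter estimates for gentamicin and midazolam
#'
#' Literature point estimates (with standard errors) for every catalogue
#' model fitted to study-level gentamicin and midazolam clearance records,
#' as reported in a published systematic comparison of clearance-scaling
#' models.  `theta` excludes residual variance; `ruv` is the residual
#' unexplained variability (log-scale variance of the exponential error
#' model).  Model 9b was reported for gentamicin only.
#'
#' @param drug `"gentamicin"` or `"midazolam"`.
#' @param model_id optional model id; when given, returns that model's entry
#'   (a list with `theta`, `se`, `ruv`, `ruv_se`), otherwise the full named
#'   list over models.
#' @return a list (see above).
#' @examples
#' published_estimates("gentamicin", "1")$theta
#' @export
published_estimates <- function(drug = c("gentamicin", "midazolam"),
                                model_id = NULL) {
  drug <- match.arg(drug)
  est <- .published[[drug]]
  if (is.null(model_id)) return(est)
  model_id <- as.character(model_id)
  if (!model_id %in% names(est))
    stop("no published ", drug, " estimates for model ", model_id,
         call. = FALSE)
  est[[model_id]]
}

.pe <- function(theta, se, ruv, ruv_se)
  list(theta = theta, se = se, ruv = ruv, ruv_se = ruv_se)

.published <- list(
  gentamicin = list(
    "1"  = .pe(c(5.97, 4.19, 45.1), c(0.33, 0.70, 2.96), 0.075, 0.018),
    "2"  = .pe(c(9.16, 1.28), c(1.42, 0.05), 0.13, 0.027),
    "3"  = .pe(2.90, 0.31, 0.64, 0.087),
    "4"  = .pe(2.55, 0.31, 0.81, 0.122),
    "5"  = .pe(c(9.16, 1.28, 5.8e-9), c(1.42, 0.05, 1.52e-9), 0.13, 0.027),
    "6"  = .pe(c(8.56, 1.26, 0.02), c(1.29, 0.04, 0.064), 0.13, 0.027),
    "7"  = .pe(c(1.51, 0.0065), c(0.17, 0.0035), 0.34, 0.087),
    "8"  = .pe(c(2.10, 0.00077), c(0.37, 0.00048), 0.55, 0.069),
    "9"  = .pe(c(5.86, 0.72, 4.25, 46.1), c(0.58, 0.097, 0.67, 4.88),
               0.075, 0.018),
    "9b" = .pe(5.59, 0.22, 0.086, 0.031),
    "10" = .pe(c(5.98, 0.65, 27.1), c(0.34, 0.037, 4.90), 0.08, 0.023),
    "11" = .pe(c(5.77, 0.21, 2.39), c(0.34, 0.018, 1.53), 0.097, 0.017),
    "12" = .pe(c(5.91, 1.10, 0.29, 0.21), c(0.39, 0.17, 0.17, 0.019),
               0.097, 0.016),
    "13" = .pe(6.67, 0.25, 0.08, 0.024),
    "14" = .pe(7.64, 0.337, 0.11, 0.032),
    "15" = .pe(c(8.54, 1.26, 1.12), c(2.08, 0.075, 0.28), 0.13, 0.027),
    "16" = .pe(c(6.08, 1.25, -0.13), c(0.57, 0.026, 0.024), 0.08, 0.018),
    "17" = .pe(c(5.31, 1.09, 1.23, 17.8, 1.26),
               c(0.35, 0.29, 0.058, 3.54, 0.049), 0.07, 0.022),
    "18" = .pe(c(5.64, 0.55, 1.21, 2.10, 0.95),
               c(0.44, 0.26, 0.032, 7.84, 0.90), 0.07, 0.014)),
  midazolam = list(
    "1"  = .pe(c(27.4, 4.04, 55.4), c(0.95, 0.53, 4.49), 0.071, 0.012),
    "2"  = .pe(c(24.9, 0.82), c(1.10, 0.10), 0.20, 0.056),
    "3"  = .pe(24.0, 1.39, 0.19, 0.05),
    "4"  = .pe(23.1, 1.35, 0.19, 0.053),
    "5"  = .pe(c(24.9, 0.82, 5.8e-9), c(1.10, 0.10, 4.13e-9), 0.20, 0.056),
    "6"  = .pe(c(24.9, 0.82, 6.6e-8), c(1.10, 0.10, 2.47e-8), 0.20, 0.056),
    "7"  = .pe(c(24.0, 5.0e-11), c(1.39, 1.43e-10), 0.20, 0.050),
    "8"  = .pe(c(24.0, 5.0e-11), c(1.39, 2.79e-11), 0.20, 0.050),
    "9"  = .pe(c(25.8, 0.57, 3.9, 68.3), c(0.98, 0.053, 0.46, 6.58),
               0.059, 0.0090),
    "10" = .pe(c(27.0, 0.71, 28.9), c(0.94, 0.060, 8.51), 0.091, 0.019),
    "11" = .pe(c(27.1, 0.11, 2.63), c(0.95, 0.020, 0.74), 0.078, 0.013),
    "12" = .pe(c(27.2, 7.3, 0.102, 0.12), c(0.96, 0.19, 0.0025, 0.015),
               0.070, 0.011),
    "13" = .pe(27.3, 1.41, 0.15, 0.039),
    "14" = .pe(27.8, 1.52, 0.17, 0.059),
    "15" = .pe(c(24.6, 0.85, 0.67), c(1.05, 0.12, 0.070), 0.20, 0.055),
    "16" = .pe(c(25.4, 1.38, -0.27), c(0.985, 0.033, 0.033), 0.10, 0.022),
    "17" = .pe(c(26.0, 13.2, 1.35, 7.2, 0.74),
               c(0.98, 8.22, 0.023, 0.39, 0.044), 0.056, 0.0083),
    "18" = .pe(c(26.1, 19.6, 1.36, 0.017, 0.72),
               c(1.00, 4.81, 0.025, 0.00046, 0.046), 0.056, 0.0080))
)
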