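# Shared fixtures, all built in code.

# small deterministic record set spanning the age range (term covariates)
make_records <- function() {
  pna <- c(1 / 365.25, 0.5, 1, 3, 5, 10, 12, 16, 25, 40)
  wt <- c(3.5, 7.6, 9, 14.2, 18, 32, 39, 58, 70, 72)
  data.frame(drug = "gentamicin", source = "fixture", n = NA_integer_,
             wt = wt, ga = 40, pna = pna,
             pma = 40 + pna * 365.25 / 7,
             cl = c(0.25, 0.9, 1.2, 1.7, 2.1, 3.2, 3.9, 5.2, 6.1, 6.3),
             ga_imputed = FALSE, wt_imputed = FALSE, midrange_age = FALSE,
             birthweight_as_weight = FALSE, wide_age_range = FALSE,
             stringsAsFactors = FALSE)
}

# noise-free records generated from a model (for perfect-fit limits)
make_noisefree <- function(model_id, theta) {
  rec <- make_records()
  rec$cl <- as.numeric(evaluate_cl(model_id, theta, rec))
  rec
}

# minimal hand-built cl_fit (for operations that only need model + theta)
make_fake_fit <- function(model_id, theta, sigma2 = 0.05, records = NULL) {
  m <- cl_model(model_id)
  structure(list(model = m, theta = stats::setNames(theta, m$par_names),
                 sigma2 = sigma2, se = rep(NA_real_, m$npar),
                 se_sigma2 = NA_real_, cov_est = NULL, cov_nat = NULL,
                 transform = m$transform, neg2ll = NA_real_,
                 n = if (is.null(records)) 0L else nrow(records),
                 converged = TRUE, n_starts_used = 1L,
                 sigma2_boundary = FALSE,
                 records = records),
            class = "cl_fit")
}

# ingestion-dialect CSV written to a temp file; returns the path
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
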