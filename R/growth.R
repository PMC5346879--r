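# Packaged growth references used for covariate imputation and synthetic
# demographics.  Both tables are synthetic piecewise-linear references
# constructed for this package (sex-averaged, anchored so that the typical
# 1-day term neonate, 1-year infant, 5-year child and 12-year adolescent
# weigh 3.5, 9, 18 and 39 kg); they stand in for an external weight-for-age
# model and are pluggable wherever a `growth_function` argument is accepted.

# postnatal age (years) -> typical body weight (kg), 0-18 y, plateau above
.wfa_age <- c(0, 1 / 12, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5,
              6, 7, 8, 9, 10, 11, 12, 14, 16, 18)
.wfa_wt  <- c(3.5, 4.4, 6.0, 7.6, 8.5, 9.0, 10.6, 12.2, 14.2, 16.2, 18.0,
              20.5, 23.0, 25.5, 28.5, 32.0, 35.5, 39.0, 49.0, 58.0, 65.0)

#' Typical body weight for postnatal age
#'
#' Packaged synthetic weight-for-age reference (sex-averaged, linearly
#' interpolated between anchor ages; constant 70 kg above 20 years,
#' linearly approached between 18 and 20 years).  Used as the default
#' `growth_function` for imputing missing weights and for generating
#' synthetic demographics.
#'
#' @param pna postnatal age in years (vectorised).
#' @return typical body weight, kg.
#' @examples
#' weight_for_age(c(0, 1, 5, 12, 30))
#' @export
weight_for_age <- function(pna) {
  stopifnot(is.numeric(pna))
  if (any(pna < 0, na.rm = TRUE)) stop("postnatal age must be >= 0",
                                       call. = FALSE)
  stats::approx(c(.wfa_age, 20, 200), c(.wfa_wt, 70, 70),
                xout = pmin(pna, 200), rule = 2)$y
}

# gestational age (weeks) -> typical birth weight (kg), 22-42 wk
.bw_ga <- c(22, 24, 26, 28, 30, 32, 34, 36, 38, 40, 42)
.bw_wt <- c(0.50, 0.65, 0.85, 1.10, 1.40, 1.80, 2.20, 2.70, 3.10, 3.50, 3.70)

#' Typical birth weight for gestational age
#'
#' Packaged synthetic birth-weight reference for 22-42 weeks of gestation,
#' linearly interpolated (clamped at the table edges).  Used to generate
#' neonatal weights in the synthetic-data module.
#'
#' @param ga gestational age in weeks (vectorised).
#' @return typical birth weight, kg.
#' @export
birthweight_for_ga <- function(ga) {
  stopifnot(is.numeric(ga))
  stats::approx(.bw_ga, .bw_wt, xout = ga, rule = 2)$y
}
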