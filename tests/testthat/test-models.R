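# Structural model library: published worked examples, separability,
# maturation and exponent behaviour.

gent <- function(id) published_estimates("gentamicin", id)
mida <- function(id) published_estimates("midazolam", id)

neonate <- data.frame(wt = 3.5, pna = 1 / 365.25, pma = 40 + 1 / 7)
adult70 <- data.frame(wt = 70, pna = 30, pma = 40 + 30 * 365.25 / 7)

test_that("published point estimates reproduce the reported typical clearances", {
  ref <- reference_children()
  # standard model, gentamicin: neonate through adolescent
  cl1 <- evaluate_cl("1", gent("1")$theta, ref)
  expect_equal(round(cl1[c(1, 4)], 2), c(0.24, 3.85), tolerance = 1e-8)
  # standard model, midazolam neonate
  expect_equal(round(evaluate_cl("1", mida("1")$theta, ref[1, ]), 2), 0.62)
  # stepwise-exponent model: infant (band exponent 1.0) and child (0.9)
  cl13 <- evaluate_cl("13", gent("13")$theta, ref)
  expect_equal(round(cl13[2], 2), 0.86)
  expect_equal(signif(cl13[3], 3), 1.96, tolerance = 0.011)
})

test_that("all models are normalised to theta1 at 70 kg mature covariates", {
  for (id in cl_model_ids()) {
    th <- gent(id)$theta
    cl <- evaluate_cl(id, th, adult70)
    b <- allometric_exponent(id, th, adult70)
    # (70/70)^b = 1 for any exponent; remaining factor is the maturation
    # value at 30 years, which is 1 for pure-size models and ~1 for
    # asymptoting maturation models
    m <- cl_model(id)
    adj <- if (is.null(m$mat)) 1 else maturation_fraction(id, th, adult70)
    expect_equal(unname(cl), unname(th[1] * adj), tolerance = 1e-12,
                 label = paste("model", id))
    if (id %in% c("1", "9", "9b", "10"))
      expect_equal(unname(cl), unname(th[1]), tolerance = 1e-3,
                   label = paste("model", id, "mature adjustment"))
  }
})

test_that("separable models factor as CL70 * (WT/70)^b * maturation", {
  grid <- data.frame(wt = c(1.2, 3.5, 9, 18, 39, 70),
                     pna = c(0.01, 0.02, 1, 5, 12, 25))
  grid$pma <- 40 + grid$pna * 365.25 / 7
  for (id in c("1", "5", "6", "7", "8", "9", "9b", "10", "11", "12")) {
    th <- gent(id)$theta
    cl <- suppressWarnings(evaluate_cl(id, th, grid))
    b <- allometric_exponent(id, th, grid)
    mat <- maturation_fraction(id, th, grid)
    expect_equal(as.numeric(cl), as.numeric(th[1] * (grid$wt / 70)^b * mat),
                 tolerance = 1e-12, label = paste("model", id))
  }
})

test_that("estimated-exponent sigmoid model nests the standard model", {
  grid <- data.frame(wt = c(2, 9, 25, 70), pma = c(38, 92, 400, 2000),
                     pna = c(0, 1, 6.9, 37.6))
  th1 <- c(5.97, 4.19, 45.1)
  expect_identical(as.numeric(evaluate_cl("9", c(th1[1], 0.75, th1[2], th1[3]),
                                          grid)),
                   as.numeric(evaluate_cl("1", th1, grid)))
  # the fixed-GFR variant equals the estimated form at its fixed constants
  expect_identical(as.numeric(evaluate_cl("9b", 5.59, grid)),
                   as.numeric(evaluate_cl("9", c(5.59, 0.632, 3.33, 55.4),
                                          grid)))
})

test_that("standard-model clearance is monotone in weight and in PMA", {
  th <- gent("1")$theta
  wts <- seq(0.5, 90, length.out = 60)
  cl_w <- evaluate_cl("1", th, data.frame(wt = wts, pma = 60))
  expect_true(all(diff(cl_w) > 0))
  pmas <- seq(25, 1500, length.out = 80)
  cl_a <- evaluate_cl("1", th, data.frame(wt = 20, pma = pmas))
  expect_true(all(diff(cl_a) > 0))
})

test_that("maturation fraction is half-maximal at the half-maturation age", {
  expect_identical(maturation_fraction("1", c(5, 4.19, 45.1),
                                       data.frame(wt = 3, pma = 45.1)), 0.5)
  expect_identical(maturation_fraction("9", c(5, 0.7, 3.9, 68.3),
                                       data.frame(wt = 3, pma = 68.3)), 0.5)
  expect_identical(maturation_fraction("9b", 5.59,
                                       data.frame(wt = 3, pma = 55.4)), 0.5)
  # direct Hill evaluation, independently computed
  expect_equal(maturation_fraction("1", c(5.97, 4.19, 45.1),
                                   data.frame(wt = 3.5, pma = 40 + 1 / 7)),
               0.3803945, tolerance = 1e-6)
  # asymptotic-exponential maturation at term: 1 - frac * e^0
  expect_equal(maturation_fraction("10", c(5.98, 0.65, 27.1),
                                   data.frame(wt = 3.5, pma = 40)),
               0.35, tolerance = 1e-12)
})

test_that("sigmoid maturation is monotone and bounded in (0, 1)", {
  pmas <- seq(24, 3000, length.out = 200)
  for (id in c("1", "9", "9b")) {
    th <- gent(id)$theta
    f <- maturation_fraction(id, th, data.frame(wt = 10, pma = pmas,
                                                pna = (pmas - 40) / 52.1786))
    expect_true(all(f > 0 & f < 1), label = paste("model", id))
    expect_true(all(diff(f) >= 0), label = paste("model", id))
  }
})

test_that("maturation fraction is unsupported for pure-size and exponent-varying models", {
  for (id in c("2", "3", "4", "13", "14", "15", "16", "17", "18"))
    expect_error(maturation_fraction(id, gent(id)$theta, adult70),
                 "no separable maturation", label = paste("model", id))
})

test_that("allometric exponents follow the published schedules", {
  expect_equal(allometric_exponent("14", 7.64,
                                   data.frame(wt = c(5, 9, 20))),
               c(1.25, 1.25, 0.76))  # boundary tie takes the lower band
  expect_equal(allometric_exponent("3", 2.90, data.frame(wt = 50)), 0.75)
  expect_equal(allometric_exponent("16", c(6, 1.0, 0),
                                   data.frame(wt = c(2, 70))), c(1, 1))
  # age-band schedule, boundary ties inclusive below
  expect_equal(allometric_exponent("13", 6.67,
                                   data.frame(wt = 10,
                                              pna = c(0.1, 0.25, 1, 2, 3, 5, 6))),
               c(1.2, 1.2, 1.0, 1.0, 0.9, 0.9, 0.75))
  expect_equal(allometric_exponent("15", c(8.54, 1.26, 1.12),
                                   data.frame(wt = c(10, 16.5, 20))),
               c(1.26, 1.26, 1.12))
})

test_that("weight-sigmoid and age-sigmoid exponents decrease monotonically", {
  th17 <- gent("17")$theta
  b17 <- allometric_exponent("17", th17,
                             data.frame(wt = seq(1, 100, length.out = 50)))
  expect_true(all(diff(b17) < 0))
  expect_true(all(b17 < th17[3] & b17 > th17[3] - th17[5]))
  th18 <- gent("18")$theta
  b18 <- allometric_exponent("18", th18,
                             data.frame(wt = 20,
                                        pna = seq(0, 50, length.out = 50)))
  expect_true(all(diff(b18) < 0))
})

test_that("step models are piecewise constant with finite band-edge jumps", {
  th <- 6.67
  # continuous in weight within an age band
  wts <- seq(10, 12, length.out = 50)
  cl <- evaluate_cl("13", th, data.frame(wt = wts, pna = 1))
  expect_true(all(abs(diff(cl)) < 0.2))
  # jump at the age-band edge is finite and equals the exponent switch
  below <- evaluate_cl("13", th, data.frame(wt = 12, pna = 2))
  above <- evaluate_cl("13", th, data.frame(wt = 12, pna = 2 + 1e-9))
  expect_equal(above / below, (12 / 70)^(0.9 - 1.0), tolerance = 1e-6)
})

test_that("linear maturation structures flag non-positive clearance instead of clipping", {
  preterm <- data.frame(wt = 0.8, pna = 0.003, pma = 20)
  expect_warning(cl <- evaluate_cl("7", c(1.51, 0.06), preterm),
                 "non-positive")
  expect_lt(as.numeric(cl), 0)          # returned unclipped
  expect_equal(attr(cl, "nonpositive"), 1L)
})

test_that("parameter validation reports arity and positivity violations", {
  expect_length(validate_params("1", c(5.97, 4.19, 45.1)), 0)
  expect_match(validate_params("1", c(5.97, 4.19)), "expected 3")
  expect_match(validate_params("1", c(5.97, 4.19, -1)), "must be > 0")
  expect_match(validate_params("2", c(-2, 0.75)), "CL70")
  # sign-free parameters are not positivity-checked
  expect_length(validate_params("16", c(6.08, 1.25, -0.13)), 0)
  expect_error(evaluate_cl("1", c(5, 4), neonate), "invalid parameters")
})

test_that("missing covariates raise a covariate error", {
  expect_error(evaluate_cl("1", c(5.97, 4.19, 45.1), data.frame(wt = 3.5)),
               "requires covariate")
  expect_error(evaluate_cl("13", 6.67, data.frame(wt = 3.5)),
               "requires covariate")
})

test_that("the model catalogue exports one complete row per model", {
  cat <- model_catalogue()
  expect_equal(nrow(cat), 19)
  expect_setequal(cat$model_id, cl_model_ids())
  expect_true(all(cat$n_params >= 1))
  expect_true(all(grepl("WT", cat$covariates)))  # every model uses weight
  # parameter counts match the published convention per structure
  counts <- setNames(cat$n_params, cat$model_id)
  expect_equal(unname(counts[c("1", "9", "9b", "13", "17")]),
               c(3, 4, 1, 1, 5))
})
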