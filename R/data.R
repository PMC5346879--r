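# Ingestion, imputation, filtering and age grouping of study-level
# clearance records.
#
# The canonical in-memory form is a data frame with columns
#   drug    "gentamicin" or "midazolam"
#   source  character provenance label
#   n       optional subject count (NA allowed)
#   wt      body weight, kg
#   ga      gestational age, weeks
#   pna     postnatal age, years
#   pma     postmenstrual age, weeks (ga + pna in weeks)
#   cl      observed clearance, L/h
# plus logical flag columns ga_imputed, wt_imputed, midrange_age,
# birthweight_as_weight, wide_age_range.

.flag_cols <- c("ga_imputed", "wt_imputed", "midrange_age",
                "birthweight_as_weight", "wide_age_range")

.pna_to_years <- c(days = 1 / 365.25, weeks = 7 / 365.25,
                   months = 1 / 12, years = 1)

# parse "2-6" / "2–6" style ranges to their midpoint; returns value and
# whether a range was collapsed
.parse_range <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  is_range <- is.na(num) & grepl("^[0-9.]+[ ]*[-–][ ]*[0-9.]+$", x)
  if (any(is_range)) {
    parts <- strsplit(x[is_range], "[-–]")
    num[is_range] <- vapply(parts, function(p) mean(as.numeric(trimws(p))),
                            numeric(1))
  }
  list(value = num, midrange = is_range)
}

#' Read study-level clearance records from CSV
#'
#' Expects a UTF-8 delimited file with a header row and columns
#' `drug, source, n, wt_kg, ga_weeks, pna_value, pna_unit, cl_l_per_h,
#' wide_age_range` (`pna_unit` one of days/weeks/months/years;
#' `wide_age_range` logical/0-1).  `wt_kg` and `pna_value` may contain
#' ranges like `"2-6"`, which are collapsed to their midpoint and flagged
#' `midrange_age` (for age ranges).  Rows with missing or non-positive
#' clearance, or with both weight and age missing, are rejected; rejected
#' rows are reported with line numbers in the `"rejected"` attribute.
#'
#' @param path path to the CSV file.
#' @param drug optional filter, `"gentamicin"` or `"midazolam"`.
#' @return canonical records data frame (see Details), with attribute
#'   `"rejected"` (data frame of line numbers and reasons).
#' @export
read_cl_data <- function(path, drug = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  mandatory <- c("drug", "cl_l_per_h")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(c("wt_kg", "pna_value") %in% names(raw)))
    stop("need at least one of columns wt_kg, pna_value", call. = FALSE)
  for (cc in c("source", "n", "wt_kg", "ga_weeks", "pna_value", "pna_unit",
               "wide_age_range"))
    if (!cc %in% names(raw)) raw[[cc]] <- NA_character_

  wtp <- .parse_range(raw$wt_kg)
  pnp <- .parse_range(raw$pna_value)
  unit <- ifelse(is.na(raw$pna_unit) | raw$pna_unit == "", "years",
                 raw$pna_unit)
  bad_unit <- !unit %in% names(.pna_to_years)
  pna <- pnp$value * .pna_to_years[unit]
  cl <- suppressWarnings(as.numeric(raw$cl_l_per_h))
  wide <- tolower(trimws(ifelse(is.na(raw$wide_age_range), "",
                                raw$wide_age_range))) %in%
    c("1", "true", "yes")

  rec <- data.frame(
    drug = tolower(trimws(raw$drug)),
    source = ifelse(is.na(raw$source), "", raw$source),
    n = suppressWarnings(as.integer(raw$n)),
    wt = wtp$value, ga = suppressWarnings(as.numeric(raw$ga_weeks)),
    pna = unname(pna), pma = NA_real_, cl = cl,
    ga_imputed = FALSE, wt_imputed = FALSE,
    midrange_age = pnp$midrange, birthweight_as_weight = FALSE,
    wide_age_range = wide, stringsAsFactors = FALSE)

  reason <- character(nrow(rec))
  reason[is.na(rec$cl)] <- "clearance missing or non-numeric"
  reason[!is.na(rec$cl) & rec$cl <= 0] <- "clearance must be > 0"
  reason[reason == "" & bad_unit & !is.na(pnp$value)] <-
    "unknown pna_unit"
  reason[reason == "" & is.na(rec$wt) & is.na(rec$pna)] <-
    "both weight and age missing"
  reason[reason == "" & !rec$drug %in% c("gentamicin", "midazolam")] <-
    "unknown drug"
  ok <- reason == ""
  rejected <- data.frame(line = which(!ok) + 1L, reason = reason[!ok],
                         stringsAsFactors = FALSE)
  out <- rec[ok, , drop = FALSE]
  if (!is.null(drug)) out <- out[out$drug == drug, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Impute missing covariates in clearance records
#'
#' Applies the covariate completion rules used for literature-extracted
#' records: a gestational age of 40 weeks is assigned when GA is not
#' reported (flag `ga_imputed`); missing weight is filled from the typical
#' weight for age via `growth_function` (flag `wt_imputed`); PMA is derived
#' as `ga + pna` expressed in weeks whenever absent.  Observed values are
#' never overwritten.  Records lacking both weight and age are dropped with
#' a warning (reported in the `"dropped"` attribute).
#'
#' @param records canonical records data frame (see [read_cl_data()]).
#' @param growth_function maps PNA (years) to typical weight (kg);
#'   default [weight_for_age()].
#' @return records with covariates completed and flags updated.
#' @export
impute_cl_data <- function(records, growth_function = weight_for_age) {
  stopifnot(is.data.frame(records))
  bad <- is.na(records$wt) & is.na(records$pna)
  if (any(bad)) {
    warning(sum(bad), " record(s) lack both weight and age; dropped",
            call. = FALSE)
    dropped <- records[bad, , drop = FALSE]
  } else dropped <- records[0, , drop = FALSE]
  records <- records[!bad, , drop = FALSE]

  miss_ga <- is.na(records$ga)
  records$ga[miss_ga] <- 40
  records$ga_imputed <- records$ga_imputed | miss_ga

  miss_wt <- is.na(records$wt)
  if (any(miss_wt))
    records$wt[miss_wt] <- growth_function(records$pna[miss_wt])
  records$wt_imputed <- records$wt_imputed | miss_wt

  miss_pma <- is.na(records$pma)
  records$pma[miss_pma] <- records$ga[miss_pma] +
    records$pna[miss_pma] * WEEKS_PER_YEAR
  rownames(records) <- NULL
  attr(records, "dropped") <- dropped
  records
}

#' Apply the study inclusion filters
#'
#' Gentamicin records with postnatal age over 50 years are excluded (to
#' avoid adult values affected by declining renal function); records pooled
#' over a wide age range (`wide_age_range` flag) are excluded for either
#' drug.  Filtering never mutates records: `kept` plus `excluded` equals the
#' input.
#'
#' @param records canonical records data frame.
#' @return list with `kept` (records), `excluded` (records plus a `reason`
#'   column).
#' @export
apply_filters <- function(records) {
  stopifnot(is.data.frame(records))
  reason <- character(nrow(records))
  reason[records$wide_age_range] <- "wide age range pooled"
  sel <- reason == "" & records$drug == "gentamicin" &
    !is.na(records$pna) & records$pna > 50
  reason[sel] <- "gentamicin age > 50 y"
  excluded <- records[reason != "", , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[reason != ""]
  else excluded$reason <- character(0)
  kept <- records[reason == "", , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

.age_group_levels <- c("neonate", "infant", "child", "adolescent", "adult")

#' Assign paediatric age groups
#'
#' Partition of postnatal age used for the age-stratified AIC decomposition:
#' neonates (0-28 days), infants (>28 days to <2 years), children (2 to
#' <12 years), adolescents (12-18 years) and adults (>18 years).  The
#' intervals are gapless, so every non-negative age maps to exactly one
#' group.
#'
#' @param pna postnatal age in years (vectorised).
#' @return factor with levels neonate, infant, child, adolescent, adult.
#' @examples
#' assign_age_group(c(14 / 365.25, 1, 5, 12, 19))
#' @export
assign_age_group <- function(pna) {
  stopifnot(is.numeric(pna))
  if (any(pna < 0, na.rm = TRUE))
    stop("postnatal age must be >= 0", call. = FALSE)
  g <- ifelse(pna <= 28 / 365.25, "neonate",
         ifelse(pna < 2, "infant",
           ifelse(pna < 12, "child",
             ifelse(pna <= 18, "adolescent", "adult"))))
  factor(g, levels = .age_group_levels)
}

#' Write an exclusion log
#'
#' @param excluded the `excluded` component of [apply_filters()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(excluded, path) {
  utils::write.csv(excluded, path, row.names = FALSE)
  invisible(path)
}
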