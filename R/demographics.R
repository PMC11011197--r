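# Demographic derivations: incidence weighting of employment and income,
# co-payment exemption limits, and the blended net household income that the
# loss-of-income model consumes.

#' Incidence weights across age strata
#'
#' Shares of newly diagnosed cases per age band, `cases / total`.
#'
#' @param strata Data frame with columns `label` and `cases` (as in
#'   `load_params()$strata`).
#' @return Named numeric vector of fractions summing to 1.
#' @export
#' @examples
#' incidence_weights(load_params()$strata)
incidence_weights <- function(strata) {
  if (is.null(strata) || nrow(strata) == 0)
    stop("empty strata", call. = FALSE)
  total <- sum(strata$cases)
  if (total <= 0) stop("total case count must be positive", call. = FALSE)
  setNames(strata$cases / total, strata$label)
}

# incidence shares at the reporting precision of the source table:
# percentages rounded to `digits` decimals, bands below `share_floor`
# suppressed (the table prints them as "< 0.5 %" and they do not enter the
# published weighted means)
.table_weights <- function(strata, digits = 1, share_floor = 0.005) {
  w <- round(100 * incidence_weights(strata), digits) / 100
  w[w < share_floor] <- 0
  if (sum(w) <= 0) stop("no stratum carries weight", call. = FALSE)
  w
}

#' Incidence-weighted mean of a stratum-level quantity
#'
#' Weighted mean of an age-stratified field using incidence shares as
#' weights. The default `"printed"` mode reproduces the source statistics'
#' derived values: band shares are taken at the table's one-decimal
#' percentage precision and near-empty bands (printed as "< 0.5 %") are
#' suppressed. `"exact"` uses the raw case shares of every band (see the
#' methods vignette for why the two differ below the reporting precision).
#'
#' @param strata Stratum data frame (see [incidence_weights()]).
#' @param field Either `"employment_rate"` or `"gross_income_monthly"`.
#' @param mode `"printed"` (reporting-precision weights) or `"exact"`.
#' @return The weighted mean (scalar).
#' @export
#' @examples
#' weighted_mean(load_params()$strata, "employment_rate")   # ~0.282
#' weighted_mean(load_params()$strata, "gross_income_monthly")  # ~4409
weighted_mean <- function(strata, field = c("employment_rate",
                                            "gross_income_monthly"),
                          mode = c("printed", "exact")) {
  field <- match.arg(field)
  mode <- match.arg(mode)
  if (anyNA(strata[[field]]))
    stop(sprintf("missing '%s' value in stratum '%s'", field,
                 strata$label[which(is.na(strata[[field]]))[1]]), call. = FALSE)
  w <- if (mode == "printed") .table_weights(strata) else incidence_weights(strata)
  stats::weighted.mean(strata[[field]], w)
}

#' Annual co-payment exemption limit
#'
#' Statutory out-of-pocket cap: a fraction (2 % generally, 1 % for chronic
#' disease) of annual gross household income after deducting a personal
#' allowance per household member; floored at zero.
#'
#' @param gross_income_monthly Gross household income per month (EUR).
#' @param household_size Persons in the household.
#' @param allowance_per_person Annual personal allowance (EUR).
#' @param rate Exemption rate (fraction of adjusted annual gross income).
#' @return Annual exemption limit in EUR.
#' @export
#' @examples
#' copay_exemption_limit(4409, 2, 5922, 0.02)  # 821.28
#' copay_exemption_limit(4409, 2, 5922, 0.01)  # 410.64
copay_exemption_limit <- function(gross_income_monthly, household_size,
                                  allowance_per_person, rate) {
  stopifnot(gross_income_monthly >= 0, household_size > 0,
            allowance_per_person >= 0, rate >= 0)
  max(0, (12 * gross_income_monthly -
            household_size * allowance_per_person)) * rate
}

#' Blended net monthly household income
#'
#' Mixes retired households (pension income per household member; the
#' taxable share of the pension is tested against the income-tax allowance
#' and taxed only above it) with working-age households (gross income scaled
#' by a configurable net-conversion factor), weighted by incidence shares.
#' With the bundled profile this reproduces the base-case net household
#' income of about 2580 EUR/month.
#'
#' @param strata Stratum data frame with a logical `retired` column.
#' @param econ Economics parameter list (`load_params()$economics`).
#' @param mode Incidence-weight mode, as in [weighted_mean()].
#' @return Net household income in EUR per month.
#' @export
net_household_income <- function(strata, econ, mode = c("printed", "exact")) {
  mode <- match.arg(mode)
  w <- if (mode == "printed") .table_weights(strata) else incidence_weights(strata)
  w <- w / sum(w)
  retired <- strata$retired

  pension_net_monthly <- local({
    taxable <- econ$pension_taxable_fraction * 12 * econ$pension_monthly
    excess <- max(0, taxable - econ$tax_allowance_per_person)
    econ$pension_monthly - excess * econ$pension_tax_rate / 12
  })
  hh_retired <- econ$household_size * pension_net_monthly
  hh_working <- econ$gross_income_monthly * econ$net_conversion_factor

  w_ret <- sum(w[retired])
  w_ret * hh_retired + (1 - w_ret) * hh_working
}

#' Summary of the demographic derivations
#'
#' Collects the incidence weights, the incidence-weighted employment rate and
#' gross income, the blended net household income and both co-payment
#' exemption limits into one table for inspection or export.
#'
#' @param params A `nomcea_params` object.
#' @return A data frame with columns `quantity`, `value` and `unit`.
#' @export
demographics_summary <- function(params) {
  ec <- params$economics
  st <- params$strata
  emp <- weighted_mean(st, "employment_rate")
  inc <- weighted_mean(st, "gross_income_monthly")
  nhh <- net_household_income(st, ec)
  lim2 <- copay_exemption_limit(ec$gross_income_monthly, ec$household_size,
                                ec$personal_allowance_per_person,
                                ec$copay_rate_general)
  lim1 <- copay_exemption_limit(ec$gross_income_monthly, ec$household_size,
                                ec$personal_allowance_per_person,
                                ec$copay_rate_chronic)
  data.frame(
    quantity = c("employment_rate_weighted", "gross_income_monthly_weighted",
                 "net_household_income_monthly",
                 "copay_exemption_limit_general_annual",
                 "copay_exemption_limit_chronic_annual"),
    value = c(emp, inc, nhh, lim2, lim1),
    unit = c("fraction", "EUR/month", "EUR/month", "EUR/year", "EUR/year"),
    stringsAsFactors = FALSE
  )
}
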