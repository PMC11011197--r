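# Patient-borne annual costs per health state, strategy and employment
# scenario: co-payments up to the statutory exemption limit, driving
# expenses, monthly care supplements, and loss of income under the German
# sick-pay rules.

#' Driving cost for a series of visits
#'
#' For a covered treatment series (long-course chemoradiotherapy or
#' chemotherapy) the insurer carries the mileage and the patient pays the
#' statutory taxi co-payment for the first and last drive only. Uncovered
#' visits (follow-up) are paid at the per-kilometre rate for the round trip.
#'
#' @param n_visits Number of visits (drives) in the series.
#' @param covered Is the series covered by the insurer?
#' @param distance_km One-way driving distance in km.
#' @param rate_per_km Rate in EUR per km.
#' @param taxi_copay_per_drive Co-payment per covered drive at the start and
#'   end of a series (EUR).
#' @param round_trip_factor Multiplier turning a one-way distance into the
#'   distance actually driven per visit.
#' @return Cost in EUR borne by the patient.
#' @export
#' @examples
#' driving_cost(28, covered = TRUE)                 # 10: first + last drive
#' driving_cost(1, covered = FALSE)                 # 10.52 = 2 * 26.3 * 0.2
driving_cost <- function(n_visits, covered, distance_km = 26.3,
                         rate_per_km = 0.2, taxi_copay_per_drive = 5,
                         round_trip_factor = 2) {
  if (n_visits < 0) stop("n_visits must be non-negative", call. = FALSE)
  if (n_visits == 0) return(0)
  if (covered) {
    # first and last drive of the series carry the taxi co-payment
    return(taxi_copay_per_drive * min(2, n_visits))
  }
  n_visits * round_trip_factor * distance_km * rate_per_km
}

#' Annual treatment co-payments under the statutory rules
#'
#' 10 EUR per unit (medication, health-care measures) plus 10 EUR per
#' in-patient night capped at 280 EUR per year, the sum capped at the
#' applicable exemption limit (2 % of adjusted gross household income, 1 %
#' for chronic disease). For continuous therapy (combined local and distant
#' recurrence) the cost is set at the chronic exemption limit itself.
#'
#' @param units Co-payment units in the year.
#' @param inpatient_nights In-patient nights in the year.
#' @param econ Economics parameter list (`load_params()$economics`).
#' @param chronic Apply the chronic (1 %) exemption limit?
#' @param at_limit Set the cost at the exemption limit (continuous therapy).
#' @return Annual co-payment in EUR.
#' @export
#' @examples
#' econ <- load_params()$economics
#' copay_cost(0, 40, econ)           # 280: in-patient cap binds
#' copay_cost(0, 0, econ, at_limit = TRUE, chronic = TRUE)  # chronic limit
copay_cost <- function(units, inpatient_nights, econ, chronic = FALSE,
                       at_limit = FALSE) {
  stopifnot(units >= 0, inpatient_nights >= 0)
  rate <- if (chronic) econ$copay_rate_chronic else econ$copay_rate_general
  limit <- copay_exemption_limit(econ$gross_income_monthly,
                                 econ$household_size,
                                 econ$personal_allowance_per_person, rate)
  if (at_limit) return(limit)
  raw <- units * econ$copay_per_unit +
    min(inpatient_nights * econ$copay_per_unit, econ$inpatient_copay_cap_annual)
  min(raw, limit)
}

#' Annual loss of income
#'
#' Retired patients lose nothing. Employed patients keep full salary for the
#' first six weeks of absence and receive sick pay at 70 % of gross income
#' for up to another 72 weeks, so the temporary loss is 30 % of gross weekly
#' income for the capped excess weeks. Permanent disability replaces the
#' personal net income with the reduced-earning-capacity pension. The mixed
#' scenario weights the employed loss by the cohort employment rate.
#'
#' @param scenario One of `"employed"`, `"retired"`, `"mixed"`.
#' @param absence_weeks Weeks of absence from work in the year.
#' @param permanent Permanent disability (overrides `absence_weeks`)?
#' @param econ Economics parameter list.
#' @return Annual loss of income in EUR.
#' @export
#' @examples
#' econ <- load_params()$economics
#' income_loss("employed", 10, FALSE, econ)  # 4 weeks at 30 % of gross
#' income_loss("retired", 52, FALSE, econ)   # 0
income_loss <- function(scenario = c("employed", "retired", "mixed"),
                        absence_weeks, permanent, econ) {
  scenario <- match.arg(scenario)
  stopifnot(absence_weeks >= 0)
  if (scenario == "retired") return(0)
  employed_loss <- if (permanent) {
    net_personal <- econ$gross_income_monthly * econ$net_conversion_factor
    max(0, net_personal - econ$reduced_earning_capacity_pension_monthly) * 12
  } else {
    weekly_gross <- econ$gross_income_monthly * 12 / 52
    excess <- min(max(absence_weeks - econ$full_pay_weeks, 0),
                  econ$sick_pay_max_weeks)
    excess * (1 - econ$sick_pay_fraction) * weekly_gross
  }
  if (scenario == "mixed") econ$employment_rate_mixed * employed_loss
  else employed_loss
}

# number of covered drives across a strategy's treatment series
.series_copay <- function(series, econ) {
  sum(vapply(series, function(ts)
    driving_cost(ts$n_drives, ts$covered, econ$driving_distance_km,
                 econ$driving_rate_per_km, econ$taxi_copay_per_drive,
                 econ$round_trip_factor), numeric(1)))
}

#' Annual patient cost per health state and cycle year
#'
#' Composes the four cost components (co-payments, driving, supplements,
#' loss of income) into an annual cost for every health state and cycle
#' year of one strategy under one employment scenario. Primary-treatment
#' costs (covered-series drives, treatment-year co-payments, primary
#' in-patient stay, initial absence from work) attach to the stable state in
#' cycle 1; recurrence states carry salvage-related in-patient stays and
#' absence in every year spent there; the combined-recurrence state is
#' costed at the chronic co-payment exemption limit with permanent
#' disability.
#'
#' @param strategy `"nom"` or `"resection"`.
#' @param params A `nomcea_params` object.
#' @param scenario Employment scenario: `"employed"`, `"retired"`, `"mixed"`.
#' @return A `nomcea_state_costs` data frame with one row per state and
#'   cycle year and columns for each component and the total.
#' @export
#' @examples
#' costs <- build_state_costs("nom", load_params(), "retired")
#' subset(costs, state == "A" & year == 3)
build_state_costs <- function(strategy = c("nom", "resection"), params,
                              scenario = c("mixed", "employed", "retired")) {
  strategy <- match.arg(strategy)
  scenario <- match.arg(scenario)
  ec <- params$economics
  st <- params$strategies[[strategy]]
  ca <- params$cost_assumptions

  fu_cost <- function(n) driving_cost(n, FALSE, ec$driving_distance_km,
                                      ec$driving_rate_per_km,
                                      ec$taxi_copay_per_drive,
                                      ec$round_trip_factor)
  series_copay <- .series_copay(st$treatment_series, ec)
  supplement <- if (st$ostomy) 12 * ec$supplement_monthly else 0

  rows <- list()
  for (state in STATE_CODES) {
    for (year in seq_len(N_CYCLES)) {
      copay <- driving <- suppl <- loss <- 0
      chronic_year <- year > 1  # chronic (1 %) limit after the primary year
      if (state == "A") {
        fu <- st$followup_visits_per_year[[year]]
        driving <- fu_cost(fu)
        if (year == 1) {
          driving <- driving + series_copay
          copay <- copay_cost(ca$copay_units_primary_year,
                              st$inpatient_nights_primary, ec,
                              chronic = FALSE)
          loss <- income_loss(scenario, st$return_to_work_weeks, FALSE, ec)
        } else {
          copay <- copay_cost(ca$copay_units_followup_year, 0, ec,
                              chronic = FALSE)
        }
        suppl <- supplement
      } else if (state == "B") {
        # stable after salvage resection: ostomy care in both arms
        driving <- fu_cost(ca$followup_visits_post_salvage_per_year)
        copay <- copay_cost(ca$copay_units_followup_year, 0, ec,
                            chronic = chronic_year)
        suppl <- 12 * ec$supplement_monthly
      } else if (state == "C") {
        driving <- .series_copay(list(list(n_drives = 2, covered = TRUE)), ec) +
          fu_cost(ca$followup_visits_post_salvage_per_year)
        copay <- copay_cost(ca$copay_units_recurrence_year,
                            st$inpatient_nights_salvage, ec,
                            chronic = chronic_year)
        loss <- income_loss(scenario, ca$absence_weeks_salvage_local, FALSE, ec)
        suppl <- supplement
      } else if (state == "D") {
        driving <- .series_copay(list(list(n_drives = 2, covered = TRUE)), ec) +
          fu_cost(ca$followup_visits_post_salvage_per_year)
        copay <- copay_cost(ca$copay_units_recurrence_year,
                            st$inpatient_nights_metastasectomy, ec,
                            chronic = chronic_year)
        loss <- income_loss(scenario, ca$absence_weeks_salvage_distant, FALSE, ec)
        suppl <- supplement
      } else if (state == "E") {
        # continuous therapy: co-payments pinned at the chronic limit
        copay <- copay_cost(0, 0, ec, chronic = TRUE, at_limit = TRUE)
        driving <- .series_copay(list(list(n_drives = 2, covered = TRUE)), ec)
        loss <- income_loss(scenario, 0, TRUE, ec)
        suppl <- supplement
      }
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strategy, scenario = scenario, state = state, year = year,
        copay_component = copay, driving_component = driving,
        supplement_component = suppl, income_loss_component = loss,
        total = copay + driving + suppl + loss, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nomcea_state_costs", class(out))
  out
}

#' State-by-year cost matrix
#'
#' Reshapes a [build_state_costs()] profile into the 6-state x 5-year matrix
#' of annual totals that the Markov engine consumes.
#'
#' @param profile A `nomcea_state_costs` data frame.
#' @return A 6 x 5 numeric matrix (rows = states A-F, columns = years).
#' @export
state_cost_matrix <- function(profile) {
  m <- matrix(0, N_STATES, N_CYCLES,
              dimnames = list(STATE_CODES, seq_len(N_CYCLES)))
  for (i in seq_len(nrow(profile)))
    m[profile$state[i], profile$year[i]] <- profile$total[i]
  m
}
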