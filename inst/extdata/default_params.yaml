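# Default parameter profile: German SHI patient-perspective model of
# watch-and-wait (NOM after TNT) versus CRT + radical resection for
# locally advanced rectal cancer, five 1-year cycles.
#
# Values flagged "assumed, calibrated" are modelling assumptions that the
# source tables do not pin down (visit schedules, absence durations,
# co-payment unit counts, the net-income conversion factor); they are
# echoed by every report so the assumption set in force is auditable.
schema_version: 1

economics:
  wtp_per_qaly: 6000                 # EUR per QALY
  discount_rate_annual: 0.035
  gross_income_monthly: 4409         # incidence-weighted, employed patients
  net_household_income_monthly: 2580
  pension_monthly: 1048
  reduced_earning_capacity_pension_monthly: 925
  personal_allowance_per_person: 5922   # EUR/yr, co-payment exemption rule
  tax_allowance_per_person: 10347       # EUR/yr, income-tax free allowance
  pension_taxable_fraction: 0.8
  pension_tax_rate: 0.14             # applied to taxable pension above allowance
  net_conversion_factor: 0.7882      # gross -> net household, assumed, calibrated
  household_size: 2
  copay_rate_general: 0.02
  copay_rate_chronic: 0.01
  copay_per_unit: 10                 # EUR
  inpatient_copay_cap_annual: 280    # EUR
  driving_distance_km: 26.3          # one-way
  driving_rate_per_km: 0.2
  taxi_copay_per_drive: 5            # first and last drive of a covered series
  round_trip_factor: 2
  supplement_monthly: 10             # ostomy care / non-prescription medication
  sick_pay_fraction: 0.7             # of gross income
  full_pay_weeks: 6
  sick_pay_max_weeks: 72
  employment_rate_mixed: 0.282

# Age-stratified rectal cancer incidence (2019) with general-population
# employment rates and mean gross monthly income (2022).
strata:
  - {label: "<25",    cases: 14,    employment_rate: 0.382, gross_income_monthly: 2913, retired: false}
  - {label: "25-<45", cases: 460,   employment_rate: 0.780, gross_income_monthly: 3881, retired: false}
  - {label: "45-<65", cases: 5807,  employment_rate: 0.737, gross_income_monthly: 4155, retired: false}
  - {label: ">=65",   cases: 11614, employment_rate: 0.034, gross_income_monthly: 4557, retired: true}

transitions:
  nom:
    overall_g3g4_toxicity: 0.32
    perioperative_death: 0.04
    periop_death_at_salvage: true     # resection only happens at salvage
    local_recurrence_cum: {"2": 0.21, "5": 0.24}
    distant_recurrence_cum: {"3": 0.04, "5": 0.08}
    overall_survival: {"3": 0.95, "5": 0.85}
    distant_given_local: 0.18
    local_given_distant: 0.54
    local_recurrence_after_salvage_5y: 0.13
    distant_after_local_3y: 0.11
    salvage_local: 0.94
    salvage_distant: 0.57
    mort_local_salvaged_5y: 0.5
    mort_local_unsalvaged_5y: 0.7
    mort_distant_5y: 0.8
    mort_local_and_distant_5y: 0.8
    other_cause_mortality_annual: 0.02
  resection:
    overall_g3g4_toxicity: 0.23
    perioperative_death: 0.04
    periop_death_at_salvage: false    # applied at model entry instead
    local_recurrence_cum: {"3": 0.03, "5": 0.05}
    distant_recurrence_cum: {"3": 0.19, "5": 0.21}
    overall_survival: {"3": 0.89, "5": 0.79}
    distant_given_local: 0.17
    local_given_distant: 0.36
    local_recurrence_after_salvage_5y: 0.13
    distant_after_local_3y: 0.11
    salvage_local: 0.59
    salvage_distant: 0.57
    mort_local_salvaged_5y: 0.5
    mort_local_unsalvaged_5y: 0.7
    mort_distant_5y: 0.8
    mort_local_and_distant_5y: 0.8
    other_cause_mortality_annual: 0.02

utilities:
  nom:
    initial_state: 0.80
    long_term_stable: 0.80
    salvage_surgery: 0.70
    local_recurrence: 0.67
    distant_recurrence: 0.70
    local_and_distant: 0.48
    death: 0.0
  resection:
    initial_state: 0.61
    long_term_stable: 0.70
    salvage_surgery: 0.70
    local_recurrence: 0.67
    distant_recurrence: 0.70
    local_and_distant: 0.48
    death: 0.0

strategies:
  nom:
    ostomy: false
    inpatient_nights_primary: 0
    inpatient_nights_salvage: 16
    inpatient_nights_metastasectomy: 5
    # covered ambulatory series: long-course CRT then consolidation CTx
    treatment_series:
      - {label: "CRT", n_drives: 28, covered: true}
      - {label: "consolidation CTx", n_drives: 8, covered: true}
    # intensified surveillance (3-monthly in years 1-2); assumed, calibrated
    followup_visits_per_year: {"1": 6, "2": 6, "3": 3, "4": 2, "5": 2}
    return_to_work_weeks: 8           # assumed, calibrated
  resection:
    ostomy: true
    inpatient_nights_primary: 16
    inpatient_nights_salvage: 16
    inpatient_nights_metastasectomy: 5
    treatment_series:
      - {label: "CRT", n_drives: 28, covered: true}
      - {label: "adjuvant CTx", n_drives: 8, covered: true}
    followup_visits_per_year: {"1": 2, "2": 2, "3": 1, "4": 1, "5": 1}
    return_to_work_weeks: 16          # assumed, calibrated

cost_assumptions:
  copay_units_primary_year: 10        # assumed, calibrated
  copay_units_followup_year: 1        # assumed, calibrated
  copay_units_recurrence_year: 20     # assumed, calibrated
  followup_visits_post_salvage_per_year: 2
  absence_weeks_salvage_local: 26     # temporary disability, assumed
  absence_weeks_salvage_distant: 26   # temporary disability, assumed
  half_cycle_correction: false
  post_salvage_mortality: pathway     # pathway | explicit (see vignette)

# Reference survey cohort marginals (rectal cancer subgroup of a German
# multicentre financial-toxicity survey; counts, SHI subgroup N = 38).
reference_cohort:
  n_total: 44
  age: {median: 67, iqr_low: 58, iqr_high: 75, min: 32, max: 92}
  gender: {female: 19, male: 25}
  shi_insured: 38
  employment: {employed: 12, not_employed: 4, retired: 18, not_reported: 4}
  income_bracket:
    "<1300": 8
    "1300-1700": 4
    "1701-2600": 8
    "2601-3600": 6
    "3601-5000": 5
    ">5000": 0
    not_reported: 7
  income_loss_bracket:
    none: 25
    "<100": 2
    "100-500": 4
    "500-1500": 4
    not_reported: 3
  extra_expense_bracket:
    none: 16
    "<100": 3
    "100-500": 12
    "500-1500": 1
    not_reported: 6
  expense_cause_mentions:            # among the 16 reporting expenses
    copayments: 17
    driving: 10
    medication: 10
    other: 1
  financial_difficulty:
    none: 24
    little: 5
    moderate: 4
    great: 2
    not_reported: 3
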