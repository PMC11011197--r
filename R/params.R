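# Parameter containers: schema-validated YAML profile carrying every number
# the model consumes. The bundled default profile is the published value set;
# assumption-class values are marked "assumed, calibrated" in the file.

.schema <- list(
  top = c("schema_version", "economics", "strata", "transitions", "utilities",
          "strategies", "cost_assumptions", "reference_cohort"),
  economics = c("wtp_per_qaly", "discount_rate_annual", "gross_income_monthly",
                "net_household_income_monthly", "pension_monthly",
                "reduced_earning_capacity_pension_monthly",
                "personal_allowance_per_person", "tax_allowance_per_person",
                "pension_taxable_fraction", "pension_tax_rate",
                "net_conversion_factor", "household_size",
                "copay_rate_general", "copay_rate_chronic", "copay_per_unit",
                "inpatient_copay_cap_annual", "driving_distance_km",
                "driving_rate_per_km", "taxi_copay_per_drive",
                "round_trip_factor", "supplement_monthly", "sick_pay_fraction",
                "full_pay_weeks", "sick_pay_max_weeks", "employment_rate_mixed"),
  stratum = c("label", "cases", "employment_rate", "gross_income_monthly",
              "retired"),
  transition = c("overall_g3g4_toxicity", "perioperative_death",
                 "periop_death_at_salvage", "local_recurrence_cum",
                 "distant_recurrence_cum", "overall_survival",
                 "distant_given_local", "local_given_distant",
                 "local_recurrence_after_salvage_5y", "distant_after_local_3y",
                 "salvage_local", "salvage_distant", "mort_local_salvaged_5y",
                 "mort_local_unsalvaged_5y", "mort_distant_5y",
                 "mort_local_and_distant_5y", "other_cause_mortality_annual"),
  utility = c("initial_state", "long_term_stable", "salvage_surgery",
              "local_recurrence", "distant_recurrence", "local_and_distant",
              "death"),
  strategy = c("ostomy", "inpatient_nights_primary", "inpatient_nights_salvage",
               "inpatient_nights_metastasectomy", "treatment_series",
               "followup_visits_per_year", "return_to_work_weeks"),
  cost_assumptions = c("copay_units_primary_year", "copay_units_followup_year",
                       "copay_units_recurrence_year",
                       "followup_visits_post_salvage_per_year",
                       "absence_weeks_salvage_local",
                       "absence_weeks_salvage_distant",
                       "half_cycle_correction", "post_salvage_mortality"),
  reference_cohort = c("n_total", "age", "gender", "shi_insured", "employment",
                       "income_bracket", "income_loss_bracket",
                       "extra_expense_bracket", "expense_cause_mentions",
                       "financial_difficulty")
)

.fail <- function(key, msg) {
  stop(sprintf("parameter validation failed at '%s': %s", key, msg),
       call. = FALSE)
}

.check_keys <- function(x, allowed, where, required = allowed) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    .fail(paste0(where, "$", unknown[1]), "unknown key")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    .fail(paste0(where, "$", missing[1]), "required key is missing")
  invisible(TRUE)
}

.check_prob <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    .fail(key, sprintf("probability must be a single value in [0, 1], got %s",
                       paste(format(x), collapse = ", ")))
  invisible(TRUE)
}

.check_nonneg <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    .fail(key, "must be a single non-negative number")
  invisible(TRUE)
}

.check_cum_map <- function(x, key, decreasing = FALSE) {
  if (length(x) == 0) .fail(key, "cumulative map is empty")
  yrs <- suppressWarnings(as.numeric(names(x)))
  if (anyNA(yrs) || any(yrs <= 0)) .fail(key, "years must be positive numbers")
  vals <- as.numeric(unlist(x))
  for (v in vals) .check_prob(v, key)
  o <- order(yrs)
  ordered <- if (decreasing) rev(vals[o]) else vals[o]
  if (is.unsorted(ordered))
    .fail(key, sprintf("cumulative %s must be %s in years",
                       if (decreasing) "survival" else "probabilities",
                       if (decreasing) "non-increasing" else "non-decreasing"))
  setNames(vals[o], yrs[o])
}

.validate_transitions <- function(tr, where) {
  .check_keys(tr, .schema$transition, where)
  maps <- c("local_recurrence_cum", "distant_recurrence_cum", "overall_survival")
  for (k in maps)
    tr[[k]] <- .check_cum_map(tr[[k]], paste0(where, "$", k),
                              decreasing = (k == "overall_survival"))
  probs <- setdiff(.schema$transition, c(maps, "periop_death_at_salvage"))
  for (k in probs) .check_prob(tr[[k]], paste0(where, "$", k))
  if (!is.logical(tr$periop_death_at_salvage))
    .fail(paste0(where, "$periop_death_at_salvage"), "must be logical")
  tr
}

.validate_utilities <- function(u, where) {
  .check_keys(u, .schema$utility, where)
  for (k in .schema$utility) .check_prob(u[[k]], paste0(where, "$", k))
  if (u$death != 0) .fail(paste0(where, "$death"), "death utility must be 0")
  u
}

.validate_strategy <- function(s, name, where) {
  .check_keys(s, .schema$strategy, where)
  if (!is.logical(s$ostomy)) .fail(paste0(where, "$ostomy"), "must be logical")
  for (k in c("inpatient_nights_primary", "inpatient_nights_salvage",
              "inpatient_nights_metastasectomy", "return_to_work_weeks"))
    .check_nonneg(s[[k]], paste0(where, "$", k))
  if (name == "nom") {
    if (s$ostomy) .fail(paste0(where, "$ostomy"), "NOM must not carry an ostomy")
    if (s$inpatient_nights_primary != 0)
      .fail(paste0(where, "$inpatient_nights_primary"),
            "NOM has no primary resection stay")
  }
  if (name == "resection" && !s$ostomy)
    .fail(paste0(where, "$ostomy"), "resection strategy implies an ostomy")
  for (ts in s$treatment_series) {
    .check_nonneg(ts$n_drives, paste0(where, "$treatment_series$n_drives"))
    if (!is.logical(ts$covered))
      .fail(paste0(where, "$treatment_series$covered"), "must be logical")
  }
  fv <- s$followup_visits_per_year
  if (!setequal(names(fv), as.character(1:N_CYCLES)))
    .fail(paste0(where, "$followup_visits_per_year"),
          "must give a visit count for each of years 1-5")
  for (k in names(fv)) .check_nonneg(fv[[k]], paste0(where, "$followup_visits_per_year$", k))
  s$followup_visits_per_year <-
    setNames(as.numeric(fv[as.character(1:N_CYCLES)]), 1:N_CYCLES)
  s
}

.validate_economics <- function(ec, where = "economics") {
  .check_keys(ec, .schema$economics, where)
  fracs <- c("discount_rate_annual", "pension_taxable_fraction",
             "pension_tax_rate", "net_conversion_factor", "copay_rate_general",
             "copay_rate_chronic", "sick_pay_fraction", "employment_rate_mixed")
  for (k in fracs) .check_prob(ec[[k]], paste0(where, "$", k))
  for (k in setdiff(.schema$economics, fracs))
    .check_nonneg(ec[[k]], paste0(where, "$", k))
  ec
}

#' Path to the bundled default parameter profile
#'
#' @return Path to the YAML file shipped with the package that carries the
#'   published base-case value set.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "nomcea",
              mustWork = TRUE)
}

#' Load and validate a model parameter profile
#'
#' Reads a YAML parameter profile, validates it against the versioned schema
#' (unknown keys are rejected, probabilities must lie in \[0, 1\], cumulative
#' risk maps must be non-decreasing, monetary values non-negative) and returns
#' a typed parameter container.
#'
#' @param path Path to a YAML profile; defaults to the bundled base-case
#'   profile.
#' @param text YAML given directly as a character string (overrides `path`).
#' @return An object of class `nomcea_params`: a list with elements
#'   `economics`, `strata` (data frame), `transitions` and `utilities` (one
#'   entry per strategy), `strategies`, `cost_assumptions` and
#'   `reference_cohort`.
#' @export
#' @examples
#' p <- load_params()
#' p$transitions$nom$overall_survival[["5"]]
load_params <- function(path = default_config_path(), text = NULL) {
  raw <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (!is.list(raw)) .fail("<document>", "profile is not a YAML mapping")
  .check_keys(raw, .schema$top, "<top>")
  if (!identical(as.integer(raw$schema_version), 1L))
    .fail("schema_version", "unsupported schema version (expected 1)")

  ec <- .validate_economics(raw$economics)

  if (length(raw$strata) == 0) .fail("strata", "at least one stratum required")
  strata <- do.call(rbind, lapply(raw$strata, function(s) {
    .check_keys(s, .schema$stratum, "strata")
    .check_nonneg(s$cases, "strata$cases")
    .check_prob(s$employment_rate, "strata$employment_rate")
    .check_nonneg(s$gross_income_monthly, "strata$gross_income_monthly")
    data.frame(label = s$label, cases = s$cases,
               employment_rate = s$employment_rate,
               gross_income_monthly = s$gross_income_monthly,
               retired = isTRUE(s$retired), stringsAsFactors = FALSE)
  }))

  .check_keys(raw$transitions, STRATEGIES, "transitions")
  trans <- lapply(STRATEGIES, function(a)
    .validate_transitions(raw$transitions[[a]], paste0("transitions$", a)))
  names(trans) <- STRATEGIES

  .check_keys(raw$utilities, STRATEGIES, "utilities")
  utils_ <- lapply(STRATEGIES, function(a)
    .validate_utilities(raw$utilities[[a]], paste0("utilities$", a)))
  names(utils_) <- STRATEGIES

  .check_keys(raw$strategies, STRATEGIES, "strategies")
  strat <- lapply(STRATEGIES, function(a)
    .validate_strategy(raw$strategies[[a]], a, paste0("strategies$", a)))
  names(strat) <- STRATEGIES

  # structural premise: intensified surveillance under organ preservation
  if (!all(strat$nom$followup_visits_per_year >
           strat$resection$followup_visits_per_year))
    .fail("strategies$nom$followup_visits_per_year",
          "NOM surveillance must exceed the resection schedule in every year")

  ca <- raw$cost_assumptions
  .check_keys(ca, .schema$cost_assumptions, "cost_assumptions")
  if (!ca$post_salvage_mortality %in% c("pathway", "explicit"))
    .fail("cost_assumptions$post_salvage_mortality",
          "must be 'pathway' or 'explicit'")
  if (!is.logical(ca$half_cycle_correction))
    .fail("cost_assumptions$half_cycle_correction", "must be logical")
  for (k in setdiff(.schema$cost_assumptions,
                    c("half_cycle_correction", "post_salvage_mortality")))
    .check_nonneg(ca[[k]], paste0("cost_assumptions$", k))

  rc <- raw$reference_cohort
  .check_keys(rc, .schema$reference_cohort, "reference_cohort")

  structure(list(schema_version = 1L, economics = ec, strata = strata,
                 transitions = trans, utilities = utils_, strategies = strat,
                 cost_assumptions = ca, reference_cohort = rc),
            class = "nomcea_params")
}

#' Serialize a parameter profile back to YAML
#'
#' Round-trips losslessly with [load_params()]: writing and re-loading yields
#' an identical container.
#'
#' @param params A `nomcea_params` object.
#' @param path Output file; if `NULL` the YAML text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
write_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "nomcea_params"))
  raw <- list(
    schema_version = params$schema_version,
    economics = params$economics,
    strata = lapply(seq_len(nrow(params$strata)), function(i)
      as.list(params$strata[i, , drop = FALSE])),
    transitions = lapply(params$transitions, function(tr) {
      for (k in c("local_recurrence_cum", "distant_recurrence_cum",
                  "overall_survival"))
        tr[[k]] <- as.list(setNames(as.numeric(tr[[k]]), names(tr[[k]])))
      tr
    }),
    utilities = params$utilities,
    strategies = lapply(params$strategies, function(s) {
      s$followup_visits_per_year <-
        as.list(setNames(as.numeric(s$followup_visits_per_year),
                         names(s$followup_visits_per_year)))
      s
    }),
    cost_assumptions = params$cost_assumptions,
    reference_cohort = params$reference_cohort
  )
  txt <- yaml::as.yaml(raw, precision = 15)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Export a validated parameter profile as JSON
#'
#' @param params A `nomcea_params` object.
#' @param path Output file; if `NULL` the JSON text is returned.
#' @return JSON text, invisibly when written to `path`.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "nomcea_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.nomcea_params <- function(x, ...) {
  cat("<nomcea_params> schema v", x$schema_version, "\n", sep = "")
  cat("  strategies: ", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  WTP ", x$economics$wtp_per_qaly, " EUR/QALY, discount ",
      x$economics$discount_rate_annual * 100, "%/yr\n", sep = "")
  cat("  strata: ", nrow(x$strata), " age bands, ",
      sum(x$strata$cases), " incident cases\n", sep = "")
  invisible(x)
}

# Assumption-class defaults that reports echo so that runs are auditable.
assumed_defaults <- function(params) {
  ca <- params$cost_assumptions
  c(sprintf("net_conversion_factor = %.4f (assumed, calibrated)",
            params$economics$net_conversion_factor),
    sprintf("follow-up visits/yr NOM = %s; resection = %s (assumed)",
            paste(params$strategies$nom$followup_visits_per_year, collapse = "/"),
            paste(params$strategies$resection$followup_visits_per_year,
                  collapse = "/")),
    sprintf("return to work after %d (NOM) / %d (resection) weeks (assumed)",
            params$strategies$nom$return_to_work_weeks,
            params$strategies$resection$return_to_work_weeks),
    sprintf("absence for salvage: local %d wk, distant %d wk (assumed)",
            ca$absence_weeks_salvage_local, ca$absence_weeks_salvage_distant),
    sprintf("co-payment units/yr: primary %d, follow-up %d, recurrence %d (assumed)",
            ca$copay_units_primary_year, ca$copay_units_followup_year,
            ca$copay_units_recurrence_year))
}
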