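# Synthetic survey cohort: reproduces the reference rectal-cancer subgroup
# of a German multicentre financial-toxicity survey from its published
# marginals, so the demographic and cost-model assumptions can be exercised
# without any real patient data. Fields are drawn independently (the source
# publishes marginals only); "not reported" is kept as an explicit category.

INCOME_BRACKETS <- c("<1300", "1300-1700", "1701-2600", "2601-3600",
                     "3601-5000", ">5000", "not_reported")
.bracket_bounds <- data.frame(
  bracket = INCOME_BRACKETS[1:6],
  lower = c(0, 1300, 1701, 2601, 3601, 5001),
  upper = c(1299, 1700, 2600, 3600, 5000, Inf), stringsAsFactors = FALSE)

.props <- function(counts, key) {
  v <- as.numeric(unlist(counts))
  if (any(v < 0) || sum(v) <= 0)
    stop(sprintf("invalid marginal '%s'", key), call. = FALSE)
  setNames(v / sum(v), names(counts))
}

# piecewise-linear quantile function through the published age quartiles
.age_quantile <- function(p, age) {
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- c(age$min, age$iqr_low, age$median, age$iqr_high, age$max)
  stats::approx(qs, vals, xout = p, rule = 2)$y
}

#' Generate a synthetic survey cohort
#'
#' Draws `n` patient records whose marginal distributions match the
#' reference cohort: age from a piecewise-linear quantile function through
#' the published median and interquartile range, and independent
#' categorical draws for gender, insurance status, employment, net
#' household income bracket, loss-of-income bracket, additional-expense
#' bracket, expense causes (multi-select, drawn only for records reporting
#' expenses) and financial difficulty. Survey items are populated only for
#' records insured with a statutory health insurance, mirroring the
#' reference analysis.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param marginals Marginal counts as in
#'   `load_params()$reference_cohort` (the default).
#' @return A data frame of class `nomcea_cohort` with one row per patient.
#' @export
#' @examples
#' coh <- generate_cohort(200, seed = 1)
#' table(coh$income_bracket)
generate_cohort <- function(n, seed = 1L,
                            marginals = load_params()$reference_cohort) {
  stopifnot(n >= 1)
  m <- marginals
  set.seed(seed)

  draw <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)

  age <- .age_quantile(runif(n), m$age)
  gender <- draw(.props(m$gender, "gender"), n)
  shi <- runif(n) < m$shi_insured / m$n_total

  employment <- income <- loss <- expense <- difficulty <-
    rep(NA_character_, n)
  cause_cols <- matrix(NA, n, 4,
                       dimnames = list(NULL, c("cause_copayments",
                                               "cause_driving",
                                               "cause_medication",
                                               "cause_other")))
  idx <- which(shi)
  k <- length(idx)
  if (k > 0) {
    employment[idx] <- draw(.props(m$employment, "employment"), k)
    income[idx] <- draw(.props(m$income_bracket, "income_bracket"), k)
    loss[idx] <- draw(.props(m$income_loss_bracket, "income_loss_bracket"), k)
    expense[idx] <- draw(.props(m$extra_expense_bracket,
                                "extra_expense_bracket"), k)
    difficulty[idx] <- draw(.props(m$financial_difficulty,
                                   "financial_difficulty"), k)

    # multi-select causes among records that reported expenses; mention
    # probabilities are mentions over reporting patients, capped at 1
    n_reporting <- sum(unlist(m$extra_expense_bracket)) -
      m$extra_expense_bracket$none - m$extra_expense_bracket$not_reported
    p_cause <- pmin(1, as.numeric(unlist(m$expense_cause_mentions)) /
                      n_reporting)
    has_exp <- idx[!expense[idx] %in% c("none", "not_reported")]
    cause_cols[idx, ] <- FALSE
    for (j in seq_along(p_cause))
      cause_cols[has_exp, j] <- runif(length(has_exp)) < p_cause[j]
    none_drawn <- has_exp[rowSums(cause_cols[has_exp, , drop = FALSE]) == 0]
    cause_cols[none_drawn, 1] <- TRUE  # at least one cause per reporter
  }

  out <- data.frame(
    age = age, gender = gender, shi_insured = shi, employment = employment,
    income_bracket = income, income_loss_bracket = loss,
    extra_expense_bracket = expense, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cause_cols))
  out$financial_difficulty <- difficulty
  class(out) <- c("nomcea_cohort", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Summarize a synthetic cohort in the reference-table shape
#'
#' Counts and integer-rounded percentages per categorical field (survey
#' items over the SHI subgroup, as in the reference publication), the age
#' quartiles, and expense causes tallied as mentions. Financial difficulty
#' is reported against both the full SHI denominator and the responders-only
#' denominator, since the source uses both.
#'
#' @param records A `nomcea_cohort` data frame.
#' @return A list of data frames (`age`, `gender`, `shi`, plus one per
#'   survey item), class `nomcea_cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    return(structure(list(), class = "nomcea_cohort_summary"))
  tab <- function(x, levels) {
    x <- x[!is.na(x)]
    n <- length(x)
    cnt <- vapply(levels, function(l) sum(x == l), numeric(1))
    data.frame(category = levels, n = cnt,
               percent = round(100 * cnt / n), stringsAsFactors = FALSE)
  }
  shi <- records[isTRUE_vec(records$shi_insured), , drop = FALSE]

  causes <- colSums(shi[, c("cause_copayments", "cause_driving",
                            "cause_medication", "cause_other"),
                        drop = FALSE], na.rm = TRUE)
  fd <- tab(shi$financial_difficulty,
            c("none", "little", "moderate", "great", "not_reported"))
  responders <- sum(fd$n) - fd$n[fd$category == "not_reported"]
  fd$percent_of_responders <- ifelse(
    fd$category == "not_reported", NA,
    round(100 * fd$n / responders))

  structure(list(
    n_total = nrow(records),
    age = data.frame(median = stats::median(records$age),
                     iqr_low = unname(stats::quantile(records$age, 0.25)),
                     iqr_high = unname(stats::quantile(records$age, 0.75))),
    gender = tab(records$gender, c("female", "male")),
    shi = data.frame(n = nrow(shi),
                     percent = round(100 * nrow(shi) / nrow(records))),
    employment = tab(shi$employment,
                     c("employed", "not_employed", "retired", "not_reported")),
    income_bracket = tab(shi$income_bracket, INCOME_BRACKETS),
    income_loss_bracket = tab(shi$income_loss_bracket,
                              c("none", "<100", "100-500", "500-1500",
                                "not_reported")),
    extra_expense_bracket = tab(shi$extra_expense_bracket,
                                c("none", "<100", "100-500", "500-1500",
                                  "not_reported")),
    expense_cause_mentions = data.frame(cause = names(causes),
                                        mentions = as.numeric(causes),
                                        stringsAsFactors = FALSE),
    financial_difficulty = fd), class = "nomcea_cohort_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Check model assumptions against a cohort summary
#'
#' Descriptive comparison (no hypothesis test): reports whether the model's
#' net household income falls inside the cohort's median income bracket and
#' whether the model's employment rate lies near the cohort's employed
#' share.
#'
#' @param summary A `nomcea_cohort_summary`.
#' @param econ Economics parameter list.
#' @return A data frame with one row per check: `check`, `model_value`,
#'   `cohort_value`, `verdict`.
#' @export
consistency_check <- function(summary, econ) {
  if (length(summary) == 0) return(data.frame())
  ib <- summary$income_bracket
  reported <- ib[ib$category != "not_reported", ]
  # median bracket: bracket containing the 50 % point of reported incomes
  cum <- cumsum(reported$n) / sum(reported$n)
  median_bracket <- reported$category[which(cum >= 0.5)[1]]

  nhh <- econ$net_household_income_monthly
  b <- .bracket_bounds
  model_bracket <- b$bracket[nhh >= b$lower & nhh <= b$upper]
  inc_verdict <- if (model_bracket == median_bracket) "inside"
  else if (abs(match(model_bracket, b$bracket) -
               match(median_bracket, b$bracket)) == 1) "adjacent"
  else "outside"

  emp <- summary$employment
  cohort_emp <- emp$n[emp$category == "employed"] / sum(emp$n)
  emp_diff <- abs(cohort_emp - econ$employment_rate_mixed)

  data.frame(
    check = c("net_household_income_bracket", "employment_rate"),
    model_value = c(sprintf("%.0f EUR (-> %s)", nhh, model_bracket),
                    sprintf("%.1f%%", 100 * econ$employment_rate_mixed)),
    cohort_value = c(sprintf("median bracket %s", median_bracket),
                     sprintf("%.1f%%", 100 * cohort_emp)),
    verdict = c(inc_verdict,
                if (emp_diff <= 0.1) "within 10 points" else "divergent"),
    stringsAsFactors = FALSE)
}
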