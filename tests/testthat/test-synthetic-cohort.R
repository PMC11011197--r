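test_that("generation is deterministic per seed", {
  m <- test_params()$reference_cohort
  a <- generate_cohort(500, seed = 5, marginals = m)
  b <- generate_cohort(500, seed = 5, marginals = m)
  expect_identical(a, b)
  c_ <- generate_cohort(500, seed = 6, marginals = m)
  expect_false(identical(a$age, c_$age))
})

test_that("marginals are recovered within binomial bounds at n = 10000", {
  m <- test_params()$reference_cohort
  n <- 10000
  coh <- generate_cohort(n, seed = 2024, marginals = m)

  ci <- function(obs, p, size) abs(obs - p) <= 3 * sqrt(p * (1 - p) / size)
  # insurance status over everyone
  expect_true(ci(mean(coh$shi_insured), 38 / 44, n))
  shi <- coh[coh$shi_insured, ]
  k <- nrow(shi)
  # employment, income, loss-of-income, expenses, difficulty over the
  # insured subgroup
  expect_true(ci(mean(shi$employment == "employed"), 12 / 38, k))
  expect_true(ci(mean(shi$employment == "retired"), 18 / 38, k))
  expect_true(ci(mean(shi$income_loss_bracket == "none"), 25 / 38, k))
  expect_true(ci(mean(shi$extra_expense_bracket == "100-500"), 12 / 38, k))
  expect_true(ci(mean(shi$financial_difficulty == "none"), 24 / 38, k))
  for (br in names(m$income_bracket)) {
    p <- m$income_bracket[[br]] / 38
    expect_true(ci(mean(shi$income_bracket == br), p, k))
  }
  # age distribution hits the published quartiles
  expect_lt(abs(median(coh$age) - 67), 1.5)
  expect_lt(abs(quantile(coh$age, 0.25) - 58), 1.5)
  expect_lt(abs(quantile(coh$age, 0.75) - 75), 1.5)
})

test_that("the median income bracket matches the reference cohort", {
  coh <- generate_cohort(10000, seed = 1, marginals = test_params()$reference_cohort)
  s <- summarize_cohort(coh)
  ib <- s$income_bracket
  reported <- ib[ib$category != "not_reported", ]
  cum <- cumsum(reported$n) / sum(reported$n)
  expect_identical(reported$category[which(cum >= 0.5)[1]], "1701-2600")
})

test_that("degenerate marginals and survey-logic invariants hold", {
  m <- test_params()$reference_cohort
  m$gender <- list(female = 1, male = 0)
  coh <- generate_cohort(200, seed = 9, marginals = m)
  expect_true(all(coh$gender == "female"))

  coh2 <- generate_cohort(2000, seed = 10,
                          marginals = test_params()$reference_cohort)
  shi <- coh2[coh2$shi_insured, ]
  causes <- rowSums(shi[, c("cause_copayments", "cause_driving",
                            "cause_medication", "cause_other")])
  # no causes without expenses; at least one cause when expenses reported
  expect_true(all(causes[shi$extra_expense_bracket == "none"] == 0))
  has <- shi$extra_expense_bracket %in% c("<100", "100-500", "500-1500")
  expect_true(all(causes[has] >= 1))
  # survey items are populated only for the insured subgroup
  out <- coh2[!coh2$shi_insured, ]
  expect_true(all(is.na(out$employment)))
  expect_true(all(is.na(out$income_bracket)))
  # invalid marginals are rejected
  bad <- test_params()$reference_cohort
  bad$gender <- list(female = -1, male = 2)
  expect_error(generate_cohort(10, seed = 1, marginals = bad), "gender")
})

test_that("the summary reports counts, percentages and both difficulty denominators", {
  coh <- generate_cohort(4000, seed = 3, marginals = test_params()$reference_cohort)
  s <- summarize_cohort(coh)
  expect_s3_class(s, "nomcea_cohort_summary")
  expect_equal(s$n_total, 4000)
  expect_equal(sum(s$gender$n), 4000)
  fd <- s$financial_difficulty
  expect_true(all(fd$percent[!is.na(fd$percent)] >= 0))
  expect_true(is.na(fd$percent_of_responders[fd$category == "not_reported"]))
  nr <- fd$n[fd$category == "not_reported"]
  resp <- sum(fd$n) - nr
  expect_equal(fd$percent_of_responders[fd$category == "none"],
               round(100 * fd$n[fd$category == "none"] / resp))

  single <- summarize_cohort(generate_cohort(1, seed = 8))
  expect_equal(single$n_total, 1)
  expect_true(all(single$gender$percent %in% c(0, 100)))

  expect_length(summarize_cohort(NULL), 0)
})

test_that("model assumptions sit inside the cohort's reported ranges", {
  p <- test_params()
  s <- summarize_cohort(generate_cohort(10000, seed = 12,
                                        marginals = p$reference_cohort))
  chk <- consistency_check(s, p$economics)
  expect_equal(nrow(chk), 2)
  # 2580 EUR lies in the 1701-2600 bracket, which is also the cohort median
  expect_identical(chk$verdict[chk$check == "net_household_income_bracket"],
                   "inside")
  # 28.2 % modelled vs ~32 % surveyed employment
  expect_identical(chk$verdict[chk$check == "employment_rate"],
                   "within 10 points")
  expect_equal(nrow(consistency_check(summarize_cohort(NULL),
                                      p$economics)), 0)
})
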