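test_that("driving costs distinguish covered series from uncovered visits", {
  # covered series: taxi co-payment for first and last drive only
  expect_equal(driving_cost(28, covered = TRUE), 10)
  expect_equal(driving_cost(8, covered = TRUE), 10)
  expect_equal(driving_cost(1, covered = TRUE), 5)
  # uncovered: round trip at the per-km rate
  expect_equal(driving_cost(1, covered = FALSE), 2 * 26.3 * 0.2)
  expect_equal(driving_cost(4, covered = FALSE), 4 * 10.52)
  expect_equal(driving_cost(0, covered = TRUE), 0)
  expect_equal(driving_cost(0, covered = FALSE), 0)
  expect_error(driving_cost(-1, covered = FALSE), "non-negative")
})

test_that("co-payments respect the in-patient cap and the exemption limits", {
  econ <- test_params()$economics
  expect_equal(copay_cost(0, 40, econ), 280)      # cap binds
  expect_equal(copay_cost(0, 16, econ), 160)
  expect_equal(copay_cost(12, 16, econ), 280)     # 120 + 160, under the limit
  expect_equal(copay_cost(0, 0, econ), 0)
  # continuous therapy is costed at the chronic limit itself
  expect_equal(copay_cost(0, 0, econ, chronic = TRUE, at_limit = TRUE), 410.64)
  # the applicable exemption limit is never exceeded
  for (units in c(0, 10, 50, 200)) {
    for (chronic in c(FALSE, TRUE)) {
      lim <- copay_exemption_limit(
        econ$gross_income_monthly, econ$household_size,
        econ$personal_allowance_per_person,
        if (chronic) econ$copay_rate_chronic else econ$copay_rate_general)
      expect_lte(copay_cost(units, 30, econ, chronic = chronic), lim)
    }
  }
})

test_that("loss of income follows the sick-pay rules", {
  econ <- test_params()$economics
  expect_equal(income_loss("retired", 52, FALSE, econ), 0)
  expect_equal(income_loss("retired", 0, TRUE, econ), 0)
  # full salary continuation for the first six weeks
  expect_equal(income_loss("employed", 6, FALSE, econ), 0)
  # beyond: 30 % of gross weekly income
  expect_equal(income_loss("employed", 10, FALSE, econ),
               4 * 0.30 * 4409 * 12 / 52, tolerance = 1e-9)
  # sick pay runs out after 72 weeks: longer absences cost no more
  expect_equal(income_loss("employed", 6 + 72, FALSE, econ),
               income_loss("employed", 120, FALSE, econ))
  # the mixed scenario weights the employed loss by the employment rate
  expect_equal(income_loss("mixed", 10, FALSE, econ),
               0.282 * income_loss("employed", 10, FALSE, econ))
  # permanent disability: net income replaced by the reduced pension
  perm <- income_loss("employed", 0, TRUE, econ)
  expect_equal(perm, (4409 * econ$net_conversion_factor - 925) * 12,
               tolerance = 1e-9)
})

test_that("state cost profiles compose the four components correctly", {
  p <- test_params()
  for (scenario in c("retired", "mixed", "employed")) {
    for (strat in c("nom", "resection")) {
      prof <- build_state_costs(strat, p, scenario)
      expect_equal(nrow(prof), 30)
      expect_true(all(prof$total >= 0))
      expect_equal(prof$total,
                   prof$copay_component + prof$driving_component +
                     prof$supplement_component + prof$income_loss_component)
      # death costs nothing
      expect_true(all(prof$total[prof$state == "F"] == 0))
    }
  }

  nom_ret <- build_state_costs("nom", p, "retired")
  # stable year 3 under NOM: surveillance driving only, no income loss
  a3 <- subset(nom_ret, state == "A" & year == 3)
  n_visits <- p$strategies$nom$followup_visits_per_year[[3]]
  expect_equal(a3$driving_component, n_visits * 2 * 26.3 * 0.2)
  expect_equal(a3$income_loss_component, 0)

  res_ret <- build_state_costs("resection", p, "retired")
  # ostomy care and non-prescription supplements: 10 EUR/month
  expect_true(all(subset(res_ret, state == "A")$supplement_component == 120))
  expect_true(all(subset(nom_ret, state == "A")$supplement_component == 0))
})

test_that("structural cost orderings hold state by state", {
  p <- test_params()
  for (scenario in c("retired", "mixed", "employed")) {
    nom <- build_state_costs("nom", p, scenario)
    res <- build_state_costs("resection", p, scenario)
    expect_true(all(res$supplement_component >= nom$supplement_component))
    # intensified surveillance drives NOM's follow-up travel above resection's
    fu <- nom$state == "A"
    expect_true(all(nom$driving_component[fu] >= res$driving_component[fu]))
  }
  for (strat in c("nom", "resection")) {
    emp <- build_state_costs(strat, p, "employed")
    mix <- build_state_costs(strat, p, "mixed")
    ret <- build_state_costs(strat, p, "retired")
    expect_true(all(emp$total >= mix$total))
    expect_true(all(mix$total >= ret$total))
  }
})

test_that("the cost matrix reshapes the profile losslessly", {
  prof <- build_state_costs("nom", test_params(), "mixed")
  m <- state_cost_matrix(prof)
  expect_equal(dim(m), c(6, 5))
  i <- sample(nrow(prof), 10)
  expect_equal(m[cbind(prof$state[i], prof$year[i])], prof$total[i])
})
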