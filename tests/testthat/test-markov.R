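test_that("constant-hazard annualization matches its closed form", {
  expect_equal(annualize(0, 3), 0)
  expect_equal(annualize(0.37, 1), 0.37)
  # a 5-year overall survival of 0.85 implies ~3.2 % annual all-cause risk
  expect_equal(annualize(1 - 0.85, 5), 1 - 0.85^(1/5), tolerance = 1e-12)
  expect_equal(annualize(1 - 0.85, 5), 0.032, tolerance = 1e-3)
  expect_error(annualize(1, 5), "hazard")
  expect_error(annualize(1.2, 5), "\\[0, 1\\]")
  expect_error(annualize(0.5, 0))
})

test_that("transition matrices are stochastic with an absorbing death state", {
  p <- test_params()
  for (strat in c("nom", "resection")) {
    M <- build_matrices(strat, p)
    expect_length(M, 5)
    for (t in 1:5) {
      expect_equal(unname(rowSums(M[[t]])), rep(1, 6), tolerance = 1e-9)
      expect_true(all(M[[t]] >= 0 & M[[t]] <= 1))
      # death is absorbing; no resurrection, no direct A -> B shortcut
      expect_equal(unname(M[[t]]["F", ]), c(0, 0, 0, 0, 0, 1))
      expect_equal(unname(M[[t]]["A", "B"]), 0)
      expect_equal(unname(M[[t]]["E", c("A","B","C","D")]),
                   c(0, 0, 0, 0))
    }
  }
})

test_that("recurrence onset honours the piecewise cumulative anchors", {
  p <- test_params()
  Mn <- build_matrices("nom", p)
  # 2-year cumulative local recurrence 0.21 -> annual 1 - 0.79^(1/2)
  pl1 <- 1 - (1 - 0.21)^(1/2)
  expect_equal(unname(Mn[[1]]["A", "C"]), pl1 * (1 - 0.18), tolerance = 1e-12)
  expect_equal(unname(Mn[[2]]["A", "C"]), pl1 * (1 - 0.18), tolerance = 1e-12)
  # beyond the 2-year anchor the incremental risk to 5 years applies
  pl4 <- 1 - (1 - (0.24 - 0.21) / (1 - 0.21))^(1/3)
  expect_equal(unname(Mn[[4]]["A", "C"]), pl4 * (1 - 0.18), tolerance = 1e-12)

  Mr <- build_matrices("resection", p)
  plr <- 1 - (1 - 0.03)^(1/3)
  expect_equal(unname(Mr[[1]]["A", "C"]), plr * (1 - 0.17), tolerance = 1e-12)
  # resection enters with the perioperative death applied
  init <- attr(Mr, "initial_occupancy")
  expect_equal(unname(init[c("A", "F")]), c(0.96, 0.04))
  expect_equal(unname(attr(Mn, "initial_occupancy")[["A"]]), 1)
})

test_that("salvage routes local recurrence to the post-salvage state", {
  p <- test_params()
  Mn <- build_matrices("nom", p)[[1]]
  # NOM: salvage 0.94 with perioperative death 0.04 at the salvage resection
  raw_b <- 0.94 * 0.96
  raw_sum <- raw_b + annualize(0.11, 3) +
    0.94 * 0.04 + 0.06 * annualize(0.7, 5) + 0.02
  expect_equal(unname(Mn["C", "B"]), raw_b / max(1, raw_sum), tolerance = 1e-12)
  Mr <- build_matrices("resection", p)[[1]]
  expect_equal(unname(Mr["C", "B"]), 0.59, tolerance = 1e-12)
  expect_equal(unname(Mr["D", "B"]), 0.57, tolerance = 1e-12)
})

test_that("cohort accounting matches closed-form totals", {
  # no transitions, utility 1 everywhere: QALYs are the discount-factor sum
  r <- run_cohort(identity_matrices(), flat_utilities(1), zero_costs(),
                  discount_rate = 0.035)
  expect_equal(r$qaly_discounted, sum(1.035^-(1:5)), tolerance = 1e-12)
  expect_equal(r$qaly_undiscounted, 5)
  # scaling utilities scales QALYs
  r08 <- run_cohort(identity_matrices(), flat_utilities(0.8), zero_costs(),
                    discount_rate = 0.035)
  expect_equal(r08$qaly_discounted, 0.8 * sum(1.035^-(1:5)), tolerance = 1e-12)
  # zero discount: discounted equals undiscounted
  p <- test_params()
  M <- build_matrices("nom", p)
  costs <- build_state_costs("nom", p, "mixed")
  r0 <- run_cohort(M, p$utilities$nom, costs, discount_rate = 0)
  expect_equal(r0$qaly_discounted, r0$qaly_undiscounted)
  expect_equal(r0$cost_discounted, r0$cost_undiscounted)
})

test_that("occupancies are distributions and death only accumulates", {
  p <- test_params()
  for (strat in c("nom", "resection")) {
    M <- build_matrices(strat, p)
    r <- run_cohort(M, p$utilities[[strat]],
                    build_state_costs(strat, p, "mixed"))
    expect_equal(unname(rowSums(r$occupancy)), rep(1, 5), tolerance = 1e-9)
    expect_true(all(r$occupancy >= 0 & r$occupancy <= 1))
    expect_true(all(diff(r$occupancy[, "F"]) >= 0))
    expect_lte(r$qaly_discounted, r$qaly_undiscounted)
    expect_lte(r$cost_discounted, r$cost_undiscounted)
  }
})

test_that("discounting strictly decreases totals as the rate rises", {
  p <- test_params()
  M <- build_matrices("nom", p)
  costs <- build_state_costs("nom", p, "mixed")
  rates <- c(0, 0.035, 0.07, 0.15)
  res <- lapply(rates, function(r)
    run_cohort(M, p$utilities$nom, costs, discount_rate = r))
  qalys <- vapply(res, function(x) x$qaly_discounted, numeric(1))
  cost <- vapply(res, function(x) x$cost_discounted, numeric(1))
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(cost) < 0))
})

test_that("five-year mortality is calibrated to the source trials", {
  p <- test_params()
  death <- sapply(c("nom", "resection"), function(strat) {
    M <- build_matrices(strat, p)
    run_cohort(M, p$utilities[[strat]],
               build_state_costs(strat, p, "mixed"))$occupancy[5, "F"]
  })
  expect_lt(abs(death[["nom"]] - 0.15), 0.02)
  expect_lt(abs(death[["resection"]] - 0.20), 0.02)
})

test_that("the microsimulation is seed-deterministic and converges to the cohort", {
  p <- test_params()
  M <- build_matrices("nom", p)
  costs <- build_state_costs("nom", p, "mixed")

  a <- run_microsim(M, p$utilities$nom, costs, n = 5000, seed = 11)
  b <- run_microsim(M, p$utilities$nom, costs, n = 5000, seed = 11)
  expect_identical(a, b)
  c_ <- run_microsim(M, p$utilities$nom, costs, n = 5000, seed = 12)
  expect_false(identical(a$occupancy, c_$occupancy))

  # n = 1: occupancy vectors are indicators
  one <- run_microsim(M, p$utilities$nom, costs, n = 1, seed = 3)
  expect_true(all(one$occupancy %in% c(0, 1)))
  expect_equal(unname(rowSums(one$occupancy)), rep(1, 5))

  # Monte-Carlo agreement with the deterministic expectation at 3 sigma
  n <- 20000
  ms <- run_microsim(M, p$utilities$nom, costs, n = n, seed = 99)
  det <- run_cohort(M, p$utilities$nom, costs)
  bound <- 3 * sqrt(det$occupancy * (1 - det$occupancy) / n)
  expect_true(all(abs(ms$occupancy - det$occupancy) <= bound + 1e-12))
})

test_that("tidy occupancy export matches the result matrix", {
  p <- test_params()
  r <- run_cohort(build_matrices("nom", p), p$utilities$nom,
                  build_state_costs("nom", p, "mixed"))
  df <- occupancy_df(r)
  expect_equal(nrow(df), 30)
  expect_equal(df$fraction[df$cycle == 5 & df$state == "F"],
               unname(r$occupancy[5, "F"]))
})
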