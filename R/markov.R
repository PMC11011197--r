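# Markov engine: per-cycle transition matrices from the published cumulative
# risk anchors, the deterministic cohort evaluation, and the seeded
# microsimulation with discounted cost and QALY accounting.

#' Convert a cumulative probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p_cum)^(1/horizon)`.
#'
#' @param p_cum Cumulative probability over `horizon_years` (in \[0, 1)).
#' @param horizon_years Horizon in years (> 0).
#' @return The equivalent annual (per-cycle) probability.
#' @export
#' @examples
#' annualize(0.15, 5)   # annual all-cause risk behind a 5-year OS of 0.85
annualize <- function(p_cum, horizon_years) {
  stopifnot(horizon_years > 0)
  if (any(p_cum < 0 | p_cum > 1)) stop("p_cum must be in [0, 1]", call. = FALSE)
  if (any(p_cum == 1))
    stop("p_cum = 1 has no finite constant hazard", call. = FALSE)
  1 - (1 - p_cum)^(1 / horizon_years)
}

# Piecewise-constant hazard honouring cumulative anchors at 2/3/5 years:
# within the first interval the annualized first anchor applies; between
# anchors the conditional incremental risk (c2 - c1)/(1 - c1) is annualized
# over the interval length; beyond the last anchor the last rate persists.
piecewise_annual <- function(anchors, year) {
  yrs <- as.numeric(names(anchors))
  cum <- as.numeric(anchors)
  o <- order(yrs)
  yrs <- yrs[o]; cum <- cum[o]
  prev_y <- 0; prev_c <- 0
  for (i in seq_along(yrs)) {
    if (year <= yrs[i]) {
      inc <- (cum[i] - prev_c) / (1 - prev_c)
      return(annualize(inc, yrs[i] - prev_y))
    }
    prev_y <- yrs[i]; prev_c <- cum[i]
  }
  n <- length(yrs)
  if (n == 1) return(annualize(cum[1], yrs[1]))
  inc <- (cum[n] - cum[n - 1]) / (1 - cum[n - 1])
  annualize(inc, yrs[n] - yrs[n - 1])
}

#' Build the per-cycle transition matrices of one strategy
#'
#' One 6 x 6 stochastic matrix per cycle year. Recurrence onset from stable
#' disease follows the piecewise-annualized cumulative local and distant
#' risks, split into the combined state for synchronous presentation using
#' the conditional co-occurrence fractions. Local recurrence is salvaged
#' with the published probability (perioperative death applied at salvage
#' where configured); unsalvaged local recurrence and distant/combined
#' recurrence die at the annualized state-specific 5-year mortalities, and
#' other-cause mortality acts as a competing exit everywhere. Rows whose
#' raw exits exceed 1 are renormalized; any residual is assigned to
#' remaining in the state.
#'
#' @param strategy `"nom"` or `"resection"`.
#' @param params A `nomcea_params` object.
#' @return A `nomcea_matrices` list of five 6 x 6 matrices with attributes
#'   `strategy` and `initial_occupancy`.
#' @export
#' @examples
#' M <- build_matrices("nom", load_params())
#' rowSums(M[[1]])
build_matrices <- function(strategy = c("nom", "resection"), params) {
  strategy <- match.arg(strategy)
  tp <- params$transitions[[strategy]]
  post_salvage <- params$cost_assumptions$post_salvage_mortality
  oc <- tp$other_cause_mortality_annual

  mats <- vector("list", N_CYCLES)
  for (t in seq_len(N_CYCLES)) {
    pl <- piecewise_annual(tp$local_recurrence_cum, t)
    pd <- piecewise_annual(tp$distant_recurrence_cum, t)
    dp <- if (tp$periop_death_at_salvage) tp$perioperative_death else 0

    M <- matrix(0, N_STATES, N_STATES,
                dimnames = list(STATE_CODES, STATE_CODES))
    # A: stable disease -------------------------------------------------
    M["A", "C"] <- pl * (1 - tp$distant_given_local)
    M["A", "D"] <- pd * (1 - tp$local_given_distant)
    M["A", "E"] <- pl * tp$distant_given_local + pd * tp$local_given_distant
    M["A", "F"] <- oc
    # B: stable after successful salvage --------------------------------
    M["B", "C"] <- annualize(tp$local_recurrence_after_salvage_5y, 5)
    M["B", "F"] <- oc +
      if (post_salvage == "explicit") annualize(tp$mort_local_salvaged_5y, 5) else 0
    # C: local recurrence (salvage attempted here) ----------------------
    M["C", "B"] <- tp$salvage_local * (1 - dp)
    M["C", "E"] <- annualize(tp$distant_after_local_3y, 3)
    M["C", "F"] <- tp$salvage_local * dp +
      (1 - tp$salvage_local) * annualize(tp$mort_local_unsalvaged_5y, 5) + oc
    # D: distant recurrence (metastasectomy where salvageable) ----------
    M["D", "B"] <- tp$salvage_distant
    M["D", "F"] <- (1 - tp$salvage_distant) * annualize(tp$mort_distant_5y, 5) + oc
    # E: combined recurrence --------------------------------------------
    M["E", "F"] <- annualize(tp$mort_local_and_distant_5y, 5) + oc
    # F: death is absorbing ---------------------------------------------
    M["F", "F"] <- 1

    for (s in setdiff(STATE_CODES, "F")) {
      tot <- sum(M[s, ])
      if (tot > 1.25)
        warning(sprintf(
          "%s cycle %d: raw exits from state %s sum to %.3f (parameter tension)",
          strategy, t, s, tot))
      if (tot > 1) M[s, ] <- M[s, ] / tot
      else M[s, s] <- 1 - tot
    }
    mats[[t]] <- M
  }

  init <- c(1, 0, 0, 0, 0, 0)
  if (!tp$periop_death_at_salvage) {
    # perioperative death of the primary resection at model entry
    init <- c(1 - tp$perioperative_death, 0, 0, 0, 0, tp$perioperative_death)
  }
  structure(mats, class = "nomcea_matrices", strategy = strategy,
            initial_occupancy = setNames(init, STATE_CODES))
}

# utility per state for a given cycle: the initial-state weight applies to
# stable disease in cycle 1 only, the long-term weight thereafter
utility_vector <- function(utilities, cycle) {
  c(A = if (cycle == 1) utilities$initial_state else utilities$long_term_stable,
    B = utilities$salvage_surgery,
    C = utilities$local_recurrence,
    D = utilities$distant_recurrence,
    E = utilities$local_and_distant,
    F = utilities$death)
}

.accumulate <- function(occupancy, util_by_cycle, cost_matrix, discount_rate,
                        half_cycle, init) {
  qaly_d <- qaly_u <- cost_d <- cost_u <- 0
  prev <- init
  for (t in seq_len(N_CYCLES)) {
    occ <- occupancy[t, ]
    eff_occ <- if (half_cycle) (prev + occ) / 2 else occ
    disc <- (1 + discount_rate)^(-t)
    q <- sum(eff_occ * util_by_cycle[[t]])
    cst <- sum(eff_occ * cost_matrix[, t])
    qaly_u <- qaly_u + q;        qaly_d <- qaly_d + q * disc
    cost_u <- cost_u + cst;      cost_d <- cost_d + cst * disc
    prev <- occ
  }
  list(qaly_discounted = qaly_d, qaly_undiscounted = qaly_u,
       cost_discounted = cost_d, cost_undiscounted = cost_u)
}

.make_result <- function(matrices, occupancy, totals, engine, n = NA_integer_,
                         seed = NA_integer_, scenario = NA_character_) {
  structure(list(
    strategy = attr(matrices, "strategy"), scenario = scenario,
    engine = engine, occupancy = occupancy,
    cost_discounted = totals$cost_discounted,
    cost_undiscounted = totals$cost_undiscounted,
    qaly_discounted = totals$qaly_discounted,
    qaly_undiscounted = totals$qaly_undiscounted,
    n_simulated = n, seed = seed), class = "nomcea_result")
}

#' Deterministic cohort evaluation
#'
#' Propagates the expected state occupancy through the five cycles
#' (`occ_t = occ_{t-1} M_t`), accumulating per-cycle utilities and annual
#' state costs discounted at `(1 + r)^-t`. End-of-cycle accounting by
#' default; a half-cycle correction (averaging the occupancy at the cycle
#' boundaries) is available as a switch.
#'
#' @param matrices A `nomcea_matrices` object from [build_matrices()].
#' @param utilities The strategy's utility list (`params$utilities$nom` etc).
#' @param state_costs A `nomcea_state_costs` profile or a 6 x 5 cost matrix.
#' @param discount_rate Annual discount rate (default 0.035).
#' @param half_cycle Apply the half-cycle correction?
#' @return A `nomcea_result` with the per-cycle occupancy matrix and
#'   discounted and undiscounted cost and QALY totals.
#' @export
run_cohort <- function(matrices, utilities, state_costs,
                       discount_rate = 0.035, half_cycle = FALSE) {
  stopifnot(inherits(matrices, "nomcea_matrices"))
  cost_m <- if (is.matrix(state_costs)) state_costs else state_cost_matrix(state_costs)
  scenario <- if (is.data.frame(state_costs)) state_costs$scenario[1] else NA_character_
  init <- attr(matrices, "initial_occupancy")
  occupancy <- matrix(NA_real_, N_CYCLES, N_STATES,
                      dimnames = list(seq_len(N_CYCLES), STATE_CODES))
  occ <- init
  for (t in seq_len(N_CYCLES)) {
    occ <- as.numeric(occ %*% matrices[[t]])
    occupancy[t, ] <- occ
  }
  utils_by_cycle <- lapply(seq_len(N_CYCLES), utility_vector,
                           utilities = utilities)
  totals <- .accumulate(occupancy, utils_by_cycle, cost_m, discount_rate,
                        half_cycle, init)
  .make_result(matrices, occupancy, totals, "cohort", scenario = scenario)
}

#' Markov microsimulation
#'
#' Samples `n` independent patient trajectories from the per-cycle matrix
#' rows with identical cost and QALY accounting to [run_cohort()]. Fully
#' reproducible for a fixed seed.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated patients.
#' @param seed Integer seed for the single random generator.
#' @return A `nomcea_result`; `occupancy` holds the observed state
#'   fractions per cycle.
#' @export
run_microsim <- function(matrices, utilities, state_costs, n = 100000L,
                         seed = 1L, discount_rate = 0.035,
                         half_cycle = FALSE) {
  stopifnot(inherits(matrices, "nomcea_matrices"), n >= 1)
  cost_m <- if (is.matrix(state_costs)) state_costs else state_cost_matrix(state_costs)
  scenario <- if (is.data.frame(state_costs)) state_costs$scenario[1] else NA_character_
  init <- attr(matrices, "initial_occupancy")

  set.seed(seed)
  state <- sample.int(N_STATES, n, replace = TRUE, prob = init)
  occupancy <- matrix(NA_real_, N_CYCLES, N_STATES,
                      dimnames = list(seq_len(N_CYCLES), STATE_CODES))
  for (t in seq_len(N_CYCLES)) {
    cum <- t(apply(matrices[[t]], 1, cumsum))
    u <- runif(n)
    nxt <- integer(n)
    for (s in seq_len(N_STATES)) {
      idx <- which(state == s)
      if (length(idx) > 0)
        nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    state <- nxt
    occupancy[t, ] <- tabulate(state, N_STATES) / n
  }

  utils_by_cycle <- lapply(seq_len(N_CYCLES), utility_vector,
                           utilities = utilities)
  # per-patient rewards are state-by-cycle constants, so the aggregate equals
  # the accounting applied to the observed occupancy fractions
  totals <- .accumulate(occupancy, utils_by_cycle, cost_m, discount_rate,
                        half_cycle, init)
  .make_result(matrices, occupancy, totals, "microsim", n = as.integer(n),
               seed = as.integer(seed), scenario = scenario)
}

#' @export
print.nomcea_result <- function(x, ...) {
  cat(sprintf("<nomcea_result> %s (%s%s)\n", x$strategy, x$engine,
              if (!is.na(x$n_simulated))
                sprintf(", n = %d, seed = %d", x$n_simulated, x$seed) else ""))
  if (!is.na(x$scenario)) cat("  scenario:", x$scenario, "\n")
  cat(sprintf("  discounted:   %8.2f EUR  %6.4f QALY\n",
              x$cost_discounted, x$qaly_discounted))
  cat(sprintf("  undiscounted: %8.2f EUR  %6.4f QALY\n",
              x$cost_undiscounted, x$qaly_undiscounted))
  cat(sprintf("  death occupancy, year 5: %.4f\n",
              x$occupancy[N_CYCLES, "F"]))
  invisible(x)
}

#' Tidy occupancy trajectories
#'
#' @param result A `nomcea_result`.
#' @return A data frame with columns `cycle`, `state`, `fraction`.
#' @export
occupancy_df <- function(result) {
  stopifnot(inherits(result, "nomcea_result"))
  data.frame(
    cycle = rep(seq_len(N_CYCLES), each = N_STATES),
    state = rep(STATE_CODES, times = N_CYCLES),
    fraction = as.numeric(t(result$occupancy)),
    stringsAsFactors = FALSE)
}
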