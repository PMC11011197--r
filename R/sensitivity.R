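# One-way threshold sensitivity analysis: because NMB is affine in both
# cost and effectiveness, the equivalence points are available in closed
# form; sweeps produce the NMB-versus-cost lines with the crossover
# annotated.

#' Cost at which the strategies' NMBs become equivalent
#'
#' Solving `WTP x E_self - cost = NMB_other` for cost. A negative threshold
#' means no non-negative cost makes the strategies equivalent (the
#' comparator can never be matched by cost reduction alone).
#'
#' @param wtp Willingness to pay per QALY (EUR, > 0).
#' @param eff_self Effectiveness of the strategy being varied (QALY).
#' @param nmb_other Comparator NMB (EUR).
#' @return A list with `value` (EUR) and `feasible` (`value >= 0`).
#' @export
#' @examples
#' cost_threshold(6000, 3.87, 13128)   # 10092
cost_threshold <- function(wtp, eff_self, nmb_other) {
  stopifnot(wtp > 0)
  v <- wtp * eff_self - nmb_other
  list(value = v, feasible = v >= 0)
}

#' Effectiveness at which the strategies' NMBs become equivalent
#'
#' Solving `WTP x qaly - cost_self = NMB_other` for the QALY value. Values
#' above `max_qaly` (5 QALYs over the five-year horizon) are flagged
#' infeasible rather than clamped.
#'
#' @inheritParams cost_threshold
#' @param cost_self Cost of the strategy being varied (EUR).
#' @param max_qaly Largest attainable effectiveness on the horizon.
#' @return A list with `value` (QALY), `rounded` (2 decimals) and
#'   `feasible` (`value <= max_qaly`).
#' @export
#' @examples
#' qaly_threshold(6000, 4711, 13128)   # 2.97 QALYs
qaly_threshold <- function(wtp, cost_self, nmb_other, max_qaly = 5) {
  stopifnot(wtp > 0)
  v <- (cost_self + nmb_other) / wtp
  list(value = v, rounded = round(v, 2), feasible = v <= max_qaly)
}

#' Threshold table for both strategies and all scenarios
#'
#' For every scenario, reports the base effectiveness and cost of each
#' strategy together with the QALY and cost equivalence points against the
#' other strategy's base NMB.
#'
#' @param inputs Data frame with columns `scenario`, `cost_nom`,
#'   `cost_resection`, `eff_nom`, `eff_resection`.
#' @param wtp Willingness to pay per QALY (EUR).
#' @return Data frame with one row per strategy and scenario and columns
#'   `base_qaly`, `qaly_equiv`, `qaly_feasible`, `base_cost`, `cost_equiv`,
#'   `cost_feasible`.
#' @export
threshold_table <- function(inputs, wtp) {
  rows <- list()
  for (i in seq_len(nrow(inputs))) {
    n_nom <- nmb(wtp, inputs$eff_nom[i], inputs$cost_nom[i])
    n_res <- nmb(wtp, inputs$eff_resection[i], inputs$cost_resection[i])
    for (strat in STRATEGIES) {
      self_eff <- if (strat == "nom") inputs$eff_nom[i] else inputs$eff_resection[i]
      self_cost <- if (strat == "nom") inputs$cost_nom[i] else inputs$cost_resection[i]
      other <- if (strat == "nom") n_res else n_nom
      qt <- qaly_threshold(wtp, self_cost, other)
      ct <- cost_threshold(wtp, self_eff, other)
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strat, scenario = inputs$scenario[i],
        base_qaly = self_eff, qaly_equiv = qt$value,
        qaly_feasible = qt$feasible,
        base_cost = self_cost, cost_equiv = ct$value,
        cost_feasible = ct$feasible, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' NMB-versus-cost sweep
#'
#' The NMB of the varied strategy falls linearly with its cost,
#' `NMB = WTP x E_self - cost`; each grid point is flagged by whether the
#' varied strategy still beats the comparator NMB, and the crossover cost
#' (if any) is attached as an attribute.
#'
#' @param cost_grid Numeric vector of costs to sweep (EUR).
#' @param wtp Willingness to pay per QALY (EUR).
#' @param eff_self Effectiveness of the varied strategy (QALY).
#' @param nmb_other Comparator NMB (EUR); `NULL` for a sweep without a
#'   comparator.
#' @return Data frame `cost`, `nmb`, `dominant`; attribute `crossover`.
#' @export
nmb_sweep <- function(cost_grid, wtp, eff_self, nmb_other = NULL) {
  if (length(cost_grid) == 0) stop("empty cost grid", call. = FALSE)
  vals <- wtp * eff_self - cost_grid
  out <- data.frame(cost = cost_grid, nmb = vals,
                    dominant = if (is.null(nmb_other)) NA else vals > nmb_other)
  attr(out, "crossover") <-
    if (is.null(nmb_other)) NA_real_ else cost_threshold(wtp, eff_self, nmb_other)$value
  out
}
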