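# Cost-effectiveness arithmetic: ICER, net monetary benefit, incremental
# NMB and dominance classification for two strategies.

#' Net monetary benefit
#'
#' `NMB = WTP x E - C`: the monetised value of the health gained minus the
#' cost borne.
#'
#' @param wtp Willingness to pay per QALY (EUR, > 0).
#' @param eff Effectiveness in QALYs.
#' @param cost Cost in EUR.
#' @return NMB in EUR.
#' @export
#' @examples
#' nmb(6000, 3.87, 4711)   # 18509
nmb <- function(wtp, eff, cost) {
  stopifnot(wtp > 0)
  wtp * eff - cost
}

#' Incremental net monetary benefit
#'
#' @param nmb_a,nmb_b NMB of the two strategies (EUR).
#' @return `nmb_a - nmb_b` in EUR.
#' @export
inmb <- function(nmb_a, nmb_b) nmb_a - nmb_b

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (C_nom - C_res) / (E_nom - E_res)`. With equal effectiveness the
#' ratio is undefined and `NA` is returned with the dominance attribute
#' still classified. When one strategy is both cheaper and at least as
#' effective (with one inequality strict) it dominates.
#'
#' @param cost_nom,cost_resection Costs per strategy (EUR).
#' @param eff_nom,eff_resection Effectiveness per strategy (QALY).
#' @return A list with elements `icer` (EUR/QALY or `NA`) and `dominance`
#'   (`"nom_dominant"`, `"resection_dominant"` or `"tradeoff"`).
#' @export
#' @examples
#' icer(4711, 6252, 3.87, 3.23)   # about -2408, NOM dominant
icer <- function(cost_nom, cost_resection, eff_nom, eff_resection) {
  d_cost <- cost_nom - cost_resection
  d_eff <- eff_nom - eff_resection
  dominance <-
    if (cost_nom <= cost_resection && eff_nom >= eff_resection &&
        (cost_nom < cost_resection || eff_nom > eff_resection)) "nom_dominant"
    else if (cost_resection <= cost_nom && eff_resection >= eff_nom &&
             (cost_resection < cost_nom || eff_resection > eff_nom)) "resection_dominant"
    else "tradeoff"
  value <- if (d_eff == 0) NA_real_ else d_cost / d_eff
  list(icer = value, dominance = dominance)
}

#' Full two-strategy cost-effectiveness comparison
#'
#' Computes the ICER, both NMBs, the incremental NMB and the dominance
#' classification from aggregate cost/effectiveness pairs.
#'
#' @inheritParams icer
#' @param wtp Willingness to pay per QALY (EUR).
#' @return An object of class `nomcea_cea`: list with `icer`, `dominance`,
#'   `nmb_nom`, `nmb_resection`, `inmb`, `delta_cost`, `delta_eff` and the
#'   inputs.
#' @export
#' @examples
#' cea_compare(4711, 6252, 3.87, 3.23, 6000)
cea_compare <- function(cost_nom, cost_resection, eff_nom, eff_resection,
                        wtp) {
  vals <- c(cost_nom, cost_resection, eff_nom, eff_resection, wtp)
  if (any(!is.finite(vals))) stop("non-finite CEA input", call. = FALSE)
  stopifnot(wtp > 0)
  ic <- icer(cost_nom, cost_resection, eff_nom, eff_resection)
  n_nom <- nmb(wtp, eff_nom, cost_nom)
  n_res <- nmb(wtp, eff_resection, cost_resection)
  structure(list(
    icer = ic$icer, dominance = ic$dominance,
    nmb_nom = n_nom, nmb_resection = n_res, inmb = inmb(n_nom, n_res),
    delta_cost = cost_nom - cost_resection,
    delta_eff = eff_nom - eff_resection,
    inputs = list(cost_nom = cost_nom, cost_resection = cost_resection,
                  eff_nom = eff_nom, eff_resection = eff_resection,
                  wtp = wtp)), class = "nomcea_cea")
}

#' @export
print.nomcea_cea <- function(x, ...) {
  cat("<nomcea_cea>\n")
  cat(sprintf("  delta cost %.2f EUR, delta eff %.4f QALY\n",
              x$delta_cost, x$delta_eff))
  cat(sprintf("  ICER: %s EUR/QALY (%s)\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.1f", x$icer),
              x$dominance))
  cat(sprintf("  NMB: NOM %.2f, resection %.2f, iNMB %.2f EUR\n",
              x$nmb_nom, x$nmb_resection, x$inmb))
  invisible(x)
}

#' Scenario-level cost-effectiveness table
#'
#' Builds the base-case results table (strategy x scenario with QALY, cost,
#' delta cost, ICER, NMB, iNMB) from per-scenario aggregate inputs.
#'
#' @param inputs A data frame with columns `scenario`, `cost_nom`,
#'   `cost_resection`, `eff_nom`, `eff_resection`.
#' @param wtp Willingness to pay per QALY (EUR).
#' @return A data frame with one row per strategy and scenario.
#' @export
cea_table <- function(inputs, wtp) {
  rows <- list()
  for (i in seq_len(nrow(inputs))) {
    x <- cea_compare(inputs$cost_nom[i], inputs$cost_resection[i],
                     inputs$eff_nom[i], inputs$eff_resection[i], wtp)
    rows[[length(rows) + 1]] <- data.frame(
      strategy = c("nom", "resection"), scenario = inputs$scenario[i],
      qaly = c(inputs$eff_nom[i], inputs$eff_resection[i]),
      cost = c(inputs$cost_nom[i], inputs$cost_resection[i]),
      delta_cost = c(x$delta_cost, NA), icer = c(x$icer, NA),
      nmb = c(x$nmb_nom, x$nmb_resection), inmb = c(x$inmb, NA),
      dominance = c(x$dominance, NA), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
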