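# End-to-end runners and report writers. Two entry points: the full model
# (engine -> costs -> CEA -> thresholds) and a CEA-only path that computes
# the comparison tables from user-supplied aggregates, so the exact
# closed-form layer is usable independently of the assumption-laden cost
# layer.

#' Run the full base case
#'
#' Builds transition matrices and state costs for both strategies from a
#' parameter profile, runs the chosen engine, and derives the
#' cost-effectiveness and threshold tables. All assumption-class defaults
#' in force are echoed as messages. When `out_dir` is given, tidy CSV/JSON
#' outputs and a run manifest are written.
#'
#' @param params A `nomcea_params` object (default: bundled profile).
#' @param scenario Employment scenario (`"mixed"`, `"employed"`,
#'   `"retired"`).
#' @param engine `"cohort"` (deterministic) or `"microsim"`.
#' @param seed Seed for the microsimulation engine.
#' @param n Number of simulated patients for the microsimulation.
#' @param out_dir Optional output directory.
#' @param quiet Suppress the assumption echo?
#' @return A list (`nomcea_bundle`) with elements `results` (per strategy),
#'   `cea`, `thresholds`, `occupancy`, `state_costs` and `manifest`.
#' @export
run_base_case <- function(params = load_params(),
                          scenario = c("mixed", "employed", "retired"),
                          engine = c("cohort", "microsim"),
                          seed = 1L, n = 100000L, out_dir = NULL,
                          quiet = FALSE) {
  stopifnot(inherits(params, "nomcea_params"))
  scenario <- match.arg(scenario)
  engine <- match.arg(engine)
  if (!quiet)
    for (line in assumed_defaults(params))
      message("assumption in force: ", line)

  r <- params$economics$discount_rate_annual
  hc <- params$cost_assumptions$half_cycle_correction
  results <- costs <- list()
  for (strat in STRATEGIES) {
    M <- build_matrices(strat, params)
    costs[[strat]] <- build_state_costs(strat, params, scenario)
    results[[strat]] <- if (engine == "cohort")
      run_cohort(M, params$utilities[[strat]], costs[[strat]], r, hc)
    else
      run_microsim(M, params$utilities[[strat]], costs[[strat]], n = n,
                   seed = seed, discount_rate = r, half_cycle = hc)
  }

  inputs <- data.frame(
    scenario = scenario,
    cost_nom = results$nom$cost_discounted,
    cost_resection = results$resection$cost_discounted,
    eff_nom = results$nom$qaly_discounted,
    eff_resection = results$resection$qaly_discounted)
  wtp <- params$economics$wtp_per_qaly
  bundle <- list(
    results = results,
    cea = cea_table(inputs, wtp),
    thresholds = threshold_table(inputs, wtp),
    occupancy = do.call(rbind, lapply(STRATEGIES, function(s)
      cbind(strategy = s, occupancy_df(results[[s]])))),
    state_costs = do.call(rbind, costs),
    manifest = run_manifest(params, engine, seed, n, scenario))
  class(bundle) <- "nomcea_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' CEA and threshold tables from aggregate inputs
#'
#' Bypasses the engine: computes the full comparison and threshold block
#' from user-supplied aggregate costs and effectiveness, the path on which
#' the closed-form arithmetic is exactly reproducible.
#'
#' @param cost_nom,cost_resection Aggregate costs (EUR).
#' @param eff_nom,eff_resection Aggregate effectiveness (QALY).
#' @param wtp Willingness to pay per QALY (EUR).
#' @param scenario Label attached to the output rows.
#' @return A list with `cea` and `thresholds` data frames.
#' @export
#' @examples
#' run_cea_only(4711, 6252, 3.87, 3.23, 6000)$cea
run_cea_only <- function(cost_nom, cost_resection, eff_nom, eff_resection,
                         wtp, scenario = "all") {
  vals <- c(cost_nom, cost_resection, eff_nom, eff_resection, wtp)
  if (any(!is.finite(vals))) stop("non-finite CEA input", call. = FALSE)
  inputs <- data.frame(scenario = scenario, cost_nom = cost_nom,
                       cost_resection = cost_resection, eff_nom = eff_nom,
                       eff_resection = eff_resection)
  list(cea = cea_table(inputs, wtp),
       thresholds = threshold_table(inputs, wtp))
}

#' Run manifest
#'
#' Identifies a run: package version, parameter-set hash, engine, seed,
#' simulation size and scenario. Identical manifests imply bit-identical
#' outputs for the deterministic stages.
#'
#' @param params A `nomcea_params` object.
#' @param engine,seed,n,scenario Run coordinates.
#' @return A list.
#' @export
run_manifest <- function(params, engine, seed, n, scenario) {
  list(package = "nomcea",
       version = as.character(utils::packageVersion("nomcea")),
       param_hash = rlang::hash(unclass(params)),
       engine = engine, seed = as.integer(seed), n = as.integer(n),
       scenario = scenario,
       assumed_defaults = assumed_defaults(params))
}

#' Write a result bundle to disk
#'
#' Tidy CSVs (CEA table, threshold table, occupancy trajectories, state
#' cost profile) plus a JSON manifest.
#'
#' @param bundle A `nomcea_bundle` from [run_base_case()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cea = file.path(out_dir, "cea_table.csv"),
    thresholds = file.path(out_dir, "threshold_table.csv"),
    occupancy = file.path(out_dir, "occupancy.csv"),
    state_costs = file.path(out_dir, "state_costs.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(bundle$cea, paths["cea"], row.names = FALSE)
  write.csv(bundle$thresholds, paths["thresholds"], row.names = FALSE)
  write.csv(bundle$occupancy, paths["occupancy"], row.names = FALSE)
  write.csv(bundle$state_costs, paths["state_costs"], row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE,
                              pretty = TRUE), paths["manifest"])
  invisible(paths)
}

#' @export
print.nomcea_bundle <- function(x, ...) {
  cat("<nomcea_bundle>", x$manifest$engine, "engine, scenario",
      x$manifest$scenario, "\n")
  for (s in STRATEGIES)
    cat(sprintf("  %-9s cost %9.2f EUR  QALY %6.4f  death(y5) %.4f\n", s,
                x$results[[s]]$cost_discounted,
                x$results[[s]]$qaly_discounted,
                x$results[[s]]$occupancy[N_CYCLES, "F"]))
  ce <- x$cea[x$cea$strategy == "nom", ]
  cat(sprintf("  iNMB %9.2f EUR (%s)\n", ce$inmb, ce$dominance))
  invisible(x)
}
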