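write_json_flat <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: timestamp, package version,
#' md5 digests of the inputs, the seed, a configuration snapshot, and the
#' name and digest of every file written. Digests are recomputable with
#' `tools::md5sum()`, making reruns auditable.
#'
#' @param out_dir directory the outputs live in.
#' @param inputs named character vector of input file paths.
#' @param outputs character vector of output file paths.
#' @param seed integer seed used (NA for deterministic commands).
#' @param config the `model_config` snapshot.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(out_dir, inputs, outputs, seed = NA, config = NULL) {
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "dmecea",
    version = as.character(utils::packageVersion("dmecea")),
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = config[!vapply(config, is.null, logical(1))],
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  write_json_flat(manifest, file.path(out_dir, "run_manifest.json"))
}

ce_result_flat <- function(res) {
  list(
    reference_arm = res$arms$arm[1],
    intervention_arm = res$arms$arm[2],
    cost_reference = res$arms$cost[1],
    qaly_reference = res$arms$qaly[1],
    cost_intervention = res$arms$cost[2],
    qaly_intervention = res$arms$qaly[2],
    delta_cost = res$delta_cost,
    delta_qaly = res$delta_qaly,
    icer = if (is.na(res$icer)) NULL else round(res$icer),
    cost_per_qaly_ratio = res$ratio,
    dominance = if (is.na(res$dominance)) "none" else res$dominance
  )
}

#' Deterministic (reference-case) analysis command
#'
#' Loads a parameter file, optionally applies overrides, runs the two-arm
#' cohort model, and writes the incremental results table
#' (`ce_result.json`), one trace CSV per arm, and a run manifest.
#'
#' @param params_path parameter file path.
#' @param out_dir output directory (created if missing).
#' @param overrides named list of `path = value` overrides
#'   (see [apply_overrides()]).
#' @param quiet suppress provenance notes.
#' @return The `ce_result`, invisibly.
#' @export
cmd_deterministic <- function(params_path, out_dir, overrides = list(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- apply_overrides(load_parameters(params_path, quiet = quiet), overrides)
  res <- run_model(params)
  outputs <- file.path(out_dir, c(
    "ce_result.json",
    paste0("trace_", names(res$traces), ".csv")
  ))
  write_json_flat(ce_result_flat(res), outputs[1])
  for (i in seq_along(res$traces)) {
    write_trace_csv(res$traces[[i]], outputs[i + 1])
  }
  write_run_manifest(out_dir,
    inputs = c(parameters = params_path), outputs = outputs,
    config = params$config
  )
  invisible(res)
}

#' Probabilistic sensitivity analysis command
#'
#' Runs [run_psa()] and writes plot-ready tables: the incremental scatter
#' (`psa_scatter.csv`: draw, delta cost, delta QALY, quadrant), the per-arm
#' absolute scatter (`psa_arm_scatter.csv`), the acceptability curve
#' (`ceac.csv`), a summary (`psa_summary.json` with quadrant fractions, the
#' CEAC value at 30000 euro/QALY, and the renormalisation count), and a run
#' manifest recording `n` and `seed`.
#'
#' @inheritParams cmd_deterministic
#' @param n number of Monte Carlo draws.
#' @param seed master seed.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(params_path, out_dir, n = 10000, seed = 1, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(params_path, quiet = quiet)
  psa <- run_psa(params, n = n, seed = seed)
  outputs <- file.path(out_dir, c(
    "psa_scatter.csv", "psa_arm_scatter.csv", "ceac.csv", "psa_summary.json"
  ))
  utils::write.csv(
    psa$draws[c("draw", "delta_cost", "delta_qaly", "quadrant")],
    outputs[1],
    row.names = FALSE
  )
  arm_scatter <- rbind(
    data.frame(draw = psa$draws$draw, arm = psa$arms[1], cost = psa$draws$cost_ref, qaly = psa$draws$qaly_ref),
    data.frame(draw = psa$draws$draw, arm = psa$arms[2], cost = psa$draws$cost_int, qaly = psa$draws$qaly_int)
  )
  utils::write.csv(arm_scatter, outputs[2], row.names = FALSE)
  utils::write.csv(psa$ceac, outputs[3], row.names = FALSE)
  write_json_flat(list(
    n = psa$n, seed = psa$seed,
    reference_arm = psa$arms[1], intervention_arm = psa$arms[2],
    quadrant_fractions = as.list(psa$quadrants),
    ceac_at_30000 = ceac_at(psa, 30000),
    transition_rows_renormalised = psa$renormalised_rows
  ), outputs[4])
  write_run_manifest(out_dir,
    inputs = c(parameters = params_path), outputs = outputs,
    seed = seed, config = params$config
  )
  invisible(psa)
}

#' Scenario sweep and tornado command
#'
#' Runs the deterministic scenario suite and the tornado pairs, writing
#' `scenarios.csv` (one row per scenario, mirroring a published-style
#' sensitivity table), `tornado.csv` (pairs sorted by impact width), and a
#' run manifest.
#'
#' @inheritParams cmd_deterministic
#' @param suite list of [scenario_spec()]s; defaults to
#'   [default_scenario_suite()].
#' @param pairs list of [tornado_pair()]s; defaults to
#'   [default_tornado_pairs()].
#' @return List with `scenarios` and `tornado` data frames, invisibly.
#' @export
cmd_scenarios <- function(params_path, out_dir, suite = NULL, pairs = NULL, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(params_path, quiet = quiet)
  if (is.null(suite)) suite <- default_scenario_suite(params)
  if (is.null(pairs)) pairs <- default_tornado_pairs(params)
  scen <- run_scenario_suite(params, suite)
  torn <- tornado(params, pairs)
  outputs <- file.path(out_dir, c("scenarios.csv", "tornado.csv"))
  utils::write.csv(scen, outputs[1], row.names = FALSE)
  utils::write.csv(torn, outputs[2], row.names = FALSE)
  write_run_manifest(out_dir,
    inputs = c(parameters = params_path), outputs = outputs,
    config = params$config
  )
  invisible(list(scenarios = scen, tornado = torn))
}
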