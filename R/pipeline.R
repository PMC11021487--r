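#' Load and resolve a pipeline run configuration
#'
#' A run configuration is a YAML file (or an equivalent named list) with
#' the blocks `paths` (`network`, `records`, `output_dir`), `fluid`
#' (`viscosity`), `boundary` (`inlet_pressure`, `venous_pressure`,
#' `terminal_resistance`, `leak`, optional `pressures` map), `annealing`
#' (any [annealing_config()] field), `ablation` (`segments` list),
#' `remodeling` (`day`, `bin_width`, `min_diameter`, `ablation_sites`),
#' and a master `seed`. Omitted keys fall back to package defaults;
#' referenced input files must exist.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The resolved configuration list (class `vasc_run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    paths = list(network = NULL, records = NULL, output_dir = "."),
    fluid = list(viscosity = 3e-3),
    boundary = list(inlet_pressure = 8000, venous_pressure = 0,
                    terminal_resistance = NULL, leak = "all",
                    pressures = NULL),
    annealing = list(),
    ablation = list(segments = NULL),
    remodeling = list(day = 20, bin_width = 30, min_diameter = 11,
                      ablation_sites = NULL),
    generator = list()
  )
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  for (key in c("network", "records")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("config error: paths$", key, " does not exist: ", p))
    }
  }
  structure(cfg, class = "vasc_run_config")
}

cfg_network <- function(cfg) {
  if (is.null(cfg$paths$network)) {
    abort("missing config key: paths$network")
  }
  read_network(cfg$paths$network)
}

cfg_bc <- function(cfg, network) {
  b <- cfg$boundary
  bc <- default_boundary_conditions(
    network,
    inlet_pressure = b$inlet_pressure,
    venous_pressure = b$venous_pressure,
    terminal_resistance = b$terminal_resistance,
    viscosity = cfg$fluid$viscosity,
    leak = b$leak
  )
  if (!is.null(b$pressures)) {
    bp <- unlist(b$pressures)
    bc$boundary_pressures[names(bp)] <- bp
  }
  bc
}

cfg_anneal <- function(cfg) {
  do.call(annealing_config,
          modifyList(list(seed = cfg$seed), cfg$annealing))
}

write_manifest <- function(cfg, outdir, command, files) {
  hashed <- unclass(cfg)
  hashed$paths$output_dir <- NULL # hash the scientific config, not paths
  lines <- c(
    paste0("command: ", command),
    paste0("seed: ", cfg$seed),
    paste0("config_hash: ", rlang::hash(hashed)),
    paste0("outputs: ", toString(files))
  )
  writeLines(lines, file.path(outdir, paste0(command, "_manifest.txt")))
}

prep_outdir <- function(cfg) {
  outdir <- cfg$paths$output_dir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

#' Pipeline command: solve the flow field
#'
#' Reads the network, applies the configured boundary conditions (unknown
#' boundary pressures default to midpoint guesses unless the config
#' provides values), solves, and writes `flows.csv`
#' (`segment_id,flow_m3s,flow_normalized,direction`), `pressures.csv`
#' (`node_id,pressure_pa`) and a run manifest into the output directory.
#'
#' @param config Path to a YAML config or a named list
#'   (see [read_run_config()]).
#' @return The solved `vasc_state`, invisibly.
#' @export
cmd_solve <- function(config) {
  cfg <- read_run_config(config)
  outdir <- prep_outdir(cfg)
  net <- cfg_network(cfg)
  bc <- cfg_bc(cfg, net)
  state <- solve_pressures(net, bc, fluid_parameters(cfg$fluid$viscosity))
  flows <- state$flows |>
    select("segment_id", flow_m3s = "flow", "flow_normalized", "direction")
  readr::write_csv(flows, file.path(outdir, "flows.csv"), progress = FALSE)
  readr::write_csv(state$pressures, file.path(outdir, "pressures.csv"),
                   progress = FALSE)
  write_manifest(cfg, outdir, "solve", c("flows.csv", "pressures.csv"))
  invisible(state)
}

#' Pipeline command: infer boundary pressures by annealing
#'
#' Runs the restart ensemble against the network's observed directions and
#' writes `ensemble.csv`
#' (`segment_id,flow_mean,flow_sd,uncertainty_index,direction_consistency,modal_direction`),
#' `best_errors.csv`, and a manifest logging the master seed.
#'
#' @inheritParams cmd_solve
#' @return The `vasc_ensemble`, invisibly.
#' @export
cmd_infer <- function(config) {
  cfg <- read_run_config(config)
  outdir <- prep_outdir(cfg)
  net <- cfg_network(cfg)
  bc <- cfg_bc(cfg, net)
  ens <- run_ensemble(net, bc, cfg_anneal(cfg))
  readr::write_csv(
    ens$stats |> select("segment_id", "flow_mean", "flow_sd",
                        "uncertainty_index", "direction_consistency",
                        "modal_direction"),
    file.path(outdir, "ensemble.csv"), progress = FALSE
  )
  readr::write_csv(
    tibble(restart = seq_along(ens$best_errors),
           best_error = ens$best_errors),
    file.path(outdir, "best_errors.csv"), progress = FALSE
  )
  write_manifest(cfg, outdir, "infer", c("ensemble.csv", "best_errors.csv"))
  invisible(ens)
}

#' Pipeline command: in-silico ablation experiment
#'
#' Runs the pre-ablation ensemble, solves the acute post-ablation
#' redistribution under the best-fit boundary pressures, and writes
#' `comparison.csv` (`segment_id,flow_pre,flow_post,delta,reversed`) and
#' `enrichment.json` (top-k precision/recall of the uncertainty ranking
#' against the reversed set with a seeded permutation p-value).
#'
#' @inheritParams cmd_solve
#' @return A list with `comparison`, `enrichment` and `ensemble`,
#'   invisibly.
#' @export
cmd_ablate <- function(config) {
  cfg <- read_run_config(config)
  outdir <- prep_outdir(cfg)
  net <- cfg_network(cfg)
  bc <- cfg_bc(cfg, net)
  spec <- as.character(cfg$ablation$segments %||% character())
  ens <- run_ensemble(net, bc, cfg_anneal(cfg))
  best <- which.min(ens$best_errors)
  bc$boundary_pressures <- ens$boundary_pressures[[best]]
  if (length(spec) > 0) {
    exp <- ablation_experiment(net, bc, spec,
                               fluid_parameters(cfg$fluid$viscosity))
    cmpr <- exp$comparison
  } else {
    pre <- solve_pressures(net, bc, fluid_parameters(cfg$fluid$viscosity))
    cmpr <- compare_states(pre, pre)
  }
  cand <- rank_collateral_candidates(ens)
  enr <- evaluate_prediction(cand, cmpr, seed = cfg$seed)
  readr::write_csv(
    cmpr$comparison |> select("segment_id", "flow_pre", "flow_post",
                              "delta", "reversed"),
    file.path(outdir, "comparison.csv"), progress = FALSE
  )
  jsonlite::write_json(glance(enr), file.path(outdir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_manifest(cfg, outdir, "ablate",
                 c("comparison.csv", "enrichment.json"))
  invisible(list(comparison = cmpr, enrichment = enr, ensemble = ens))
}

#' Pipeline command: remodeling metrics
#'
#' Reads longitudinal diameter records and writes the percent-change
#' table, the binned diameter distribution at the configured day, and —
#' when ablation sites are configured — the per-region summary.
#'
#' @inheritParams cmd_solve
#' @return A list of the output tibbles, invisibly.
#' @export
cmd_remodel <- function(config) {
  cfg <- read_run_config(config)
  outdir <- prep_outdir(cfg)
  if (is.null(cfg$paths$records)) abort("missing config key: paths$records")
  rec <- read_remodeling_records(cfg$paths$records)
  rm_cfg <- cfg$remodeling
  pct <- percent_diameter_change(rec)
  hist <- diameter_histogram(rec, day = rm_cfg$day,
                             bin_width = rm_cfg$bin_width,
                             min_diameter = rm_cfg$min_diameter)
  files <- c("percent_change.csv", "diameter_histogram.csv")
  readr::write_csv(pct, file.path(outdir, files[1]), progress = FALSE)
  readr::write_csv(hist, file.path(outdir, files[2]), progress = FALSE)
  out <- list(percent_change = pct, histogram = hist)
  if (!is.null(rm_cfg$ablation_sites)) {
    sites <- tibble(
      x_um = vapply(rm_cfg$ablation_sites, function(s) s[[1]], numeric(1)),
      y_um = vapply(rm_cfg$ablation_sites, function(s) s[[2]], numeric(1))
    )
    reg <- assign_regions(rec, sites)
    summ <- region_summary(reg, day = rm_cfg$day)
    readr::write_csv(summ, file.path(outdir, "region_summary.csv"),
                     progress = FALSE)
    files <- c(files, "region_summary.csv")
    out$region_summary <- summ
  }
  write_manifest(cfg, outdir, "remodel", files)
  invisible(out)
}

#' Pipeline command: materialize the standard fixture set
#'
#' Writes the documented synthetic test networks (three-node toy,
#' two-arcade ladder, convergent venous fixture, and a tracing-scale
#' ~150-segment arcade network with forward-simulated observations) plus
#' a programmed remodeling record table into the output directory, all in
#' the edge-list CSV dialect.
#'
#' @inheritParams cmd_solve
#' @return Character vector of files written, invisibly.
#' @export
cmd_fixtures <- function(config) {
  cfg <- read_run_config(config)
  outdir <- prep_outdir(cfg)
  seed <- cfg$seed
  write_one <- function(net, stem) {
    write_network(net, file.path(outdir, paste0(stem, ".csv")))
    c(paste0(stem, ".csv"), paste0(stem, "_nodes.csv"))
  }
  files <- character()
  files <- c(files, write_one(fixture_three_node(), "three_node"))
  files <- c(files, write_one(fixture_two_arcade()$network, "two_arcade"))
  files <- c(files,
             write_one(fixture_venous_convergent()$network, "venous"))
  gen <- generate_network(
    do.call(generator_params,
            modifyList(list(depth = 6, arcades = 20,
                            boundary_crossings = 12), cfg$generator)),
    seed = seed
  )
  obs_net <- forward_observe(gen$network, gen$bc,
                             stagnant_fraction = 0.1, seed = seed)
  files <- c(files, write_one(obs_net, "tracing_scale"))
  rec <- make_remodeling_fixture(seed = seed)
  readr::write_csv(rec, file.path(outdir, "remodeling_records.csv"),
                   progress = FALSE)
  files <- c(files, "remodeling_records.csv")
  write_manifest(cfg, outdir, "fixtures", files)
  invisible(files)
}

#' Dispatch a pipeline command by name
#'
#' @param command One of `"solve"`, `"infer"`, `"ablate"`, `"remodel"`,
#'   `"fixtures"`.
#' @param config Path to a YAML config or a named list.
#' @return The command's return value, invisibly.
#' @export
run_command <- function(command, config) {
  fn <- switch(command,
    solve = cmd_solve, infer = cmd_infer, ablate = cmd_ablate,
    remodel = cmd_remodel, fixtures = cmd_fixtures,
    abort(paste0("unknown command: ", command))
  )
  fn(config)
}
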