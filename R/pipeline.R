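#' Read a flat key-value configuration file
#'
#' YAML-style `key: value` lines (no nesting); blank lines and `#`
#' comments ignored; values are type-converted.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  out <- list()
  for (ln in lines) {
    i <- regexpr(":", ln, fixed = TRUE)
    if (i < 1) stop("malformed config line: ", sQuote(ln))
    key <- trimws(substr(ln, 1, i - 1))
    val <- trimws(substr(ln, i + 1, nchar(ln)))
    out[[key]] <- utils::type.convert(val, as.is = TRUE)
  }
  out
}

# per-run seeds derived from the master seed by a fixed counter scheme
derive_seeds <- function(master_seed, n) {
  (as.integer(master_seed) %% 1000000L) * 1000L + seq_len(n)
}

#' Run the full target-discovery pipeline
#'
#' Orchestrates: load (or generate) model + expression + differential
#' expression; switch off unexpressed reactions at the focal timepoint;
#' compute the eligible reaction set and mutation space; run `runs`
#' independent seeded evolutions; prune, micro-optimise and rank each
#' captured solution; extract key sets via the revised fitness; aggregate
#' into the target table. Everything lands in `out_dir` along with a
#' manifest recording every seed and parameter.
#'
#' @param config named list (or path to a flat config file). Recognised
#'   keys, with defaults: `fixture_seed` (generate the bundled toy fixture;
#'   default 1) or `model_file`/`expression_file`/`de_file`/
#'   `reference_fluxes_file` plus `targets` (named numeric) and
#'   `citrate_id`; `runs` (8), `master_seed` (1), `generations` (5000),
#'   `population` (50), `p_mutate` (0.3), `fold_threshold` (2),
#'   `fitness_threshold` (6), `revised_threshold` (3.5), `min_increase`
#'   (50), `switch_timepoint` ("T2"), `tpm_cutoff` (1),
#'   `max_solutions_per_run` (3), `simulate` (FALSE), `duration` (96),
#'   `dt` (0.01), `constrained` (TRUE).
#' @param out_dir output directory.
#' @return invisibly, a list with the aggregated `targets`, per-run
#'   solutions, and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(fixture_seed = 1L, runs = 8L, master_seed = 1L,
                   generations = 5000L, population = 50L, p_mutate = 0.3,
                   fold_threshold = 2, fitness_threshold = 6,
                   revised_threshold = 3.5, min_increase = 50,
                   switch_timepoint = "T2", tpm_cutoff = 1,
                   max_solutions_per_run = 3L,
                   simulate = FALSE, duration = 96, dt = 0.01,
                   constrained = TRUE)
  cfg <- modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$model_file)) {
    for (f in c("model_file", "expression_file", "de_file",
                "reference_fluxes_file"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("config file missing on disk: ", cfg[[f]])
    model <- read_model_tsv(cfg$model_file)
    profiles <- read_expression_tsv(cfg$expression_file)
    de <- read_de_tsv(cfg$de_file)
    ref <- read.delim(cfg$reference_fluxes_file, stringsAsFactors = FALSE)
    targets <- unlist(cfg$targets)
    citrate_id <- cfg$citrate_id
    exchange_map <- cfg$exchange_map
  } else {
    fixture <- make_toy_model(seed = cfg$fixture_seed)
    expr <- make_expression_tables(fixture, seed = cfg$fixture_seed)
    model <- fixture$model
    profiles <- expr$profiles
    de <- expr$de
    ref <- fixture$truth$reference_fluxes
    targets <- fixture$truth$targets
    citrate_id <- fixture$truth$citrate_id
    exchange_map <- fixture$truth$exchange_map
  }
  if (is.null(model$biomass_id) || is.na(model$biomass_id))
    stop("model needs a biomass reaction")

  spec <- fitness_spec(targets, citrate_id,
                       threshold = cfg$fitness_threshold)

  if (isTRUE(cfg$simulate) && !is.null(exchange_map)) {
    traj <- simulate_batch(model, kinetic_parameters(), toy_initial_state(),
                           duration = cfg$duration, dt = cfg$dt,
                           constrained = cfg$constrained,
                           exchange_map = exchange_map)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  }

  working <- apply_expression_switch(model, profiles[[cfg$switch_timepoint]],
                                     cutoff = cfg$tpm_cutoff)
  elig <- eligible_reactions(working, profiles, de,
                             fold_threshold = cfg$fold_threshold)
  base <- evo_fitness(list(), working, spec)
  if (base$status != "optimal")
    stop("baseline model infeasible under target constraints")
  pinned <- setdiff(names(targets), citrate_id)
  base_fixed <- setNames(lapply(pinned, function(r) rep(targets[[r]], 2)),
                         pinned)
  base_cit <- solve_fba(working, base_fixed, objective = citrate_id,
                        sense = "max")
  space <- build_mutation_space(working, spec, elig, ref,
                                baseline_fluxes = base_cit$fluxes)

  params <- evolution_parameters(population = cfg$population,
                                 p_mutate = cfg$p_mutate,
                                 generations = cfg$generations,
                                 fitness_threshold = cfg$fitness_threshold,
                                 fold_threshold = cfg$fold_threshold)
  seeds <- derive_seeds(cfg$master_seed, cfg$runs)
  all_rows <- list()
  run_summaries <- list()
  for (i in seq_len(cfg$runs)) {
    run_id <- sprintf("run%02d", i)
    run <- evolve_bounds(working, spec, space, params, seed = seeds[i],
                         run_id = run_id,
                         max_solutions = cfg$max_solutions_per_run)
    write_solutions_json(run, file.path(out_dir,
                                        paste0(run_id, "_solutions.json")))
    refined <- lapply(run$solutions, function(s) {
      r <- prune_solution(s, working, spec, threshold = cfg$fitness_threshold)
      optimise_bounds(r, working, spec)
    })
    rows <- lapply(refined, function(r)
      solution_targets(r, working, spec, base_cit$objective_value,
                       run_id = run_id,
                       revised_threshold = cfg$revised_threshold))
    all_rows <- c(all_rows, rows)
    run_summaries[[run_id]] <- list(
      seed = seeds[i], solutions = length(run$solutions),
      generations = run$generations_run,
      key_reactions = vapply(run$solutions, `[[`, character(1),
                             "key_reaction"))
  }
  target_rows <- do.call(rbind, c(all_rows, list(
    data.frame(run_id = character(0), reaction_id = character(0),
               direction = character(0), percent_increase = numeric(0),
               stringsAsFactors = FALSE))))
  targets_tab <- aggregate_targets(target_rows, model = model,
                                   min_increase = cfg$min_increase)
  write_targets_tsv(targets_tab, file.path(out_dir, "targets.tsv"))
  if (nrow(target_rows))
    write.table(target_membership(target_rows),
                file.path(out_dir, "membership.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = cfg[order(names(cfg))],
    run_seeds = as.list(setNames(seeds, names(run_summaries))),
    runs = run_summaries,
    unconstrained_citrate = base_cit$objective_value,
    eligible_reactions = elig$reaction_id,
    mutation_space = names(space),
    n_targets = nrow(targets_tab))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(targets = targets_tab, target_rows = target_rows,
                 manifest = manifest, spec = spec, model = working,
                 space = space))
}
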