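#' Prune redundant mutations from a solution
#'
#' Greedy simplification: mutations are reverted one at a time in
#' deterministic order (ascending fitness contribution, ties by id) and a
#' reversion is kept whenever the solution fitness stays at or above the
#' threshold. The pass repeats until no further mutation can be removed,
#' so the refined fitness never drops below the threshold.
#'
#' @param solution an `evo_solution` (or any list with `mutations`).
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @param threshold retention threshold (default 6).
#' @return list of class `refined_solution` with `parent_run`,
#'   `mutations`, `fitness`, `removed`.
#' @export
prune_solution <- function(solution, model, spec, threshold = 6) {
  muts <- solution$mutations
  fit <- evo_fitness(muts, model, spec)$fitness
  if (fit < threshold)
    stop("solution fitness ", format(fit), " below threshold; cannot prune")
  removed <- character(0)
  repeat {
    if (!length(muts)) break
    ids <- sort(names(muts))
    contrib <- vapply(ids, function(rid)
      fit - evo_fitness(muts[setdiff(names(muts), rid)], model, spec)$fitness,
      numeric(1))
    ord <- ids[order(contrib, ids)]
    dropped <- FALSE
    for (rid in ord) {
      f2 <- evo_fitness(muts[setdiff(names(muts), rid)], model, spec)$fitness
      if (f2 >= threshold) {
        muts[[rid]] <- NULL
        removed <- c(removed, rid)
        fit <- f2
        dropped <- TRUE
        break  # contributions change; recompute ordering
      }
    }
    if (!dropped) break
  }
  structure(list(parent_run = solution$run_id,
                 seed = solution$seed,
                 mutations = muts, fitness = fit, removed = removed),
            class = "refined_solution")
}

#' Micro-optimise mutated bounds
#'
#' Coordinate-wise hill climb: each mutated bound is nudged by a step of
#' 1% of its magnitude in both directions (clipped to its allowed
#' interval) and a nudge is kept only when it improves the fitness.
#' Sweeps repeat until no bound moves or `max_sweeps` is reached, so the
#' fitness is non-decreasing.
#'
#' @param refined a `refined_solution`.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @param step_frac step as a fraction of the bound magnitude (default 0.01).
#' @param max_sweeps sweep budget (default 20).
#' @return the refined solution with optimised bounds.
#' @export
optimise_bounds <- function(refined, model, spec,
                            step_frac = 0.01, max_sweeps = 20) {
  muts <- refined$mutations
  fit <- evo_fitness(muts, model, spec)$fitness
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (rid in sort(names(muts))) {
      m <- muts[[rid]]
      step <- step_frac * max(abs(m$B), 0.001)
      for (delta in c(-step, step)) {
        B2 <- m$B + delta
        if (!is.null(m$interval))
          B2 <- min(max(B2, m$interval[1]), m$interval[2])
        if (identical(B2, m$B)) next
        trial <- muts
        trial[[rid]] <- move_mutation(m, B2)
        f2 <- evo_fitness(trial, model, spec)$fitness
        if (f2 > fit + 1e-12) {
          muts <- trial
          m <- muts[[rid]]
          fit <- f2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  refined$mutations <- muts
  refined$fitness <- fit
  refined
}

#' Rank mutations by fitness contribution
#'
#' Contribution of a mutation is the fitness lost when its flux bounds are
#' individually restored to the originals. Rows are sorted by descending
#' contribution, ties by reaction id.
#'
#' @param refined a `refined_solution`.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @return data.frame `reaction_id, kind, contribution`.
#' @export
rank_mutations <- function(refined, model, spec) {
  muts <- refined$mutations
  if (!length(muts))
    return(data.frame(reaction_id = character(0), kind = character(0),
                      contribution = numeric(0)))
  fit <- evo_fitness(muts, model, spec)$fitness
  ids <- sort(names(muts))
  contrib <- vapply(ids, function(rid)
    fit - evo_fitness(muts[setdiff(names(muts), rid)], model, spec)$fitness,
    numeric(1))
  out <- data.frame(reaction_id = ids,
                    kind = vapply(muts[ids], `[[`, character(1), "kind"),
                    contribution = unname(contrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution, out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Key reaction set via revised fitness
#'
#' Walks the contribution-ranked mutation list, cumulatively restoring
#' original bounds and recomputing a revised fitness in which the citrate
#' target is replaced by the unconstrained optimum; the walk stops once
#' the revised fitness reaches the threshold. The returned set is the
#' minimal ranked prefix whose restoration recovers near-optimal citrate
#' output.
#'
#' @param refined a `refined_solution`.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @param unconstrained_citrate citrate optimum of the unmutated model.
#' @param revised_threshold revised-fitness threshold (default 3.5).
#' @return character vector of reaction ids (possibly empty); if the
#'   threshold is never reached the full set is returned with a warning.
#' @export
extract_key_set <- function(refined, model, spec, unconstrained_citrate,
                            revised_threshold = 3.5) {
  rspec <- spec
  rspec$targets[spec$citrate_id] <- unconstrained_citrate
  if (evo_fitness(refined$mutations, model, rspec)$fitness >= revised_threshold)
    return(character(0))
  ranked <- rank_mutations(refined, model, spec)
  restored <- character(0)
  for (rid in ranked$reaction_id) {
    restored <- c(restored, rid)
    remaining <- refined$mutations[setdiff(names(refined$mutations), restored)]
    if (evo_fitness(remaining, model, rspec)$fitness >= revised_threshold)
      return(restored)
  }
  warning("revised fitness never reached ", revised_threshold,
          "; returning full mutation set")
  restored
}

#' Percent increase in citrate output from restoring one mutation
#'
#' Citrate-maximizing LP solves with the full mutation set versus the set
#' with the given reaction's bounds restored to the originals (all other
#' mutations retained):
#' `100 * (citrate_restored - citrate_mutated) / citrate_mutated`.
#'
#' @param refined a `refined_solution`.
#' @param reaction_id mutated reaction to restore.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @return percent increase, or `NA` (with a warning) when the mutated
#'   citrate flux is zero.
#' @export
citric_percent_increase <- function(refined, reaction_id, model, spec) {
  if (!reaction_id %in% names(refined$mutations))
    stop("reaction not mutated in this solution: ", reaction_id)
  cit <- function(muts) {
    extra <- lapply(muts, function(m) c(m$lb, m$ub))
    for (rid in setdiff(names(spec$targets), spec$citrate_id))
      extra[[rid]] <- rep(spec$targets[[rid]], 2)
    sol <- solve_fba(model, extra, objective = spec$citrate_id, sense = "max")
    if (sol$status != "optimal") stop("citrate LP ", sol$status)
    sol$objective_value
  }
  mutated <- cit(refined$mutations)
  restored <- cit(refined$mutations[setdiff(names(refined$mutations),
                                            reaction_id)])
  if (abs(mutated) < 1e-12) {
    warning("mutated citrate flux is zero; percent increase undefined")
    return(NA_real_)
  }
  100 * (restored - mutated) / mutated
}

#' Target rows from one refined solution
#'
#' Applies [extract_key_set()] and converts each key reaction into a
#' suggested intervention: the direction is the opposite of the in silico
#' mutation (a constrained reaction is a target for up-regulation, a
#' forced one for down-regulation), with the citrate percent increase
#' from [citric_percent_increase()].
#'
#' @param refined a `refined_solution`.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @param unconstrained_citrate citrate optimum of the unmutated model.
#' @param run_id run label for aggregation (default: the parent run).
#' @param ... passed to [extract_key_set()].
#' @return data.frame `run_id, reaction_id, direction, percent_increase`.
#' @export
solution_targets <- function(refined, model, spec, unconstrained_citrate,
                             run_id = refined$parent_run, ...) {
  keys <- extract_key_set(refined, model, spec, unconstrained_citrate, ...)
  if (!length(keys))
    return(data.frame(run_id = character(0), reaction_id = character(0),
                      direction = character(0), percent_increase = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    run_id = run_id,
    reaction_id = keys,
    direction = vapply(refined$mutations[keys], function(m)
      if (m$kind == "constrain") "up-regulate" else "down-regulate",
      character(1)),
    percent_increase = vapply(keys, function(rid)
      citric_percent_increase(refined, rid, model, spec), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Aggregate target suggestions across runs
#'
#' Union of key reactions over all rows; frequency is the number of
#' distinct runs a reaction appears in, and the reported percent increase
#' is the highest across solutions. The table is sorted by descending
#' frequency, then descending percent increase; `prominent` flags rows at
#' or above `min_increase`.
#'
#' @param target_rows data.frame of rows from [solution_targets()]
#'   (rbind over runs), columns `run_id, reaction_id, direction,
#'   percent_increase`.
#' @param model optional `metabolic_model` used to attach names/equations.
#' @param min_increase prominence threshold in percent (default 50).
#' @return data.frame
#'   `reaction_id, name, equation, target, frequency, citric_percent_increase,
#'    prominent`.
#' @export
aggregate_targets <- function(target_rows, model = NULL, min_increase = 50) {
  if (!nrow(target_rows))
    return(data.frame(reaction_id = character(0), name = character(0),
                      equation = character(0), target = character(0),
                      frequency = integer(0),
                      citric_percent_increase = numeric(0),
                      prominent = logical(0), stringsAsFactors = FALSE))
  groups <- split(target_rows, target_rows$reaction_id)
  out <- do.call(rbind, lapply(groups, function(g) {
    best <- g[which.max(replace(g$percent_increase,
                                is.na(g$percent_increase), -Inf)), ]
    data.frame(reaction_id = best$reaction_id,
               target = best$direction,
               frequency = length(unique(g$run_id)),
               citric_percent_increase = max(g$percent_increase, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(model)) {
    i <- match(out$reaction_id, model$reactions$reaction_id)
    out$name <- model$reactions$name[i]
    out$equation <- model$reactions$equation[i]
  } else {
    out$name <- out$reaction_id
    out$equation <- NA_character_
  }
  out$prominent <- out$citric_percent_increase >= min_increase
  out <- out[order(-out$frequency, -out$citric_percent_increase,
                   out$reaction_id),
             c("reaction_id", "name", "equation", "target", "frequency",
               "citric_percent_increase", "prominent")]
  rownames(out) <- NULL
  out
}

#' Write the aggregated target table as TSV
#'
#' @param targets data.frame from [aggregate_targets()].
#' @param path output path.
#' @param min_increase drop rows below this percent increase (default 0:
#'   keep all).
#' @export
write_targets_tsv <- function(targets, path, min_increase = 0) {
  keep <- targets[targets$citric_percent_increase >= min_increase, ,
                  drop = FALSE]
  write.table(keep, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-run target membership matrix
#'
#' Plain tabular stand-in for a circular multi-run comparison figure:
#' one row per reaction, one 0/1 column per run.
#'
#' @param target_rows rows from [solution_targets()] across runs.
#' @return data.frame.
#' @export
target_membership <- function(target_rows) {
  runs <- sort(unique(target_rows$run_id))
  rxns <- sort(unique(target_rows$reaction_id))
  m <- vapply(runs, function(r)
    as.integer(rxns %in% target_rows$reaction_id[target_rows$run_id == r]),
    integer(length(rxns)))
  m <- matrix(m, nrow = length(rxns), dimnames = list(NULL, runs))
  out <- data.frame(reaction_id = rxns, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("reaction_id", runs)
  out
}
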