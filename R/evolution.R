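#' Fitness specification for the flux-bound evolution
#'
#' Tracks five exchange fluxes — internal phosphate, glucose, xylose,
#' biomass, citric acid — against target values. The citrate target is the
#' constrained (in vivo-like) output flux; the other targets are the
#' corresponding fluxes of the unconstrained baseline solution, so that
#' evolved solutions reproduce the constrained product flux while keeping
#' carbon input and biomass output unchanged.
#'
#' @param targets named numeric vector of target fluxes keyed by exchange
#'   reaction id (five entries).
#' @param citrate_id id of the citrate exchange among the targets.
#' @param cap fitness value returned for an exact fit (default 12; the
#'   least-squares fitness diverges at zero deviation).
#' @param threshold fitness at which an individual counts as an evolved
#'   solution (default 6).
#' @return list of class `fitness_spec`.
#' @export
fitness_spec <- function(targets, citrate_id, cap = 12, threshold = 6) {
  if (!citrate_id %in% names(targets))
    stop("citrate_id must be one of the target exchanges")
  structure(list(targets = targets, citrate_id = citrate_id,
                 cap = cap, threshold = threshold),
            class = "fitness_spec")
}

#' Least-squares fitness of a mutation set
#'
#' Solves the model under the individual's mutated bounds with the
#' non-citrate target exchanges pinned to their target fluxes and citrate
#' output maximized, then scores
#' \deqn{F = -\log_{10} \sum_i (f_{t,i} - f_{a,i})^2}
#' over the tracked exchanges, where \eqn{f_t} are the targets and
#' \eqn{f_a} the achieved fluxes. An exact fit returns the configured cap;
#' an infeasible LP returns `-Inf`.
#'
#' @param mutations named list `reaction_id -> list(lb, ub, ...)` of
#'   mutated bounds (may be empty).
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @return list with `fitness`, `fluxes` (achieved tracked fluxes) and
#'   `status`.
#' @export
evo_fitness <- function(mutations, model, spec) {
  extra <- lapply(mutations, function(m) c(m$lb, m$ub))
  for (rid in setdiff(names(spec$targets), spec$citrate_id))
    extra[[rid]] <- rep(spec$targets[[rid]], 2)
  sol <- solve_fba(model, extra, objective = spec$citrate_id, sense = "max")
  if (sol$status != "optimal")
    return(list(fitness = -Inf, fluxes = NULL, status = sol$status))
  fa <- sol$fluxes[names(spec$targets)]
  list(fitness = fitness_score(spec$targets, fa, cap = spec$cap),
       fluxes = fa, status = "optimal")
}

#' Least-squares fitness score
#'
#' The scoring rule applied to target and achieved flux vectors:
#' `F = -log10(sum((f_t - f_a)^2))`, capped at `cap` as the deviation
#' approaches zero (the expression diverges at a perfect fit).
#'
#' @param ft target fluxes.
#' @param fa achieved fluxes (same order).
#' @param cap fitness cap for perfect fits (default 12).
#' @return the fitness value.
#' @export
fitness_score <- function(ft, fa, cap = 12) {
  ss <- sum((ft - fa)^2)
  if (ss < 10^(-cap)) cap else -log10(ss)
}

#' Mutation scale rule
#'
#' Scale parameter of the Laplace mutation kernel as a function of the
#' flux bound it perturbs: `b = 0.01*|B|` for nonzero `B`, `b = 0.001`
#' when `B` is zero.
#'
#' @param B the flux bound being mutated.
#' @return scale parameter `b` (> 0).
#' @export
mutation_scale <- function(B) {
  if (abs(B) > 0) 0.01 * abs(B) else 0.001
}

#' Laplace-distributed draws
#'
#' Symmetric two-sided exponential (Laplace) deviates by inversion,
#' with location `mu` and scale `b` (`E|x - mu| = b`).
#'
#' @param n number of draws.
#' @param mu location.
#' @param b scale (> 0).
#' @return numeric vector.
#' @export
rlaplace <- function(n, mu = 0, b = 1) {
  if (b <= 0) stop("scale must be > 0")
  u <- runif(n) - 0.5
  mu - b * sign(u) * log1p(-2 * abs(u))
}

#' Mutation limits for an eligible reaction
#'
#' Translates a differential-expression event into the interval a mutated
#' flux bound may occupy. Constraining (down-regulation) may tighten the
#' bound no further than the larger-magnitude reference flux divided by
#' the fold change; forcing (up-regulation) must raise the flux to at
#' least the smaller-magnitude reference flux times the fold change, and
#' never beyond the maximum allowable flux (the FVA maximum under the base
#' exchange constraints). Forcing is disallowed on reactions without a
#' clear flux direction (FVA interval straddling zero).
#'
#' @param reaction_id eligible reaction.
#' @param direction `"constrain"` or `"force"`.
#' @param fold_change reaction-level expression fold change (>= 2).
#' @param flux_t1,flux_t3 reference fluxes at the flanking timepoints.
#' @param model a `metabolic_model`.
#' @param fixed base exchange constraints (see [flux_variability()]).
#' @param baseline_flux the reaction's flux in the unconstrained baseline
#'   solution at the focal timepoint, used as the upper end of the initial
#'   constrain draw; defaults to the larger-magnitude reference flux.
#' @return list with `kind`, `sign` (+1 forward / -1 backward / 0 no clear
#'   direction), `constraint_limit`, `draw_hi`, `min_forced`,
#'   `max_allowable`, `feasible` (whether any mutation interval exists),
#'   and the FVA interval.
#' @export
mutation_limits <- function(reaction_id, direction, fold_change,
                            flux_t1, flux_t3, model, fixed = NULL,
                            baseline_flux = NULL) {
  if (fold_change < 1) stop("fold_change must be >= 1")
  fva <- flux_variability(model, reaction_id, fixed)
  tol <- 1e-9
  sgn <- if (fva[["max"]] > tol && fva[["min"]] >= -tol) 1
         else if (fva[["min"]] < -tol && fva[["max"]] <= tol) -1
         else 0
  hi_ref <- max(abs(flux_t1), abs(flux_t3))
  lo_ref <- min(abs(flux_t1), abs(flux_t3))
  out <- list(reaction_id = reaction_id, kind = direction, sign = sgn,
              fva = fva, constraint_limit = NA_real_, draw_hi = NA_real_,
              min_forced = NA_real_, max_allowable = NA_real_,
              feasible = FALSE)
  if (direction == "constrain") {
    out$constraint_limit <- hi_ref / fold_change
    base <- if (is.null(baseline_flux)) hi_ref else abs(baseline_flux)
    out$draw_hi <- max(base, hi_ref)
    out$feasible <- out$draw_hi > out$constraint_limit + tol
  } else if (direction == "force") {
    if (sgn == 0) return(out)  # no clear direction of flux
    out$min_forced <- lo_ref * fold_change
    out$max_allowable <- max(abs(fva))
    out$feasible <- out$min_forced <= out$max_allowable + tol
  } else stop("direction must be 'constrain' or 'force'")
  out
}

#' Evolution parameters
#'
#' Generational scheme defaults: population 50, tournament selection of
#' size 2, elitism 1, per-individual mutation probability 0.3 per
#' generation, 150000 generations, solution threshold 6.
#'
#' @param population population size.
#' @param tournament tournament size.
#' @param elitism individuals copied unchanged each generation.
#' @param p_mutate per-individual probability of one mutation event per
#'   generation.
#' @param generations generation budget.
#' @param fitness_threshold solution capture threshold.
#' @param fold_threshold eligibility fold-change threshold.
#' @return list of class `evolution_parameters`.
#' @export
evolution_parameters <- function(population = 50, tournament = 2,
                                 elitism = 1, p_mutate = 0.3,
                                 generations = 150000,
                                 fitness_threshold = 6,
                                 fold_threshold = 2) {
  structure(as.list(environment()), class = "evolution_parameters")
}

#' Mutation search space from eligibility and reference fluxes
#'
#' Combines [eligible_reactions()] output with reference fluxes and
#' [mutation_limits()] into the per-reaction table the evolutionary
#' algorithm draws from. Reactions without a feasible mutation interval
#' are dropped (logged via message).
#'
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec` (its non-citrate targets become the fixed
#'   exchange constraints for FVA).
#' @param elig data.frame from [eligible_reactions()].
#' @param ref_fluxes data.frame `reaction_id, flux_t1, flux_t3`.
#' @param baseline_fluxes optional named vector of baseline fluxes at the
#'   focal timepoint.
#' @return list of per-reaction limit records.
#' @export
build_mutation_space <- function(model, spec, elig, ref_fluxes,
                                 baseline_fluxes = NULL) {
  fixed <- lapply(setdiff(names(spec$targets), spec$citrate_id),
                  function(rid) rep(spec$targets[[rid]], 2))
  names(fixed) <- setdiff(names(spec$targets), spec$citrate_id)
  space <- list()
  for (i in seq_len(nrow(elig))) {
    rid <- elig$reaction_id[i]
    j <- match(rid, ref_fluxes$reaction_id)
    if (is.na(j)) {
      message("no reference fluxes for eligible reaction ", rid, "; skipped")
      next
    }
    lim <- mutation_limits(rid, elig$direction[i], elig$fold_change[i],
                           ref_fluxes$flux_t1[j], ref_fluxes$flux_t3[j],
                           model, fixed = fixed,
                           baseline_flux = if (!is.null(baseline_fluxes))
                             baseline_fluxes[[rid]] else NULL)
    if (!lim$feasible) {
      message("no feasible mutation interval for ", rid, " (",
              elig$direction[i], "); skipped")
      next
    }
    i_r <- match(rid, model$reactions$reaction_id)
    lim$orig_lb <- model$reactions$lower_bound[i_r]
    lim$orig_ub <- model$reactions$upper_bound[i_r]
    lim$reversible <- model$reactions$reversible[i_r]
    space[[rid]] <- lim
  }
  space
}

# translate a mutated bound magnitude into (lb, ub) for the reaction
mutation_bounds <- function(lim, B) {
  if (lim$kind == "constrain") {
    if (lim$sign >= 0) {
      ub <- B
      lb <- if (lim$reversible) max(lim$orig_lb, -B) else lim$orig_lb
    } else {
      lb <- -B
      ub <- if (lim$reversible) min(lim$orig_ub, B) else lim$orig_ub
    }
  } else {
    if (lim$sign > 0) { lb <- B; ub <- lim$orig_ub }
    else { ub <- -B; lb <- lim$orig_lb }
  }
  list(lb = lb, ub = ub)
}

#' Apply one mutation event to an individual's mutation set
#'
#' Initial mutations draw the bound uniformly inside the allowed interval
#' (`[constraint_limit, draw_hi]` when constraining,
#' `[min_forced, max_allowable]` when forcing); subsequent mutations add a
#' Laplace(0, b) perturbation with `b` from [mutation_scale()], clipped to
#' the same interval. Constrain mutations on reversible reactions move
#' both bounds symmetrically toward zero.
#'
#' @param mutations current named list of mutation records.
#' @param rid reaction to mutate (must be in `space`).
#' @param space mutation space from [build_mutation_space()].
#' @return updated mutation list.
#' @export
mutate_bounds <- function(mutations, rid, space) {
  lim <- space[[rid]]
  if (is.null(lim)) stop("reaction not in mutation space: ", rid)
  interval <- if (lim$kind == "constrain")
    c(lim$constraint_limit, lim$draw_hi)
  else c(lim$min_forced, lim$max_allowable)
  if (is.null(mutations[[rid]])) {
    B <- runif(1, interval[1], interval[2])
  } else {
    B <- mutations[[rid]]$B + rlaplace(1, 0, mutation_scale(mutations[[rid]]$B))
    B <- min(max(B, interval[1]), interval[2])
  }
  bb <- mutation_bounds(lim, B)
  mutations[[rid]] <- list(reaction_id = rid, kind = lim$kind, B = B,
                           lb = bb$lb, ub = bb$ub,
                           sign = lim$sign, reversible = lim$reversible,
                           orig_lb = lim$orig_lb, orig_ub = lim$orig_ub,
                           interval = interval)
  mutations
}

# recompute a mutation record's (lb, ub) after moving its magnitude to B2
move_mutation <- function(m, B2) {
  lim <- list(kind = m$kind, sign = m$sign, reversible = m$reversible,
              orig_lb = m$orig_lb, orig_ub = m$orig_ub)
  bb <- mutation_bounds(lim, B2)
  m$B <- B2
  m$lb <- bb$lb
  m$ub <- bb$ub
  m
}

#' Key reaction of a solution
#'
#' Complements each mutated flux bound with its original value in turn and
#' recomputes the fitness; the key reaction is the mutation whose
#' restoration costs the most fitness. Ties break lexicographically by
#' reaction id.
#'
#' @param mutations mutation set of the solution.
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @return list with `key_reaction` and the named `contributions` vector.
#' @export
identify_key_reaction <- function(mutations, model, spec) {
  if (!length(mutations)) stop("solution has no mutations")
  full <- evo_fitness(mutations, model, spec)$fitness
  ids <- sort(names(mutations))
  contrib <- vapply(ids, function(rid) {
    full - evo_fitness(mutations[setdiff(names(mutations), rid)],
                       model, spec)$fitness
  }, numeric(1))
  list(key_reaction = ids[which.max(contrib)], contributions = contrib)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Transcriptome-guided evolution of flux bounds
#'
#' Generational evolutionary algorithm over mutation sets: tournament
#' selection with elitism, one optional mutation event per individual per
#' generation. Whenever an individual's fitness reaches the capture
#' threshold, the individual is frozen as a solution, its key reaction is
#' identified by single-bound complementation, that reaction's bounds are
#' reset to the originals across the whole population, and it is blocked
#' from mutating again — driving the search toward further, distinct
#' solutions.
#'
#' @param model a `metabolic_model`.
#' @param spec a `fitness_spec`.
#' @param space mutation space from [build_mutation_space()].
#' @param params an `evolution_parameters`.
#' @param seed RNG seed for this run (all stochasticity derives from it).
#' @param run_id identifier stored in captured solutions.
#' @param max_solutions stop after this many captures (default unlimited).
#' @param verbose emit one message per capture.
#' @return list of class `evo_run`: `solutions` (list of `evo_solution`),
#'   `blocked`, `generations_run`, `seed`, `run_id`.
#' @export
evolve_bounds <- function(model, spec, space, params = evolution_parameters(),
                          seed = 1L, run_id = "run1",
                          max_solutions = Inf, verbose = FALSE) {
  if (!length(space)) stop("nothing to evolve: eligible set is empty")
  with_seed(seed, {
    base <- evo_fitness(list(), model, spec)
    if (!is.finite(base$fitness) && base$status != "optimal")
      stop("base model infeasible under target constraints")
    N <- params$population
    pop <- replicate(N, list(mutations = list(), fitness = base$fitness),
                     simplify = FALSE)
    blocked <- character(0)
    solutions <- list()
    gen_run <- 0L
    for (gen in seq_len(params$generations)) {
      gen_run <- gen
      fit <- vapply(pop, `[[`, numeric(1), "fitness")
      elite_idx <- order(-fit)[seq_len(params$elitism)]
      newpop <- pop[elite_idx]
      for (k in seq_len(N - params$elitism)) {
        cand <- sample.int(N, params$tournament, replace = TRUE)
        newpop[[length(newpop) + 1L]] <- pop[[cand[which.max(fit[cand])]]]
      }
      pop <- newpop
      avail <- setdiff(names(space), blocked)
      if (!length(avail)) break
      for (k in seq.int(params$elitism + 1L, N)) {
        if (runif(1) > params$p_mutate) next
        rid <- avail[sample.int(length(avail), 1L)]
        pop[[k]]$mutations <- mutate_bounds(pop[[k]]$mutations, rid, space)
        pop[[k]]$fitness <- evo_fitness(pop[[k]]$mutations, model, spec)$fitness
      }
      repeat {
        fit <- vapply(pop, `[[`, numeric(1), "fitness")
        hit <- which(fit >= params$fitness_threshold)
        hit <- hit[vapply(pop[hit], function(p) length(p$mutations) > 0L,
                          logical(1))]
        if (!length(hit)) break
        best <- hit[which.max(fit[hit])]
        ind <- pop[[best]]
        key <- identify_key_reaction(ind$mutations, model, spec)
        sol <- structure(list(run_id = run_id, seed = seed,
                              generation = gen, fitness = ind$fitness,
                              mutations = ind$mutations,
                              key_reaction = key$key_reaction,
                              contributions = key$contributions),
                         class = "evo_solution")
        solutions[[length(solutions) + 1L]] <- sol
        if (verbose)
          message(sprintf("capture: gen %d fitness %.3f key %s",
                          gen, ind$fitness, key$key_reaction))
        blocked <- c(blocked, key$key_reaction)
        for (k in seq_len(N)) {
          if (key$key_reaction %in% names(pop[[k]]$mutations)) {
            pop[[k]]$mutations[[key$key_reaction]] <- NULL
            pop[[k]]$fitness <-
              evo_fitness(pop[[k]]$mutations, model, spec)$fitness
          }
        }
        if (length(solutions) >= max_solutions) break
      }
      if (length(solutions) >= max_solutions) break
      if (length(setdiff(names(space), blocked)) == 0L) break
    }
    structure(list(solutions = solutions, blocked = blocked,
                   generations_run = gen_run, seed = seed, run_id = run_id),
              class = "evo_run")
  })
}

#' @export
print.evo_run <- function(x, ...) {
  cat("<evo_run>", x$run_id, " seed", x$seed, "\n")
  cat(" ", length(x$solutions), "solution(s) in", x$generations_run,
      "generations; blocked:", paste(x$blocked, collapse = ", "), "\n")
  invisible(x)
}

#' Write solutions of a run as JSON
#' @param run an `evo_run` (or list of `evo_solution`).
#' @param path output path.
#' @export
write_solutions_json <- function(run, path) {
  sols <- if (inherits(run, "evo_run")) run$solutions else run
  out <- lapply(sols, function(s) list(
    run_id = s$run_id, seed = s$seed, generation = s$generation,
    fitness = s$fitness, key_reaction = s$key_reaction,
    mutations = lapply(unname(s$mutations), function(m)
      m[c("reaction_id", "kind", "B", "lb", "ub", "orig_lb", "orig_ub")])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
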