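# in-code fixtures and independent oracles used across test files

# linear chain: A -> B -> C with exchanges at both ends
chain_model <- function(input_cap = 10) {
  new_metabolic_model(data.frame(
    reaction_id = c("EX_A", "R1", "R2", "EX_C"),
    name = c("A exchange", "step1", "step2", "C exchange"),
    equation = c("A <==>", "A -> B", "B -> C", "C <==>"),
    lower_bound = c(-input_cap, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000),
    association = "", subsystem = "",
    stringsAsFactors = FALSE), id = "chain", objective_id = "EX_C",
    biomass_id = NULL)
}

# two routes from A to P with carbon yields 1.0 and 0.5
branch_model <- function(input_cap = 10) {
  new_metabolic_model(data.frame(
    reaction_id = c("EX_A", "R_HI", "R_LO", "EX_P"),
    name = c("A exchange", "high-yield route", "low-yield route",
             "P exchange"),
    equation = c("A <==>", "A -> P", "A -> 0.5*P", "P <==>"),
    lower_bound = c(-input_cap, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000),
    association = "", subsystem = "",
    stringsAsFactors = FALSE), id = "branch", objective_id = "EX_P",
    biomass_id = NULL)
}

# independent LP oracle on a metabolic model via boot::simplex
# (shift x = lb + y, upper bounds as A1 rows, equalities sign-normalized)
oracle_lp <- function(model, objective_id, sense = "max",
                      extra_constraints = NULL) {
  rxns <- model$reactions$reaction_id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  for (rid in names(extra_constraints)) {
    i <- match(rid, rxns)
    lb[i] <- extra_constraints[[rid]][1]
    ub[i] <- extra_constraints[[rid]][2]
  }
  A <- model$S
  cc <- as.numeric(rxns == objective_id)
  d <- ub - lb
  free <- which(d > 1e-12)  # drop variables fixed by equal bounds
  b3 <- -as.numeric(A %*% lb)
  sgn <- ifelse(b3 < 0, -1, 1)
  o <- boot::simplex(a = cc[free], A1 = diag(length(free)), b1 = d[free],
                     A3 = (A * sgn)[, free, drop = FALSE], b3 = b3 * sgn,
                     maxi = sense == "max")
  if (o$solved != 1) return(list(solved = o$solved, objective = NA_real_))
  list(solved = 1, objective = unname(o$value + sum(cc * lb)))
}

# shared toy fixture objects (built once per test session)
toy_env <- new.env()
get_toy <- function() {
  if (is.null(toy_env$fx)) {
    toy_env$fx <- make_toy_model()
    toy_env$expr <- make_expression_tables(toy_env$fx)
    tr <- toy_env$fx$truth
    toy_env$spec <- fitness_spec(tr$targets, tr$citrate_id)
    pinned <- setdiff(names(tr$targets), tr$citrate_id)
    toy_env$fixed <- setNames(lapply(pinned, function(r)
      rep(tr$targets[[r]], 2)), pinned)
    toy_env$base_cit <- solve_fba(toy_env$fx$model, toy_env$fixed,
                                  objective = tr$citrate_id, sense = "max")
    toy_env$elig <- eligible_reactions(toy_env$fx$model, toy_env$expr$profiles,
                                       toy_env$expr$de)
    toy_env$space <- suppressMessages(build_mutation_space(
      toy_env$fx$model, toy_env$spec, toy_env$elig,
      tr$reference_fluxes, toy_env$base_cit$fluxes))
  }
  toy_env
}

# craft a mutation record the way mutate_bounds would store it
make_mutation <- function(rid, kind, B, model, interval = NULL,
                          sign = 1) {
  i <- match(rid, model$reactions$reaction_id)
  orig_lb <- model$reactions$lower_bound[i]
  orig_ub <- model$reactions$upper_bound[i]
  rev <- model$reactions$reversible[i]
  if (kind == "constrain") {
    lb <- if (rev) max(orig_lb, -B) else orig_lb
    ub <- B
  } else {
    lb <- B
    ub <- orig_ub
  }
  list(reaction_id = rid, kind = kind, B = B, lb = lb, ub = ub,
       sign = sign, reversible = rev, orig_lb = orig_lb, orig_ub = orig_ub,
       interval = interval)
}
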