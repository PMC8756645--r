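test_that("the least-squares fitness matches its closed forms", {
  # a single 0.01 deviation: -log10(1e-4) = 4
  expect_equal(fitness_score(c(0.12, 1, 2), c(0.11, 1, 2)), 4,
               tolerance = 1e-12)
  # two 0.1 deviations: -log10(0.02)
  expect_equal(fitness_score(c(1, 2), c(1.1, 1.9)), -log10(0.02),
               tolerance = 1e-12)
  # perfect fit returns the cap (and the cap qualifies as a solution)
  expect_equal(fitness_score(c(1, 2), c(1, 2)), 12)
  expect_gt(fitness_score(c(1, 2), c(1, 2)), 6)

  # the model-backed fitness agrees with an independent re-evaluation
  # of the scoring formula
  env <- get_toy()
  f <- evo_fitness(list(CITT = list(lb = 0, ub = 0.2)), env$fx$model,
                   env$spec)
  expect_equal(f$fitness, -log10(sum((env$spec$targets - f$fluxes)^2)),
               tolerance = 1e-12)
  # infeasible bounds give the -Inf sentinel
  bad <- evo_fitness(list(GLCT = list(lb = 0, ub = 0)), env$fx$model,
                     env$spec)
  expect_identical(bad$fitness, -Inf)
})

test_that("the mutation scale rule is exact", {
  expect_identical(mutation_scale(0.5), 0.005)
  expect_identical(mutation_scale(0), 0.001)
  expect_identical(mutation_scale(-2), 0.02)
})

test_that("Laplace draws have the distribution's moments", {
  set.seed(101)
  b <- mutation_scale(1)  # 0.01
  x <- rlaplace(1e5, 0, b)
  # mean 0 within 3 SE (var = 2 b^2)
  expect_lt(abs(mean(x)), 3 * sqrt(2 * b^2 / 1e5))
  # E|x| = b within 3 SE (var of |x| is b^2)
  expect_lt(abs(mean(abs(x)) - b), 3 * b / sqrt(1e5))
  expect_error(rlaplace(1, 0, 0), "scale")
})

test_that("mutation limits encode the multiplicative bounds", {
  env <- get_toy()
  model <- env$fx$model
  # down 4-fold with reference flux magnitude 2.0: constraint limit 0.5
  lim <- mutation_limits("CITT", "constrain", 4, 2.0, 0.3, model,
                         fixed = env$fixed)
  expect_equal(lim$constraint_limit, 0.5, tolerance = 1e-12)
  expect_true(lim$feasible)
  # forcing uses the smaller reference times the fold, capped by FVA max
  limf <- mutation_limits("CITT", "force", 2, 0.05, 0.2, model,
                          fixed = env$fixed)
  expect_equal(limf$min_forced, 0.1, tolerance = 1e-12)
  expect_equal(limf$max_allowable, unname(limf$fva["max"]), tolerance = 1e-9)
  # a reversible reaction with FVA straddling zero cannot be forced
  cyc <- new_metabolic_model(data.frame(
    reaction_id = c("EX_A", "R", "EX_B"), name = "",
    equation = c("A <==>", "A <==> B", "B <==>"),
    lower_bound = c(-3, -1000, -3), upper_bound = c(3, 1000, 3),
    association = "", subsystem = "", stringsAsFactors = FALSE))
  limr <- mutation_limits("R", "force", 2, 1, 2, cyc)
  expect_equal(limr$sign, 0)
  expect_false(limr$feasible)
})

test_that("mutated bounds always stay inside their allowed interval", {
  env <- get_toy()
  set.seed(33)
  muts <- list()
  for (i in 1:200) {
    muts <- mutate_bounds(muts, "CITT", env$space)
    m <- muts$CITT
    expect_gte(m$B, m$interval[1] - 1e-12)
    expect_lte(m$B, m$interval[2] + 1e-12)
    expect_lte(m$ub, m$orig_ub)
    expect_gte(m$lb, m$orig_lb)
  }
})

test_that("seeded mutation sequences are reproducible", {
  env <- get_toy()
  draw_seq <- function(seed) {
    set.seed(seed)
    muts <- list()
    out <- numeric(20)
    for (i in 1:20) {
      muts <- mutate_bounds(muts, "CITT", env$space)
      out[i] <- muts$CITT$B
    }
    out
  }
  expect_identical(draw_seq(7), draw_seq(7))
  expect_false(identical(draw_seq(7), draw_seq(8)))
})

test_that("key-reaction identification matches brute-force restoration", {
  env <- get_toy()
  model <- env$fx$model
  muts <- list(
    CITT = make_mutation("CITT", "constrain", 0.12, model),
    ACC = make_mutation("ACC", "constrain", 0.05, model))
  key <- identify_key_reaction(muts, model, env$spec)
  expect_equal(key$key_reaction, "CITT")
  # brute force both restorations independently
  full <- evo_fitness(muts, model, env$spec)$fitness
  for (rid in names(muts)) {
    drop1 <- evo_fitness(muts[setdiff(names(muts), rid)], model,
                         env$spec)$fitness
    expect_equal(key$contributions[[rid]], full - drop1, tolerance = 1e-12)
  }
  # equal (zero) contributions: lexicographically first id wins
  muts0 <- list(ALD = make_mutation("ALD", "constrain", 0.05, model),
                ACC = make_mutation("ACC", "constrain", 0.05, model))
  expect_equal(identify_key_reaction(muts0, model, env$spec)$key_reaction,
               "ACC")
})

test_that("evolution runs are deterministic for a seed", {
  env <- get_toy()
  params <- evolution_parameters(generations = 2000)
  r1 <- evolve_bounds(env$fx$model, env$spec, env$space, params, seed = 5,
                      max_solutions = 1)
  r2 <- evolve_bounds(env$fx$model, env$spec, env$space, params, seed = 5,
                      max_solutions = 1)
  expect_identical(lapply(r1$solutions, unclass),
                   lapply(r2$solutions, unclass))
  expect_length(r1$solutions, 1)
  expect_equal(r1$solutions[[1]]$key_reaction, "CITT")
  expect_gte(r1$solutions[[1]]$fitness, 6)
})

test_that("blocked key reactions never reappear in later solutions", {
  fx2 <- make_toy_model(toy_model_spec(bottlenecks = c("CITT", "CITSYN")))
  expr2 <- make_expression_tables(fx2)
  spec2 <- fitness_spec(fx2$truth$targets, "EX_CIT")
  elig2 <- eligible_reactions(fx2$model, expr2$profiles, expr2$de)
  pinned <- setdiff(names(fx2$truth$targets), "EX_CIT")
  fixed <- setNames(lapply(pinned, function(r) rep(fx2$truth$targets[[r]], 2)),
                    pinned)
  bc <- solve_fba(fx2$model, fixed, objective = "EX_CIT", sense = "max")
  space2 <- suppressMessages(build_mutation_space(
    fx2$model, spec2, elig2, fx2$truth$reference_fluxes, bc$fluxes))
  run <- evolve_bounds(fx2$model, spec2, space2,
                       evolution_parameters(generations = 5000),
                       seed = 11, max_solutions = 2)
  expect_length(run$solutions, 2)
  keys <- vapply(run$solutions, `[[`, character(1), "key_reaction")
  # two distinct key reactions, both planted bottlenecks
  expect_length(unique(keys), 2)
  expect_true(all(keys %in% fx2$truth$bottlenecks))
  # after capture, the blocked reaction is absent from later mutation sets
  expect_false(keys[1] %in% names(run$solutions[[2]]$mutations))
  # captured mutations all live inside their allowed intervals
  for (s in run$solutions)
    for (m in s$mutations) {
      expect_gte(m$B, m$interval[1] - 1e-12)
      expect_lte(m$B, m$interval[2] + 1e-12)
    }
})

test_that("an empty eligible set refuses to evolve", {
  env <- get_toy()
  expect_error(evolve_bounds(env$fx$model, env$spec, list(),
                             evolution_parameters(generations = 10)),
               "nothing to evolve")
})
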