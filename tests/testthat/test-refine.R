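test_that("pruning strips no-op mutations and keeps the fitness above 6", {
  env <- get_toy()
  model <- env$fx$model
  sol <- list(run_id = "runA", seed = 1,
              mutations = list(
                CITT = make_mutation("CITT", "constrain", 0.12, model),
                ACC = make_mutation("ACC", "constrain", 0.05, model),
                ALD = make_mutation("ALD", "constrain", 0.06, model)))
  ref <- prune_solution(sol, model, env$spec)
  expect_equal(names(ref$mutations), "CITT")
  expect_setequal(ref$removed, c("ACC", "ALD"))
  expect_gte(ref$fitness, 6)
  # a minimal solution is untouched
  minimal <- list(run_id = "runB", seed = 1,
                  mutations = list(
                    CITT = make_mutation("CITT", "constrain", 0.12, model)))
  ref2 <- prune_solution(minimal, model, env$spec)
  expect_equal(names(ref2$mutations), "CITT")
  expect_length(ref2$removed, 0)
  # below-threshold input is rejected
  weak <- list(run_id = "runC", seed = 1,
               mutations = list(
                 CITT = make_mutation("CITT", "constrain", 0.2, model)))
  expect_error(prune_solution(weak, model, env$spec), "below threshold")
})

test_that("bound micro-optimisation is monotone and recovers displacements", {
  env <- get_toy()
  model <- env$fx$model
  # bound displaced ~5% from the optimum of this 1-mutation landscape
  ref <- structure(list(parent_run = "runA", seed = 1,
                        mutations = list(
                          CITT = make_mutation("CITT", "constrain", 0.126,
                                               model,
                                               interval = c(0.1, 0.6)))),
                   class = "refined_solution")
  before <- evo_fitness(ref$mutations, model, env$spec)$fitness
  opt <- optimise_bounds(ref, model, env$spec)
  expect_gte(opt$fitness, before)
  # 1-D scan oracle: the optimum of |B - 0.12| sits at 0.12; the climb
  # should land within one step size of it
  expect_lt(abs(opt$mutations$CITT$B - 0.12), 0.01 * 0.126 + 1e-9)
  # an already-optimal bound is unchanged
  ref0 <- structure(list(parent_run = "runA", seed = 1,
                         mutations = list(
                           CITT = make_mutation("CITT", "constrain", 0.12,
                                                model,
                                                interval = c(0.1, 0.6)))),
                    class = "refined_solution")
  opt0 <- optimise_bounds(ref0, model, env$spec)
  expect_equal(opt0$mutations$CITT$B, 0.12, tolerance = 1e-12)
})

test_that("contribution ranking equals brute-force single restorations", {
  env <- get_toy()
  model <- env$fx$model
  ref <- structure(list(mutations = list(
    CITT = make_mutation("CITT", "constrain", 0.12, model),
    ACC = make_mutation("ACC", "constrain", 0.05, model))),
    class = "refined_solution")
  ranked <- rank_mutations(ref, model, env$spec)
  expect_equal(ranked$reaction_id, c("CITT", "ACC"))  # dominant first
  full <- evo_fitness(ref$mutations, model, env$spec)$fitness
  for (i in seq_len(nrow(ranked))) {
    rid <- ranked$reaction_id[i]
    oracle <- full - evo_fitness(ref$mutations[setdiff(names(ref$mutations),
                                                       rid)],
                                 model, env$spec)$fitness
    expect_equal(ranked$contribution[i], oracle, tolerance = 1e-9)
  }
})

test_that("the revised-fitness walk recovers exactly the planted key set", {
  env <- get_toy()
  model <- env$fx$model
  uncon <- env$base_cit$objective_value
  ref <- structure(list(mutations = list(
    CITT = make_mutation("CITT", "constrain", 0.12, model),
    ACC = make_mutation("ACC", "constrain", 0.05, model))),
    class = "refined_solution")
  keys <- extract_key_set(ref, model, env$spec, uncon)
  expect_identical(keys, "CITT")
  expect_true(all(keys %in% names(ref$mutations)))
  # a solution that never constrained citrate starts above the revised
  # threshold: empty key set
  ref2 <- structure(list(mutations = list(
    ACC = make_mutation("ACC", "constrain", 0.05, model))),
    class = "refined_solution")
  expect_identical(extract_key_set(ref2, model, env$spec, uncon),
                   character(0))
})

test_that("citrate percent increase matches the two-LP oracle", {
  env <- get_toy()
  model <- env$fx$model
  ref <- structure(list(mutations = list(
    CITT = make_mutation("CITT", "constrain", 0.12, model),
    ACC = make_mutation("ACC", "constrain", 0.05, model))),
    class = "refined_solution")
  pct <- citric_percent_increase(ref, "CITT", model, env$spec)
  # hand oracle: with the exporter capped the output is its cap (0.12);
  # restored, the carbon-limited optimum 0.3159 is recovered (the ACC
  # tightening carries no flux at either optimum)
  expect_equal(pct, 100 * (0.3159 - 0.12) / 0.12, tolerance = 1e-6)
  # paper-scale analog: 0.12 -> 0.3159 is about a 163% increase
  expect_equal(pct, 163.25, tolerance = 0.01)
  # restoring a zero-contribution mutation changes nothing
  expect_equal(citric_percent_increase(ref, "ACC", model, env$spec), 0,
               tolerance = 1e-9)
})

test_that("direction flip is the stated involution", {
  env <- get_toy()
  model <- env$fx$model
  ref <- structure(list(parent_run = "runX", mutations = list(
    CITT = make_mutation("CITT", "constrain", 0.12, model))),
    class = "refined_solution")
  rows <- solution_targets(ref, model, env$spec,
                           env$base_cit$objective_value)
  expect_equal(rows$direction, "up-regulate")   # constrain -> up-regulate
})

test_that("aggregation reproduces a hand-tallied frequency table", {
  env <- get_toy()
  model <- env$fx$model
  # three runs: CITT in all three, GLYC in one, a weak-effect decoy in one
  rows <- rbind(
    data.frame(run_id = "run1", reaction_id = "CITT",
               direction = "up-regulate", percent_increase = 163.2),
    data.frame(run_id = "run2", reaction_id = "CITT",
               direction = "up-regulate", percent_increase = 160.0),
    data.frame(run_id = "run3", reaction_id = "CITT",
               direction = "up-regulate", percent_increase = 162.1),
    data.frame(run_id = "run2", reaction_id = "GLYC",
               direction = "up-regulate", percent_increase = 80.0),
    data.frame(run_id = "run3", reaction_id = "CITSYN",
               direction = "up-regulate", percent_increase = 20.0))
  tab <- aggregate_targets(rows, model = model)
  # hand tally: CITT 3 runs (max 163.2), GLYC 1 (80), CITSYN 1 (20)
  expect_equal(tab$reaction_id, c("CITT", "GLYC", "CITSYN"))
  expect_equal(tab$frequency, c(3L, 1L, 1L))
  expect_equal(tab$citric_percent_increase, c(163.2, 80, 20))
  expect_true(all(tab$frequency <= 3))
  # prominent filter at 50% excludes the planted 20%-effect decoy
  expect_equal(tab$prominent, c(TRUE, TRUE, FALSE))
  # the 20%-effect pct is itself the product of a real two-LP computation:
  # constraining synthesis to 0.144 behind an exporter capped at 0.12
  ref20 <- structure(list(mutations = list(
    CITSYN = make_mutation("CITSYN", "constrain", 0.12, model),
    CITT = make_mutation("CITT", "constrain", 0.144, model))),
    class = "refined_solution")
  expect_equal(citric_percent_increase(ref20, "CITSYN", model, env$spec),
               20, tolerance = 1e-6)
  # a reaction in no key set is absent
  expect_false("RESP" %in% tab$reaction_id)
  # membership matrix mirrors the rows
  mem <- target_membership(rows)
  expect_equal(mem$run2[mem$reaction_id == "GLYC"], 1L)
  expect_equal(mem$run1[mem$reaction_id == "GLYC"], 0L)
})
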