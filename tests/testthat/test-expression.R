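test_that("OR sums and AND minimises transcript expression", {
  tpm <- c(tA = 3, tB = 5, tC = 1)
  expect_equal(reaction_expression(parse_association("tA OR tB"), tpm), 8)
  expect_equal(reaction_expression(parse_association("tA AND tB"), tpm), 3)
  # nested two-level tree evaluated by hand: min(2,7) = 2, 2 + 1 = 3
  tpm2 <- c(tA = 2, tB = 7, tC = 1)
  expect_equal(
    reaction_expression(parse_association("(tA AND tB) OR tC"), tpm2), 3)
  # no association: sentinel, not zero
  expect_true(is.na(reaction_expression(NULL, tpm)))
  # missing transcript warns and contributes zero
  expect_warning(v <- reaction_expression(parse_association("tA OR tZ"), tpm),
                 "tZ")
  expect_equal(v, 3)
})

test_that("monotonicity: OR never decreases, AND never increases", {
  set.seed(5)
  for (rep in 1:20) {
    ids <- paste0("t", 1:4)
    tpm <- setNames(round(runif(4, 0, 50), 2), ids)
    base_or <- reaction_expression(parse_association("t1 OR t2"), tpm)
    grown_or <- reaction_expression(parse_association("t1 OR t2 OR t3"), tpm)
    expect_gte(grown_or, base_or)
    base_and <- reaction_expression(parse_association("t1 AND t2"), tpm)
    grown_and <- reaction_expression(parse_association("t1 AND t2 AND t3"), tpm)
    expect_lte(grown_and, base_and)
  }
})

test_that("TPM switch-off is strict and idempotent", {
  m <- new_metabolic_model(data.frame(
    reaction_id = c("EX_A", "RLOW", "RAT", "RNOA", "EX_B"),
    name = "",
    equation = c("A <==>", "A -> B", "A -> B", "A -> B", "B <==>"),
    lower_bound = c(-10, 0, 0, 0, 0), upper_bound = c(0, 5, 5, 5, 1000),
    association = c("", "tLow", "tAt", "", ""), subsystem = "",
    stringsAsFactors = FALSE))
  tpm <- c(tLow = 0.4, tAt = 1.0)
  m2 <- apply_expression_switch(m, tpm)
  gb <- function(mm, rid) unlist(mm$reactions[
    mm$reactions$reaction_id == rid, c("lower_bound", "upper_bound")])
  expect_equal(unname(gb(m2, "RLOW")), c(0, 0))   # 0.4 < 1: off
  expect_equal(unname(gb(m2, "RAT")), c(0, 5))    # exactly 1: untouched
  expect_equal(unname(gb(m2, "RNOA")), c(0, 5))   # no association: untouched
  m3 <- apply_expression_switch(m2, tpm)
  expect_identical(m3$reactions, m2$reactions)    # idempotent
})

test_that("reaction-level differential calls follow the fold and q rules", {
  tree <- parse_association("tA")
  de <- data.frame(transcript_id = "tA", comparison = "T1-T2",
                   log2FC = 2, q_value = 1e-5, stringsAsFactors = FALSE)
  # without pseudocount the 2 -> 8 shift is exactly log2(8/2) = 2
  d <- reaction_differential(tree, de, c(tA = 2), c(tA = 8),
                             comparison = "T1-T2", pseudocount = 0)
  expect_equal(d$log2fc, 2, tolerance = 1e-12)
  expect_true(d$significant)
  # default pseudocount shrinks it slightly
  d2 <- reaction_differential(tree, de, c(tA = 2), c(tA = 8),
                              comparison = "T1-T2")
  expect_equal(d2$log2fc, log2(8.5 / 2.5), tolerance = 1e-12)
  # non-significant q kills the call regardless of fold
  de$q_value <- 0.5
  d3 <- reaction_differential(tree, de, c(tA = 2), c(tA = 8),
                              comparison = "T1-T2")
  expect_false(d3$significant)
  # dual-zero expression: undefined, flagged with a reason
  d4 <- reaction_differential(tree, de, c(tA = 0), c(tA = 0),
                              comparison = "T1-T2")
  expect_true(is.na(d4$log2fc))
  expect_match(d4$reason, "no expression")
  # 3-transcript OR with mixed shifts matches the hand-computed sum ratio
  tree3 <- parse_association("tA OR tB OR tC")
  de3 <- data.frame(transcript_id = c("tA", "tB", "tC"), comparison = "T1-T2",
                    log2FC = 0, q_value = c(1e-6, 0.9, 0.9),
                    stringsAsFactors = FALSE)
  early <- c(tA = 10, tB = 20, tC = 5)   # sum 35
  late <- c(tA = 50, tB = 15, tC = 30)   # sum 95
  d5 <- reaction_differential(tree3, de3, early, late, comparison = "T1-T2")
  expect_equal(d5$log2fc, log2(95.5 / 35.5), tolerance = 1e-12)
  expect_true(d5$significant)
})

test_that("eligibility finds exactly the planted events", {
  env <- get_toy()
  elig <- env$elig
  expect_setequal(elig$reaction_id, env$fx$truth$eligible)
  expect_equal(elig$direction[elig$reaction_id == "CITT"], "constrain")
  expect_equal(elig$direction[elig$reaction_id == "XYLT"], "force")
  expect_equal(elig$fold_change[elig$reaction_id == "CITT"], 6,
               tolerance = 1e-9)
  # the sub-threshold phosphate-transport event (fold 1.5) is excluded
  expect_false("PIT" %in% elig$reaction_id)
})

test_that("eligibility is empty when every shift is below threshold", {
  env <- get_toy()
  model <- env$fx$model
  profiles <- env$expr$profiles
  # flat profiles: copy T1 everywhere
  flat <- list(T1 = profiles$T1, T2 = profiles$T1, T3 = profiles$T1)
  de <- data.frame(transcript_id = names(profiles$T1),
                   comparison = "T1-T2", log2FC = 0, q_value = 1e-9,
                   stringsAsFactors = FALSE)
  out <- eligible_reactions(model, flat, de)
  expect_equal(nrow(out), 0)
})

test_that("direction conflicts resolve by larger magnitude, ties drop", {
  m <- new_metabolic_model(data.frame(
    reaction_id = c("EX_A", "R1", "EX_B"), name = "",
    equation = c("A <==>", "A -> B", "B <==>"),
    lower_bound = c(-10, 0, 0), upper_bound = c(0, 5, 1000),
    association = c("", "tR", ""), subsystem = "",
    stringsAsFactors = FALSE))
  de <- data.frame(transcript_id = "tR",
                   comparison = c("T1-T2", "T2-T3"),
                   log2FC = c(-1.2, 2), q_value = 1e-6,
                   stringsAsFactors = FALSE)
  # down 2.3x at T1-T2 (40 -> 17.1), up 4x at T2-T3 (17.1 -> 70)
  profiles <- list(T1 = c(tR = 40), T2 = c(tR = 17.1), T3 = c(tR = 70))
  out <- eligible_reactions(m, profiles, de)
  expect_equal(out$direction, "force")  # larger |log2FC| wins
  # exact tie: up then down by the same factor -> ineligible
  profiles2 <- list(T1 = c(tR = 10), T2 = c(tR = 41.5), T3 = c(tR = 10))
  out2 <- eligible_reactions(m, profiles2, de)
  expect_equal(nrow(out2), 0)
  # intersection mode requires the event in both comparisons
  out3 <- eligible_reactions(m, profiles, de, mode = "intersection")
  expect_equal(nrow(out3), 1)  # tR significant in both
})

test_that("expression and DE tables round-trip through TSV", {
  env <- get_toy()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(env$expr$profiles, path)
  back <- read_expression_tsv(path)
  expect_equal(names(back), c("T1", "T2", "T3"))
  for (tp in names(back))
    expect_equal(back[[tp]][names(env$expr$profiles[[tp]])],
                 env$expr$profiles[[tp]], tolerance = 1e-9)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_de_tsv(env$expr$de, path2)
  back2 <- read_de_tsv(path2)
  expect_equal(back2$log2FC, env$expr$de$log2FC, tolerance = 1e-9)
  expect_equal(back2$transcript_id, env$expr$de$transcript_id)
})
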