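# GA operators and the full loop: cardinality preservation, operator
# sampling statistics, memoization, elitism, determinism, and recovery of
# the exhaustive optimum.

five_space <- function() {
  manual_candidate_space(c("R1", "R2", "R3", "R4", "R5"),
                         make_branch_env_space())
}

test_that("initial populations have exact cardinalities and are seeded", {
  cand <- five_space()
  cfg <- ga_config(population_size = 20, K = 2, E = 1, seed = 5)
  pop1 <- with_seed(5, init_population(cand, cfg))
  pop2 <- with_seed(5, init_population(cand, cfg))
  expect_identical(pop1, pop2)
  for (ch in pop1) {
    expect_length(ch$knockouts, 2)
    expect_length(ch$environment, 1)
    expect_true(all(ch$knockouts %in% cand$knockout_candidates))
  }
  # degenerate K=0, E=0
  cfg0 <- ga_config(population_size = 5, elite_count = 2, K = 0, E = 0)
  pop0 <- with_seed(1, init_population(cand, cfg0))
  expect_true(all(vapply(pop0, function(ch)
    length(ch$knockouts) == 0 && length(ch$environment) == 0,
    logical(1))))
  expect_error(with_seed(1, init_population(
    cand, ga_config(K = 9, E = 0))), "exceeds")
})

test_that("crossover preserves cardinality and respects the union rule", {
  cand <- five_space()
  cfg <- ga_config(K = 4, E = 0, crossover_probability = 1)
  a <- design_chromosome(c("R1", "R2", "R3", "R4"), character(0))
  b <- design_chromosome(c("R2", "R3", "R4", "R5"), character(0))
  with_seed(2, {
    for (i in 1:50) {
      ch <- crossover(a, b, cfg)
      expect_length(ch$knockouts, 4)
      expect_true(all(ch$knockouts %in% union(a$knockouts, b$knockouts)))
    }
    same <- crossover(a, a, cfg)
    expect_identical(same$knockouts, a$knockouts)
  })
})

test_that("crossover of disjoint parents samples elements uniformly", {
  cfg <- ga_config(K = 4, E = 0, crossover_probability = 1)
  a <- design_chromosome(c("A1", "A2", "A3", "A4"), character(0))
  b <- design_chromosome(c("B1", "B2", "B3", "B4"), character(0))
  n <- 10000
  counts <- with_seed(3, {
    tab <- integer(8)
    names(tab) <- c(a$knockouts, b$knockouts)
    for (i in seq_len(n)) {
      ch <- crossover(a, b, cfg)
      tab[ch$knockouts] <- tab[ch$knockouts] + 1L
    }
    tab
  })
  # each element kept with probability 1/2; binomial 3-sigma band
  p <- 0.5
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < 3.5 * sigma))
})

test_that("mutation swaps at most one element per segment, uniformly", {
  cand <- manual_candidate_space(paste0("R", 1:8),
                                 make_branch_env_space())
  cfg <- ga_config(K = 3, E = 0, mutation_probability = 1)
  base <- design_chromosome(c("R1", "R2", "R3"), character(0))
  n <- 10000
  counts <- with_seed(4, {
    tab <- integer(5)
    names(tab) <- paste0("R", 4:8)
    for (i in seq_len(n)) {
      ch <- mutate(base, cand, cfg)
      expect_length(ch$knockouts, 3)
      gained <- setdiff(ch$knockouts, base$knockouts)
      expect_lte(length(gained), 1)
      if (length(gained)) tab[gained] <- tab[gained] + 1L
    }
    tab
  })
  p <- 1 / 5
  sigma <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) < 3.5 * sigma))
  # no inactive candidate -> segment unchanged
  tight <- manual_candidate_space(c("R1", "R2", "R3"),
                                  make_branch_env_space())
  ch <- with_seed(1, mutate(base, tight, cfg))
  expect_identical(ch$knockouts, base$knockouts)
})

test_that("the GA recovers the known optimum on the five-candidate toy", {
  toy <- make_fivepath_toy()
  cand <- five_space()
  cfg <- scoring_config(a = 1)
  tg <- target_set(up = "R1")
  ex <- exhaustive_search(toy, tg, cand, K = 1, E = 1,
                          scoring_config = cfg)
  expect_identical(ex$best_chromosome$knockouts, "R3")
  expect_equal(ex$best_score, 1)
  run <- run_ga(toy, tg, cand, cfg,
                ga_config(population_size = 10, elite_count = 3,
                          generations = 10, K = 1, E = 1, seed = 11))
  expect_identical(run$best_chromosome$knockouts,
                   ex$best_chromosome$knockouts)
  expect_equal(run$best_score, ex$best_score)
})

test_that("per-generation best never decreases and runs are reproducible", {
  toy <- make_fivepath_toy()
  cand <- five_space()
  cfg <- scoring_config(a = 1)
  tg <- target_set(up = "R1")
  gcfg <- ga_config(population_size = 8, elite_count = 2,
                    generations = 8, K = 1, E = 1, seed = 7)
  r1 <- run_ga(toy, tg, cand, cfg, gcfg)
  r2 <- run_ga(toy, tg, cand, cfg, gcfg)
  expect_true(all(diff(r1$trajectory$best) >= 0))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$best_chromosome, r2$best_chromosome)
  expect_identical(r1$archive, r2$archive)
})

test_that("archive scores equal fresh evaluation (memo soundness)", {
  toy <- make_fivepath_toy()
  cand <- five_space()
  cfg <- scoring_config(a = 1)
  tg <- target_set(up = "R1")
  run <- run_ga(toy, tg, cand, cfg,
                ga_config(population_size = 6, elite_count = 2,
                          generations = 5, K = 1, E = 1, seed = 2))
  # archive holds unique chromosomes only
  expect_false(anyDuplicated(run$archive$chromosome) > 0)
  for (i in seq_len(nrow(run$archive))) {
    key <- run$archive$chromosome[i]
    ko <- sub("^K\\[(.*)\\]E\\[.*$", "\\1", key)
    en <- sub("^.*E\\[(.*)\\]$", "\\1", key)
    split1 <- function(s) if (nzchar(s))
      strsplit(s, ",", fixed = TRUE)[[1]] else character(0)
    view <- apply_constraints(toy, split1(ko), split1(en),
                              cand$environment)
    expect_equal(run$archive$score[i],
                 evolvex_score(view, tg, cfg)$value)
  }
})

test_that("a run over an all-infeasible space completes with a flag", {
  toy <- make_branch_toy()
  # R2+R3 always knocked out together kills growth; K=2 over exactly
  # those two candidates makes every chromosome infeasible
  cand <- manual_candidate_space(c("R2", "R3"), make_branch_env_space())
  run <- run_ga(toy, target_set(up = "R1"), cand, scoring_config(a = 1),
                ga_config(population_size = 4, elite_count = 1,
                          generations = 3, K = 2, E = 1, seed = 1))
  expect_false(run$feasible)
  expect_identical(run$best_score, -Inf)
})

test_that("binary serialization uses 0 for active positions", {
  cand <- five_space()
  ch <- design_chromosome(c("R2", "R4"), "EX_A")
  bits <- serialize_chromosome(ch, cand)
  expect_identical(unname(bits[c("ko:R2", "ko:R4", "env:EX_A")]),
                   c(0L, 0L, 0L))
  expect_identical(unname(bits[c("ko:R1", "ko:R3", "ko:R5")]),
                   c(1L, 1L, 1L))
})
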