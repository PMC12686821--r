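# Pruning rules against brute-force oracles computed with the reference
# solver.

ref_essential_sweep <- function(model, env, objective,
                                fraction = 1e-6) {
  open <- evolvexga:::open_environment(model, env)
  base <- ref_fba(open, objective = objective)
  out <- character(0)
  for (j in seq_along(open$rxns)) {
    ko <- open
    ko$lb[j] <- 0; ko$ub[j] <- 0
    r <- ref_fba(ko, objective = objective)
    if (r$status != "optimal" || r$objval < fraction * base$objval) {
      out <- c(out, open$rxns[j])
    }
  }
  out
}

ref_blocked <- function(model, env, tol = 1e-9) {
  open <- evolvexga:::open_environment(model, env)
  out <- character(0)
  for (r in open$rxns) {
    rng <- ref_flux_range(open, r)
    if (all(abs(rng) <= tol)) out <- c(out, r)
  }
  out
}

test_that("branch-toy essentiality matches intuition", {
  m <- make_branch_toy()
  env <- make_branch_env_space()
  ess <- find_growth_essential(m, env)
  expect_true("EX_A" %in% ess)   # sole carbon source
  expect_false("R1" %in% ess)    # parallel to R3
  expect_false("R3" %in% ess)
  aug <- add_pathway(m, make_branch_pathway())
  pess <- find_production_essential(aug, env)
  expect_true(all(c("P", "EX_Prod") %in% pess))  # sole route
  expect_false("R1" %in% pess)
})

test_that("essential and blocked sets equal reference-solver sweeps on random toys", {
  env_of <- function(m) make_toy_env_space(m)
  for (seed in c(2, 5, 11)) {
    m <- make_random_toy(12, seed = seed)
    env <- env_of(m)
    expect_setequal(find_growth_essential(m, env),
                    ref_essential_sweep(m, env, m$growth_reaction))
    expect_setequal(find_blocked(m, env), ref_blocked(m, env))
  }
})

test_that("a dead-end reaction is blocked, the branch toy has none", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tcategory",
               "EX_A\tA ->\t-10\t0\tauto",
               "R1\tA -> B\t0\t10\tauto",
               "RD\tA -> D\t0\t10\tauto",     # D is a dead end
               "GROWTH\tB ->\t0\t10\tbiomass"), path)
  m <- read_toy_model(path)
  env <- chemical_environment_space(
    data.frame(component = "A", exchange_id = "EX_A", role = "carbon"),
    uptake_bound_magnitude = 10)
  expect_identical(find_blocked(m, env), "RD")
  expect_length(find_blocked(make_branch_toy(),
                             make_branch_env_space()), 0)
})

test_that("candidate space applies all pruning rules with provenance", {
  aug <- add_pathway(make_branch_toy(), make_branch_pathway())
  env <- make_branch_env_space()
  cs <- build_candidate_space(aug, env)
  expect_setequal(cs$knockout_candidates, c("R1", "R2", "R3"))
  expect_false(aug$growth_reaction %in% cs$knockout_candidates)
  expect_false(any(cs$knockout_candidates %in%
                     aug$rxns[aug$category == "exchange"]))
  # one reason per excluded reaction, covering everything removed
  excluded <- setdiff(aug$rxns, cs$knockout_candidates)
  expect_setequal(cs$provenance$reaction, excluded)
  expect_false(anyDuplicated(cs$provenance$reaction) > 0)
})

test_that("pruning is monotone in extra exclusions", {
  aug <- add_pathway(make_branch_toy(), make_branch_pathway())
  env <- make_branch_env_space()
  base <- build_candidate_space(aug, env)
  fewer <- build_candidate_space(aug, env, extra_exclusions = "R2")
  expect_true(all(fewer$knockout_candidates %in%
                    base$knockout_candidates))
  expect_false("R2" %in% fewer$knockout_candidates)
})

test_that("an all-essential model yields an empty-candidate error", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tcategory",
               "EX_A\tA ->\t-10\t0\tauto",
               "R1\tA -> B\t0\t10\tauto",
               "GROWTH\tB ->\t0\t10\tbiomass"), path)
  m <- read_toy_model(path)  # R1 is the only internal and is essential
  env <- chemical_environment_space(
    data.frame(component = "A", exchange_id = "EX_A", role = "carbon"),
    uptake_bound_magnitude = 10)
  expect_error(build_candidate_space(m, env), "no knockout candidates")
})

test_that("gene-annotation and diffusion tags exclude reactions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tcategory\tgene_associated",
               "EX_A\tA ->\t-10\t0\tauto\t0",
               "R1\tA -> B\t0\t10\tauto\t1",
               "R2\tA -> B\t0\t10\tauto\t0",       # no gene
               "R3\tA -> B\t0\t10\tdiffusion\t1",  # diffusion tag
               "R4\tB -> C\t0\t10\tauto\t1",
               "GROWTH\tC ->\t0\t10\tbiomass\t0"), path)
  m <- read_toy_model(path)
  env <- chemical_environment_space(
    data.frame(component = "A", exchange_id = "EX_A", role = "carbon"),
    uptake_bound_magnitude = 10)
  cs <- build_candidate_space(m, env)
  expect_setequal(cs$knockout_candidates, "R1")
  pr <- cs$provenance
  expect_identical(pr$reason[pr$reaction == "R2"], "no-gene-annotation")
  expect_identical(pr$reason[pr$reaction == "R3"],
                   "transport/exchange/diffusion/biomass")
})
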