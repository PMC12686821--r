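# The two-stage coupling score: analytic branch-toy values, oracle
# agreement (sign-enumeration LPs on the reference solver), FVA
# equivalence for single targets, and the score's structural properties.

branch_view <- function(knockouts = character(0)) {
  apply_constraints(make_branch_toy(), knockouts, "EX_A",
                    make_branch_env_space())
}

test_that("branch-toy scores match the analytic values", {
  cfg <- scoring_config(a = 1)
  expect_equal(evolvex_score(branch_view(), target_set(up = "R1"),
                             cfg)$value, 0)
  expect_equal(evolvex_score(branch_view("R3"), target_set(up = "R1"),
                             cfg)$value, 1)
  expect_equal(evolvex_score(branch_view("R3"), target_set(up = "R1"),
                             scoring_config(a = 10))$value, 10)
  expect_equal(evolvex_score(branch_view(), target_set(down = "R3"),
                             cfg)$value, -1)
  expect_equal(min_total_uptake(branch_view(), cfg)$value, 1)
  expect_equal(min_total_uptake(branch_view(),
                                scoring_config(a = 10))$value, 10)
})

test_that("empty target sets score exactly zero", {
  sc <- evolvex_score(branch_view(), target_set(), scoring_config(a = 1))
  expect_identical(sc$value, 0)
  expect_true(sc$feasible)
})

test_that("infeasible designs get the -Inf sentinel, not an error", {
  # knocking out both routes to C makes growth impossible
  sc <- evolvex_score(branch_view(c("R2", "R3")), target_set(up = "R1"),
                      scoring_config(a = 1))
  expect_false(sc$feasible)
  expect_identical(sc$value, -Inf)
})

test_that("an uptake cap below the stage-1 minimum is infeasible", {
  cfg <- scoring_config(a = 10, uptake_cap = 5)   # needs 10
  r <- min_total_uptake(branch_view(), cfg)
  expect_false(r$feasible)
  sc <- evolvex_score(branch_view(), target_set(up = "R1"), cfg)
  expect_identical(sc$value, -Inf)
  # a cap above the minimum changes nothing
  cfg2 <- scoring_config(a = 10, uptake_cap = 75)
  expect_equal(min_total_uptake(branch_view(), cfg2)$value, 10)
})

test_that("score equals the sign-enumeration oracle on random designs", {
  cfg <- scoring_config(a = 1, bound_magnitude = 100)
  n_cases <- 0
  for (seed in 1:25) {
    m <- make_random_toy(12, seed = seed)
    env <- make_toy_env_space(m)
    internal <- m$rxns[m$category == "internal"]
    if (length(internal) < 2) next
    cases <- with_seed(1000 + seed, {
      lapply(1:2, function(i) {
        tg_pool <- sample(internal)
        list(up = tg_pool[1],
             down = if (length(tg_pool) > 2 && runif(1) < 0.5)
               tg_pool[2] else character(0),
             ko = if (runif(1) < 0.6)
               sample(setdiff(internal, tg_pool[1:2]),
                      min(1, length(internal) - 2)) else character(0),
             nut = sample(env$candidates$exchange_id,
                          min(2, nrow(env$candidates))))
      })
    })
    for (cs in cases) {
      view <- apply_constraints(m, cs$ko, cs$nut, env)
      tg <- target_set(up = cs$up, down = cs$down)
      mine <- evolvex_score(view, tg, cfg)
      oracle <- brute_force_score(view, tg, cfg)
      expect_equal(mine$feasible, oracle$feasible,
                   info = paste("seed", seed))
      if (mine$feasible && oracle$feasible) {
        n_cases <- n_cases + 1
        expect_equal(mine$value, oracle$value, tolerance = 1e-6,
                     info = paste("seed", seed))
      }
    }
  }
  expect_gt(n_cases, 20)
})

test_that("single up-target scores equal the FVA minimum under the pin", {
  cfg <- scoring_config(a = 1, bound_magnitude = 100)
  for (seed in c(3, 7, 9)) {
    m <- make_random_toy(12, seed = seed)
    env <- make_toy_env_space(m)
    internal <- m$rxns[m$category == "internal"]
    nut <- env$candidates$exchange_id[1]
    view <- apply_constraints(m, character(0), nut, env)
    prepared <- evolvexga:::prepare_view(view, cfg)
    st1 <- min_total_uptake(view, cfg)
    if (!st1$feasible) next
    urow <- evolvexga:::uptake_row(prepared)
    pin_A <- matrix(urow, 1)
    pin_rhs <- st1$value * (1 + cfg$uptake_slack) + cfg$uptake_slack
    for (tg in internal[seq_len(min(3, length(internal)))]) {
      mine <- evolvex_score(view, target_set(up = tg), cfg)
      ref <- ref_abs_min(prepared, tg, extra_A = pin_A,
                         extra_sense = "<=", extra_rhs = pin_rhs)
      expect_equal(mine$value, ref, tolerance = 1e-6,
                   info = paste(seed, tg))
    }
  }
})

test_that("joint up-target score is at least the sum of single scores", {
  cfg <- scoring_config(a = 1, bound_magnitude = 100)
  for (seed in c(2, 6)) {
    m <- make_random_toy(14, seed = seed)
    env <- make_toy_env_space(m)
    internal <- m$rxns[m$category == "internal"]
    if (length(internal) < 2) next
    pair <- with_seed(seed, sample(internal, 2))
    view <- apply_constraints(m, character(0),
                              env$candidates$exchange_id[1], env)
    joint <- evolvex_score(view, target_set(up = pair), cfg)$value
    singles <- sum(vapply(pair, function(t) {
      evolvex_score(view, target_set(up = t), cfg)$value
    }, numeric(1)))
    expect_gte(joint, singles - 1e-8)
  }
})

test_that("score scales linearly with the fixed growth when bounds are slack", {
  v1 <- evolvex_score(branch_view("R3"), target_set(up = "R1"),
                      scoring_config(a = 1))$value
  v2 <- evolvex_score(branch_view("R3"), target_set(up = "R1"),
                      scoring_config(a = 2))$value
  expect_equal(v2, 2 * v1)
})

test_that("reversible down-targets solve as MILP with exact absolute value", {
  # make R3 reversible so its down-target needs the big-M binary; the
  # worst case now runs R3 backward in a futile cycle with R1+R2, limited
  # only by R1's upper bound: |R3| = 20 - 1 = 19
  m <- make_branch_toy()
  m$lb[m$rxns == "R3"] <- -20
  env <- make_branch_env_space()
  view <- apply_constraints(m, character(0), "EX_A", env)
  sc <- evolvex_score(view, target_set(down = "R3"), scoring_config(a = 1))
  expect_identical(sc$problem_class, "MILP")
  expect_equal(sc$value, -19)
  expect_equal(unname(sc$per_target["R3"]), 19)
  # the sign-enumeration oracle agrees on the cycle worst case
  expect_equal(brute_force_score(view, target_set(down = "R3"),
                                 scoring_config(a = 1))$value, -19,
               tolerance = 1e-6)
})

test_that("scoring is deterministic for a fixed view and config", {
  cfg <- scoring_config(a = 1)
  s1 <- evolvex_score(branch_view("R3"), target_set(up = "R1"), cfg)
  s2 <- evolvex_score(branch_view("R3"), target_set(up = "R1"), cfg)
  expect_identical(s1$value, s2$value)
  expect_identical(s1$per_target, s2$per_target)
})

test_that("targets must exist and not overlap", {
  expect_error(target_set(up = "R1", down = "R1"), "both")
  expect_error(evolvex_score(branch_view(), target_set(up = "NOPE"),
                             scoring_config()), "not in model")
})
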