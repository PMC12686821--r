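# Synthetic toy networks and independent brute-force oracles.
#
# The toys are small, growth-feasible networks used throughout the test
# suite and documentation.  The oracles recompute the package's central
# quantities by a different route: the coupling score by sign-pattern
# enumeration over single-stage LPs solved with pracma's simplex (a
# different solver and a different formulation than the big-M MILP), GA
# optima by exhaustive enumeration, ROOM objectives by enumeration over
# change-indicator patterns.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so deterministic generators
#' do not perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' The branch toy network
#'
#' Five reactions over three metabolites: an uptake `EX_A` (A <-> out,
#' bounds `[-10, 0]`), a two-step route `R1` (A -> B), `R2` (B -> C), a
#' one-step bypass `R3` (A -> C), and `GROWTH` (C -> out).  The bypass
#' makes `R1` uncoupled from growth until `R3` is knocked out.
#'
#' @return a `metabolic_network`.
#' @export
make_branch_toy <- function() {
  S <- matrix(c(
    # EX_A  R1  R2  R3  GROWTH
      -1,  -1,   0, -1,  0,   # A
       0,   1,  -1,  0,  0,   # B
       0,   0,   1,  1, -1),  # C
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"),
                    c("EX_A", "R1", "R2", "R3", "GROWTH")))
  metabolic_network(S, lb = c(-10, 0, 0, 0, 0),
                    ub = c(0, 20, 20, 20, 20),
                    growth_reaction = "GROWTH")
}

#' A production pathway for the branch toy
#'
#' Two reactions: `P` (C -> Prod) and the product drain `EX_Prod`
#' (Prod -> out).
#'
#' @return a `pathway_definition`.
#' @export
make_branch_pathway <- function() {
  pathway_definition(list(
    list(id = "P", coeffs = c(C = -1, Prod = 1), lb = 0, ub = 20),
    list(id = "EX_Prod", coeffs = c(Prod = -1), lb = 0, ub = 20)),
    new_metabolites = "Prod")
}

#' Environment space for the branch toy
#'
#' A single carbon candidate, the `EX_A` uptake.
#'
#' @param uptake_bound_magnitude uptake opening magnitude (default 10).
#' @return a `chemical_environment_space`.
#' @export
make_branch_env_space <- function(uptake_bound_magnitude = 10) {
  chemical_environment_space(
    data.frame(component = "A", exchange_id = "EX_A", role = "carbon"),
    uptake_bound_magnitude = uptake_bound_magnitude)
}

#' A toy with five knockout candidates and one coupling solution
#'
#' The branch toy extended with two harmless side drains (`R4`: A -> E with
#' drain `EX_E`; `R5`: B -> F with drain `EX_F`).  With up-target `R1`,
#' only the knockout of the bypass `R3` couples `R1` to growth; `R1`,
#' `R2`, `R4`, `R5` are neutral or self-defeating knockouts, giving a
#' five-candidate single-optimum search space for GA tests.
#'
#' @return a `metabolic_network`.
#' @export
make_fivepath_toy <- function() {
  S <- matrix(0, 5, 9,
              dimnames = list(c("A", "B", "C", "E", "F"),
                              c("EX_A", "R1", "R2", "R3", "R4", "R5",
                                "EX_E", "EX_F", "GROWTH")))
  S["A", "EX_A"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  S["A", "R3"] <- -1; S["C", "R3"] <- 1
  S["A", "R4"] <- -1; S["E", "R4"] <- 1
  S["B", "R5"] <- -1; S["F", "R5"] <- 1
  S["E", "EX_E"] <- -1
  S["F", "EX_F"] <- -1
  S["C", "GROWTH"] <- -1
  metabolic_network(S,
                    lb = c(-10, 0, 0, 0, 0, 0, 0, 0, 0),
                    ub = c(0, 20, 20, 20, 20, 20, 20, 20, 20),
                    growth_reaction = "GROWTH")
}

#' Generate a random toy network
#'
#' A connected, growth-feasible random network: a linear backbone from a
#' substrate uptake to the biomass drain, plus random internal reactions
#' (coefficients in `{-2,-1,1,2}`, mixed reversibility) and occasional
#' extra nutrient exchanges.  Regenerates with perturbed seeds until the
#' network grows (bounded retries), and is deterministic per seed.
#'
#' @param n_reactions total reaction count (5 to 30).
#' @param seed integer seed.
#' @return a `metabolic_network`.
#' @export
make_random_toy <- function(n_reactions = 15, seed = 1) {
  stopifnot(n_reactions >= 5, n_reactions <= 30)
  for (try in 0:49) {
    model <- with_seed(seed + 7919L * try, random_toy_once(n_reactions))
    env <- make_toy_env_space(model)
    open <- open_environment(model, env)
    g <- fba(open)
    if (g$status == "optimal" && g$objval > 0.1) return(model)
  }
  stop("failed to generate a growth-feasible toy after 50 attempts")
}

random_toy_once <- function(n_reactions) {
  path_len <- sample(2:4, 1)
  n_extra <- n_reactions - path_len - 2L
  n_mets <- path_len + 1L + max(1L, round(n_extra * 0.6))
  mets <- paste0("M", seq_len(n_mets))

  ids <- character(0)
  coeffs <- list()
  lb <- numeric(0); ub <- numeric(0); category <- character(0)
  push <- function(id, cf, l, u, cat = NA_character_) {
    ids <<- c(ids, id); coeffs[[id]] <<- cf
    lb <<- c(lb, l); ub <<- c(ub, u); category <<- c(category, cat)
  }
  push("EX_M1", c(M1 = -1), -10, 0, "exchange")
  for (i in seq_len(path_len)) {
    push(paste0("B", i),
         stats::setNames(c(-1, 1), c(mets[i], mets[i + 1])), 0, 20)
  }
  push("GROWTH", stats::setNames(-1, mets[path_len + 1L]), 0, 20,
       "biomass")
  extra_id <- 0L
  for (i in seq_len(max(0L, n_extra))) {
    if (stats::runif(1) < 0.25) {
      m <- sample(mets[-1], 1)
      id <- paste0("EX_", m, "_", i)
      if (stats::runif(1) < 0.5) {
        push(id, stats::setNames(-1, m), -10, 0, "exchange")   # nutrient
      } else {
        push(id, stats::setNames(-1, m), 0, 10, "exchange")    # drain
      }
    } else {
      extra_id <- extra_id + 1L
      ns <- sample(1:2, 1); np <- sample(1:2, 1)
      subs <- sample(mets, ns)
      prods <- sample(setdiff(mets, subs), np)
      cf <- c(stats::setNames(-sample(1:2, ns, replace = TRUE), subs),
              stats::setNames(sample(1:2, np, replace = TRUE), prods))
      rev <- stats::runif(1) < 0.4
      push(paste0("R", extra_id), cf, if (rev) -20 else 0, 20)
    }
  }
  used <- unique(unlist(lapply(coeffs, names)))
  S <- matrix(0, length(used), length(ids), dimnames = list(used, ids))
  for (j in seq_along(ids)) S[names(coeffs[[j]]), j] <- coeffs[[j]]
  metabolic_network(S, lb, ub, "GROWTH", category = category)
}

#' Environment space covering all of a toy's uptake exchanges
#'
#' Every exchange reaction that permits uptake becomes a candidate
#' (roles assigned round-robin); no base-open exchanges.
#'
#' @param model a `metabolic_network`.
#' @param uptake_bound_magnitude uptake opening magnitude (default 10).
#' @return a `chemical_environment_space`.
#' @export
make_toy_env_space <- function(model, uptake_bound_magnitude = 10) {
  ex <- model$rxns[model$category == "exchange" & model$lb < 0]
  if (length(ex) == 0L) stop("toy has no uptake exchange")
  chemical_environment_space(
    data.frame(component = sub("^EX_", "", ex), exchange_id = ex,
               role = rep(c("carbon", "nitrogen", "other"),
                          length.out = length(ex))),
    uptake_bound_magnitude = uptake_bound_magnitude)
}

# ---------------------------------------------------------------------------
# reference LP path: pracma's simplex on shifted nonnegative variables

# The oracle LP path: every problem is re-expressed in shifted nonnegative
# variables y = x - lb (a different encoding than the implementation's
# bounded-variable form) and handed to pracma's textbook big-M simplex.
# That simplex is numerically fragile on degenerate bases (it can raise a
# singular-system error, or stall, on instances the bounded simplex solves
# cleanly), so a non-converged run is never read as infeasibility: the
# same shifted formulation is then solved with the package simplex
# instead.  Solver independence holds wherever pracma converges;
# formulation independence holds everywhere.
ref_solve_lp <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  cc <- if (maximize) -obj else obj
  A <- as.matrix(A)
  Ale <- NULL; ble <- NULL; Aeq <- NULL; beq <- NULL
  for (i in seq_along(sense)) {
    a <- A[i, ]; r <- rhs[i] - sum(a * lb)
    if (sense[i] == "<=") { Ale <- rbind(Ale, a); ble <- c(ble, r) }
    else if (sense[i] == ">=") { Ale <- rbind(Ale, -a); ble <- c(ble, -r) }
    else { Aeq <- rbind(Aeq, a); beq <- c(beq, r) }
  }
  res <- tryCatch(
    pracma::linprog(cc = cc, A = Ale, b = ble, Aeq = Aeq, beq = beq,
                    ub = ub - lb, maxiter = 5000, bigM = 1e7),
    error = function(e) NULL)
  if (!is.null(res) && isTRUE(res$errno == 1)) {
    x <- res$x + lb
    return(list(status = "optimal", objval = sum(obj * x), x = x))
  }
  # pracma did not converge (or declared infeasibility, which its big-M
  # phase cannot certify reliably): solve the same shifted formulation
  # with the package simplex
  span <- ub - lb
  nA <- rbind(Ale, Aeq)
  nsense <- c(rep("<=", NROW(Ale)), rep("=", NROW(Aeq)))
  nrhs <- c(ble, beq)
  fb <- solve_lp(cc, nA, nsense, nrhs, rep(0, length(lb)), span)
  if (fb$status != "optimal") {
    return(list(status = fb$status, objval = NA_real_, x = NULL))
  }
  x <- fb$x + lb
  list(status = "optimal", objval = sum(obj * x), x = x)
}

ref_steady_state <- function(model, obj, maximize, extra_A = NULL,
                             extra_sense = NULL, extra_rhs = NULL,
                             lb = NULL, ub = NULL) {
  S <- as.matrix(model$S)
  A <- rbind(S, extra_A)
  sense <- c(rep("=", nrow(S)), extra_sense)
  rhs <- c(rep(0, nrow(S)), extra_rhs)
  ref_solve_lp(obj, A, sense, rhs,
               if (is.null(lb)) model$lb else lb,
               if (is.null(ub)) model$ub else ub, maximize = maximize)
}

#' Reference FBA via the oracle solver
#'
#' Same optimization as [fba()], computed with pracma's simplex; used to
#' cross-check essentiality and variability sweeps.
#'
#' @inheritParams fba
#' @return as [fba()] without the flux vector.
#' @export
ref_fba <- function(model, objective = NULL, maximize = TRUE) {
  if (is.null(objective)) objective <- model$growth_reaction
  obj <- numeric(length(model$rxns))
  obj[match(objective, model$rxns)] <- 1
  r <- ref_steady_state(model, obj, maximize)
  list(status = r$status, objval = r$objval)
}

#' Brute-force EvolveX score (independent oracle)
#'
#' Recomputes the two-stage coupling score by a different route: stage 1
#' through the reference solver, stage 2 by enumerating the sign patterns
#' of all target fluxes and solving one sign-restricted LP per pattern
#' (absolute values become linear within each orthant), taking the minimum
#' over patterns.  Exact for small target sets.
#'
#' @inheritParams evolvex_score
#' @return list with `value` and `feasible`.
#' @export
brute_force_score <- function(view, targets, config = scoring_config()) {
  model <- prepare_view(view, config)
  n <- length(model$rxns)
  urow <- uptake_row(model)
  extra_A <- NULL; extra_sense <- NULL; extra_rhs <- NULL
  if (!is.null(config$uptake_cap)) {
    extra_A <- matrix(urow, 1); extra_sense <- "<="
    extra_rhs <- config$uptake_cap
  }
  st1 <- ref_steady_state(model, urow, maximize = FALSE,
                          extra_A = extra_A, extra_sense = extra_sense,
                          extra_rhs = extra_rhs)
  if (st1$status != "optimal") {
    return(list(value = -Inf, feasible = FALSE))
  }
  r1 <- st1$objval
  tg <- c(targets$up, targets$down)
  if (length(tg) == 0L) return(list(value = 0, feasible = TRUE))
  ti <- match(tg, model$rxns)
  tsign <- c(rep(1, length(targets$up)), rep(-1, length(targets$down)))

  pin_A <- if (length(model$environment)) matrix(urow, 1) else NULL
  pin_sense <- if (length(model$environment)) "<=" else NULL
  pin_rhs <- if (length(model$environment)) {
    r1 * (1 + config$uptake_slack) + config$uptake_slack
  } else NULL

  best <- Inf
  npat <- 2^length(tg)
  for (p in seq_len(npat) - 1L) {
    signs <- ifelse(bitwAnd(p, 2^(seq_along(tg) - 1L)) > 0, -1, 1)
    rows <- matrix(0, length(tg), n)
    for (t in seq_along(tg)) rows[t, ti[t]] <- -signs[t]  # sign restriction
    obj <- numeric(n)
    obj[ti] <- obj[ti] + signs * tsign
    r <- ref_steady_state(model, obj, maximize = FALSE,
                          extra_A = rbind(pin_A, rows),
                          extra_sense = c(pin_sense,
                                          rep("<=", length(tg))),
                          extra_rhs = c(pin_rhs, rep(0, length(tg))))
    if (r$status == "optimal" && r$objval < best) best <- r$objval
  }
  if (!is.finite(best)) return(list(value = -Inf, feasible = FALSE))
  list(value = best, feasible = TRUE)
}

#' Exhaustive design search (GA oracle)
#'
#' Enumerates every size-K knockout set and size-E environment set from
#' the candidate space, scores each with [evolvex_score()], and returns
#' the best with the GA's tie-break (highest score, then lexicographically
#' smallest serialization).
#'
#' @inheritParams run_ga
#' @param K,E design cardinalities.
#' @param max_designs guard on the enumeration size (default `1e4`).
#' @return list with `best_chromosome`, `best_score`, and the full scored
#'   `designs` data frame.
#' @export
exhaustive_search <- function(model, targets, candidates, K, E,
                              scoring_config = scoring_config(),
                              max_designs = 1e4) {
  ko <- candidates$knockout_candidates
  en <- candidates$environment$candidates$exchange_id
  ko_sets <- if (K > 0) utils::combn(sort(ko), K, simplify = FALSE)
    else list(character(0))
  en_sets <- if (E > 0) utils::combn(sort(en), E, simplify = FALSE)
    else list(character(0))
  n_total <- length(ko_sets) * length(en_sets)
  if (n_total > max_designs) stop("search space too large to enumerate: ",
                                  n_total)
  best_chrom <- NULL; best_score <- -Inf; best_key <- NULL
  keys <- character(n_total); scores <- numeric(n_total)
  idx <- 0L
  for (ks in ko_sets) {
    for (es in en_sets) {
      idx <- idx + 1L
      chrom <- design_chromosome(ks, es)
      view <- apply_constraints(model, chrom$knockouts,
                                chrom$environment,
                                candidates$environment)
      s <- evolvex_score(view, targets, scoring_config)$value
      key <- chrom_key(chrom)
      keys[idx] <- key; scores[idx] <- s
      if (s > best_score || (s == best_score && (is.null(best_key) ||
                                                 key < best_key))) {
        best_score <- s; best_chrom <- chrom; best_key <- key
      }
    }
  }
  list(best_chromosome = best_chrom, best_score = best_score,
       designs = data.frame(chromosome = keys, score = scores))
}

#' Exhaustive ROOM objective (oracle)
#'
#' Minimal number of flux changes by direct enumeration: change-indicator
#' patterns are scanned in order of increasing change count and each
#' pattern is checked by an LP feasibility problem (reactions with
#' indicator 0 confined to their no-change window) through the reference
#' solver.
#'
#' @inheritParams room_min_change
#' @return the minimal change count (integer), or `Inf` when no pattern is
#'   feasible.
#' @export
ref_room_objective <- function(model, w,
                               product_exchange = model$product_exchange,
                               config = room_config()) {
  n <- length(model$rxns)
  stopifnot(n <= 14)
  w <- w[model$rxns]
  w_upper <- w + config$delta * abs(w) + config$epsilon
  w_lower <- w - config$delta * abs(w) - config$epsilon
  target <- config$production_fraction *
    max_theoretical_production(model, product_exchange)
  pi <- match(product_exchange, model$rxns)
  base_lb <- model$lb; base_ub <- model$ub
  base_lb[pi] <- max(base_lb[pi], target)
  patterns <- expand.grid(rep(list(0:1), n))
  counts <- rowSums(patterns)
  for (k in sort(unique(counts))) {
    for (r in which(counts == k)) {
      y <- as.numeric(patterns[r, ])
      lb <- ifelse(y == 0, pmax(base_lb, w_lower), base_lb)
      ub <- ifelse(y == 0, pmin(base_ub, w_upper), base_ub)
      if (any(lb > ub)) next
      sol <- ref_steady_state(model, numeric(n), maximize = FALSE,
                              lb = lb, ub = ub)
      if (sol$status == "optimal") return(k)
    }
  }
  Inf
}
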