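# Genetic algorithm over fixed-cardinality designs: each individual is a
# set of exactly K reaction knockouts plus a set of exactly E chemical
# environment components.  Elitism carries the best individuals unchanged;
# crossover resamples a child segment from the union of the parents'
# segments; mutation swaps one active element for an inactive candidate.
# Fitness is the EvolveX score; infeasible designs score -Inf and rank
# last.

#' GA configuration
#'
#' @param population_size individuals per generation (default 50).
#' @param elite_count best individuals carried unchanged (default 10).
#' @param crossover_probability,mutation_probability applied independently
#'   per segment (knockouts, environment); default 0.8 each.
#' @param generations number of generations to run.
#' @param K knockouts per individual (default 4).
#' @param E environment components per individual (default 3).
#' @param seed RNG seed for the whole run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, elite_count = 10,
                      crossover_probability = 0.8,
                      mutation_probability = 0.8,
                      generations = 50, K = 4, E = 3, seed = 1) {
  stopifnot(elite_count < population_size,
            crossover_probability >= 0, crossover_probability <= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            K >= 0, E >= 0, generations >= 1)
  structure(list(population_size = population_size,
                 elite_count = elite_count,
                 crossover_probability = crossover_probability,
                 mutation_probability = mutation_probability,
                 generations = generations, K = K, E = E, seed = seed),
            class = "ga_config")
}

#' Construct a design chromosome
#'
#' @param knockouts character vector of exactly K reaction ids.
#' @param environment character vector of exactly E component exchange ids.
#' @return an object of class `design_chromosome` (sets stored sorted).
#' @export
design_chromosome <- function(knockouts, environment) {
  structure(list(knockouts = sort(unique(as.character(knockouts))),
                 environment = sort(unique(as.character(environment)))),
            class = "design_chromosome")
}

chrom_key <- function(chrom) {
  paste0("K[", paste(chrom$knockouts, collapse = ","), "]E[",
         paste(chrom$environment, collapse = ","), "]")
}

#' Serialize a chromosome as a binary vector
#'
#' One position per knockout candidate followed by one per environment
#' candidate; value 0 marks an active knockout or a selected component,
#' value 1 an untouched one.
#'
#' @param chrom a `design_chromosome`.
#' @param candidates a `candidate_space`.
#' @return named integer vector of 0/1.
#' @export
serialize_chromosome <- function(chrom, candidates) {
  ko <- candidates$knockout_candidates
  en <- candidates$environment$candidates$exchange_id
  bits <- c(ifelse(ko %in% chrom$knockouts, 0L, 1L),
            ifelse(en %in% chrom$environment, 0L, 1L))
  names(bits) <- c(paste0("ko:", ko), paste0("env:", en))
  bits
}

# sample() treats a length-1 numeric x as 1:x; guard against that
resample <- function(x, size) x[sample.int(length(x), size)]

#' Initialize a GA population
#'
#' Each chromosome gets K distinct knockouts and E distinct components
#' sampled uniformly from the candidate space.  Uses the current RNG
#' stream.
#'
#' @param candidates a `candidate_space`.
#' @param config a [ga_config()].
#' @return list of `design_chromosome`.
#' @export
init_population <- function(candidates, config) {
  ko <- candidates$knockout_candidates
  en <- candidates$environment$candidates$exchange_id
  if (config$K > length(ko)) stop("K exceeds knockout candidate count")
  if (config$E > length(en)) stop("E exceeds environment candidate count")
  lapply(seq_len(config$population_size), function(i) {
    design_chromosome(resample(ko, config$K), resample(en, config$E))
  })
}

#' Crossover two chromosomes
#'
#' Independently per segment, with the configured probability the child's
#' segment is a uniform size-preserving subset of the union of the parents'
#' segments; otherwise it is copied from the first parent.
#'
#' @param parent_a,parent_b `design_chromosome`s.
#' @param config a [ga_config()].
#' @return a `design_chromosome`.
#' @export
crossover <- function(parent_a, parent_b, config) {
  cross_segment <- function(a, b, size) {
    if (size > 0 && stats::runif(1) < config$crossover_probability) {
      resample(union(a, b), size)
    } else {
      a
    }
  }
  design_chromosome(
    cross_segment(parent_a$knockouts, parent_b$knockouts, config$K),
    cross_segment(parent_a$environment, parent_b$environment, config$E))
}

#' Mutate a chromosome
#'
#' Independently per segment, with the configured probability one active
#' element is swapped for a uniformly chosen inactive candidate.  A segment
#' with no inactive candidate is left unchanged.
#'
#' @param chrom a `design_chromosome`.
#' @param candidates a `candidate_space`.
#' @param config a [ga_config()].
#' @return a `design_chromosome`.
#' @export
mutate <- function(chrom, candidates, config) {
  mutate_segment <- function(active, pool) {
    if (length(active) == 0L ||
        stats::runif(1) >= config$mutation_probability) {
      return(active)
    }
    inactive <- setdiff(pool, active)
    if (length(inactive) == 0L) return(active)
    out_el <- resample(active, 1)
    in_el <- resample(inactive, 1)
    c(setdiff(active, out_el), in_el)
  }
  design_chromosome(
    mutate_segment(chrom$knockouts, candidates$knockout_candidates),
    mutate_segment(chrom$environment,
                   candidates$environment$candidates$exchange_id))
}

order_population <- function(scores, keys) {
  # -Inf-safe: rank by descending score, ties by lexicographic key
  ord <- order(keys)
  ord[order(-scores[ord])]
}

#' Run the genetic algorithm
#'
#' Scores every individual (memoized by chromosome identity), carries the
#' `elite_count` best unchanged, and fills the rest of each generation by
#' uniform parent selection, crossover and mutation.  Deterministic for a
#' fixed seed.
#'
#' @param model a `metabolic_network` (with pathway added).
#' @param targets a [target_set()].
#' @param candidates a `candidate_space` from [build_candidate_space()].
#' @param scoring_config a [scoring_config()].
#' @param config a [ga_config()].
#' @param progress if `TRUE`, log per-generation best scores.
#' @return an object of class `ga_run`: `best_chromosome`, `best_score`,
#'   `trajectory` (per-generation best/mean), `archive` (every evaluated
#'   chromosome with its score), `feasible`, plus config echoes.
#' @export
run_ga <- function(model, targets, candidates,
                   scoring_config = scoring_config(),
                   config = ga_config(), progress = FALSE) {
  set.seed(config$seed)
  env_space <- candidates$environment
  memo <- new.env(parent = emptyenv())
  score_of <- function(chrom) {
    key <- chrom_key(chrom)
    if (!is.null(memo[[key]])) return(memo[[key]])
    view <- apply_constraints(model, chrom$knockouts, chrom$environment,
                              env_space)
    s <- evolvex_score(view, targets, scoring_config)$value
    memo[[key]] <- s
    s
  }
  pop <- init_population(candidates, config)
  trajectory <- data.frame(generation = integer(0), best = numeric(0),
                           mean = numeric(0))
  best_chrom <- NULL
  best_score <- -Inf
  best_key <- ""
  for (gen in seq_len(config$generations)) {
    scores <- vapply(pop, score_of, numeric(1))
    keys <- vapply(pop, chrom_key, character(1))
    ord <- order_population(scores, keys)
    gen_best <- scores[ord[1]]
    if (gen_best > best_score ||
        (gen_best == best_score && keys[ord[1]] < best_key)) {
      best_score <- gen_best
      best_chrom <- pop[[ord[1]]]
      best_key <- keys[ord[1]]
    }
    finite <- scores[is.finite(scores)]
    trajectory <- rbind(trajectory, data.frame(
      generation = gen, best = gen_best,
      mean = if (length(finite)) mean(finite) else NA_real_))
    if (progress) {
      message(sprintf("generation %d: best %.6g (feasible %d/%d)",
                      gen, gen_best, length(finite), length(scores)))
    }
    if (gen == config$generations) break
    elites <- pop[ord[seq_len(config$elite_count)]]
    children <- vector("list", config$population_size -
                         config$elite_count)
    for (i in seq_along(children)) {
      parents <- sample.int(length(pop), 2)
      child <- crossover(pop[[parents[1]]], pop[[parents[2]]], config)
      children[[i]] <- mutate(child, candidates, config)
    }
    pop <- c(elites, children)
  }
  keys <- ls(memo)
  archive <- data.frame(
    chromosome = keys,
    score = vapply(keys, function(k) memo[[k]], numeric(1)),
    row.names = NULL)
  archive <- archive[order(-archive$score, archive$chromosome), ]
  structure(list(best_chromosome = best_chrom, best_score = best_score,
                 trajectory = trajectory, archive = archive,
                 feasible = is.finite(best_score),
                 scoring_config = scoring_config, config = config,
                 seed = config$seed),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat("ga_run:", nrow(x$trajectory), "generations,",
      nrow(x$archive), "designs evaluated\n")
  if (x$feasible) {
    cat("  best score:", format(x$best_score), "mmol/gCDW\n")
    cat("  knockouts:", paste(x$best_chromosome$knockouts,
                              collapse = ", "), "\n")
    cat("  environment:", paste(x$best_chromosome$environment,
                                collapse = ", "), "\n")
  } else {
    cat("  no feasible design found\n")
  }
  invisible(x)
}
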