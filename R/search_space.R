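# Search-space pruning: the GA's knockout candidates are the model's
# reactions minus growth-essential, production-essential and blocked
# reactions, reactions without gene annotation, transport/exchange/
# diffusion pseudo-reactions, and any user-supplied extra exclusions
# (e.g. lipid metabolism).

# open every candidate (and base-open) exchange for uptake at the
# environment's bound magnitude; used as the superset environment for
# essentiality and blocked-reaction screens
open_environment <- function(model, env_space) {
  ids <- c(env_space$candidates$exchange_id, env_space$base_open)
  idx <- match(ids, model$rxns)
  if (anyNA(idx)) stop("exchange id not in model: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  model$lb[idx] <- pmin(model$lb[idx], -env_space$uptake_bound_magnitude)
  model
}

essential_sweep <- function(model, objective, essentiality_fraction) {
  base <- fba(model, objective = objective)
  if (base$status != "optimal") stop("base model infeasible for ",
                                     objective)
  cutoff <- essentiality_fraction * base$objval
  ess <- character(0)
  for (j in seq_along(model$rxns)) {
    ko <- model
    ko$lb[j] <- 0; ko$ub[j] <- 0
    r <- fba(ko, objective = objective)
    if (r$status != "optimal" || r$objval < cutoff) {
      ess <- c(ess, model$rxns[j])
    }
  }
  ess
}

#' Growth-essential reactions
#'
#' Single-deletion sweep with every candidate exchange open: a reaction is
#' essential when forcing its bounds to `[0, 0]` drops the maximum growth
#' below `essentiality_fraction` times the unconstrained maximum.
#'
#' @param model a `metabolic_network`.
#' @param env_space a [chemical_environment_space()].
#' @param essentiality_fraction relative growth cutoff (default `1e-6`, an
#'   LP noise floor).
#' @return character vector of reaction ids.
#' @export
find_growth_essential <- function(model, env_space,
                                  essentiality_fraction = 1e-6) {
  open <- open_environment(model, env_space)
  essential_sweep(open, open$growth_reaction, essentiality_fraction)
}

#' Production-essential reactions
#'
#' As [find_growth_essential()] with the objective replaced by the
#' heterologous product's exchange flux.
#'
#' @inheritParams find_growth_essential
#' @param product_exchange product exchange id; defaults to the model's.
#' @return character vector of reaction ids.
#' @export
find_production_essential <- function(model, env_space,
                                      product_exchange =
                                        model$product_exchange,
                                      essentiality_fraction = 1e-6) {
  if (is.null(product_exchange)) stop("no product exchange defined")
  open <- open_environment(model, env_space)
  essential_sweep(open, product_exchange, essentiality_fraction)
}

#' Blocked reactions
#'
#' Reactions that can carry no flux in any nutritional environment,
#' screened with all candidate exchanges simultaneously open (a superset
#' environment: under uptake-monotone feasible regions a reaction blocked
#' there is blocked in every sub-environment).  A reaction is blocked when
#' its flux-variability minimum and maximum are both within `tol` of zero.
#'
#' @inheritParams find_growth_essential
#' @param tol absolute flux tolerance (default `1e-9`).
#' @return character vector of reaction ids.
#' @export
find_blocked <- function(model, env_space, tol = 1e-9) {
  open <- open_environment(model, env_space)
  v <- fva(open)
  v$reaction[abs(v$min) <= tol & abs(v$max) <= tol]
}

#' Build the GA candidate space
#'
#' Applies the pruning rules and records one exclusion reason per removed
#' reaction (first matching rule in the order: growth-essential,
#' production-essential, blocked, no gene annotation, pseudo-reaction
#' category, extra exclusion).
#'
#' @inheritParams find_growth_essential
#' @param extra_exclusions additional reaction ids to remove (e.g. lipid
#'   metabolism).
#' @param include_production if `TRUE` (default when the model has a
#'   product exchange) production-essential reactions are excluded too.
#' @return an object of class `candidate_space` with fields
#'   `knockout_candidates`, `environment` (the env space) and `provenance`
#'   (data frame `reaction`, `reason`).
#' @export
build_candidate_space <- function(model, env_space,
                                  extra_exclusions = character(0),
                                  include_production =
                                    !is.null(model$product_exchange),
                                  essentiality_fraction = 1e-6,
                                  blocked_tol = 1e-9) {
  validate_env_space(env_space, model)
  ess_g <- find_growth_essential(model, env_space, essentiality_fraction)
  ess_p <- if (include_production) {
    find_production_essential(model, env_space,
                              essentiality_fraction = essentiality_fraction)
  } else character(0)
  blocked <- find_blocked(model, env_space, blocked_tol)
  no_gene <- model$rxns[!model$gene_associated]
  pseudo <- model$rxns[model$category %in%
                         c("transport", "exchange", "diffusion", "biomass")]
  reason <- stats::setNames(rep(NA_character_, length(model$rxns)),
                            model$rxns)
  mark <- function(ids, why) {
    fresh <- ids[is.na(reason[ids])]
    reason[fresh] <<- why
  }
  mark(ess_g, "growth-essential")
  mark(ess_p, "production-essential")
  mark(blocked, "blocked")
  mark(no_gene, "no-gene-annotation")
  mark(pseudo, "transport/exchange/diffusion/biomass")
  mark(intersect(extra_exclusions, model$rxns), "extra-exclusion")
  candidates <- model$rxns[is.na(reason)]
  if (length(candidates) == 0L) stop("no knockout candidates remain")
  provenance <- data.frame(reaction = names(reason)[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           row.names = NULL)
  structure(list(knockout_candidates = candidates,
                 environment = env_space, provenance = provenance),
            class = "candidate_space")
}

#' @export
print.candidate_space <- function(x, ...) {
  cat("candidate_space:", length(x$knockout_candidates),
      "knockout candidates,", nrow(x$environment$candidates),
      "environment candidates\n")
  tab <- table(x$provenance$reason)
  for (nm in names(tab)) cat("  excluded ", nm, ": ", tab[[nm]], "\n",
                             sep = "")
  invisible(x)
}
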