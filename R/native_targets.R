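# Native up-regulation targets via a ROOM variant.
#
# ROOM ordinarily predicts a deletion mutant's flux state by minimizing the
# number of reactions whose flux leaves a tolerance window around a
# wild-type reference.  Here the deletion constraint is replaced by a
# production requirement: the heterologous product's exchange flux must
# reach a fraction of its maximum theoretical value.  The minimal change
# set then contains the native precursor, energy and redox reactions that
# must move when the cellular objective shifts from growth to production;
# the subset whose flux increases becomes the up-target set for the
# coupling search.

#' ROOM configuration
#'
#' @param delta relative half-width of the no-change window (default 0.5).
#' @param epsilon absolute half-width floor (default 1e-5).
#' @param production_fraction required fraction of the maximum theoretical
#'   production (default 0.99).
#' @return an object of class `room_config`.
#' @export
room_config <- function(delta = 0.5, epsilon = 1e-5,
                        production_fraction = 0.99) {
  stopifnot(delta >= 0, epsilon > 0,
            production_fraction > 0, production_fraction <= 1)
  structure(list(delta = delta, epsilon = epsilon,
                 production_fraction = production_fraction),
            class = "room_config")
}

#' Wild-type reference flux state
#'
#' The parsimonious growth-maximal flux distribution: maximum growth, then
#' minimum total absolute flux.  Deterministic for a fixed model, which
#' removes the arbitrariness of alternate growth optima.
#'
#' @param model a `metabolic_network`.
#' @return named flux vector.
#' @export
wild_type_reference <- function(model) {
  pfba(model)$fluxes
}

#' Maximum theoretical production
#'
#' Maximizes the product exchange flux with growth left unconstrained
#' (only kept nonnegative).
#'
#' @param model a `metabolic_network`.
#' @param product_exchange product exchange id; defaults to the model's.
#' @param require_growth optional minimum growth flux (default 0).
#' @return the maximum product exchange flux.
#' @export
max_theoretical_production <- function(model,
                                       product_exchange =
                                         model$product_exchange,
                                       require_growth = 0) {
  if (is.null(product_exchange)) stop("no product exchange defined")
  gi <- match(model$growth_reaction, model$rxns)
  model$lb[gi] <- max(model$lb[gi], require_growth)
  r <- fba(model, objective = product_exchange)
  if (r$status != "optimal") stop("production optimization failed: ",
                                  r$status)
  r$objval
}

#' Minimal flux-change set for production (ROOM variant)
#'
#' Solves the MILP: minimize the number of reactions whose flux leaves the
#' window `[w - delta*|w| - epsilon, w + delta*|w| + epsilon]` around the
#' wild-type reference `w`, subject to steady state, bounds, and the
#' product exchange flux reaching `production_fraction` of its maximum
#' theoretical value.
#'
#' @param model a `metabolic_network` with finite bounds.
#' @param w wild-type reference fluxes (named, e.g. from
#'   [wild_type_reference()]).
#' @param product_exchange product exchange id; defaults to the model's.
#' @param config a [room_config()].
#' @return an object of class `room_result`: `changed` and `upregulated`
#'   reaction id sets, `objective` (number of changes), `fluxes`
#'   (production-state), `production`, `w_upper`, `w_lower`.
#' @export
room_min_change <- function(model, w,
                            product_exchange = model$product_exchange,
                            config = room_config()) {
  if (is.null(product_exchange)) stop("no product exchange defined")
  n <- length(model$rxns)
  w <- w[model$rxns]
  stopifnot(!anyNA(w))
  if (any(!is.finite(model$lb)) || any(!is.finite(model$ub))) {
    stop("ROOM requires finite bounds; see clamp_bounds()")
  }
  w_upper <- w + config$delta * abs(w) + config$epsilon
  w_lower <- w - config$delta * abs(w) - config$epsilon

  pmax_th <- max_theoretical_production(model, product_exchange)
  target <- config$production_fraction * pmax_th
  pi <- match(product_exchange, model$rxns)
  lb <- model$lb
  lb[pi] <- max(lb[pi], target)
  if (lb[pi] > model$ub[pi] + 1e-9) stop("production constraint infeasible")

  # variables: v (n) | y (n) binary
  S <- as.matrix(model$S)
  m <- nrow(S)
  rows <- vector("list", 1 + 2 * n)
  rows[[1]] <- cbind(S, matrix(0, m, n))
  sense <- rep("=", m)
  rhs <- rep(0, m)
  for (j in seq_len(n)) {
    up <- numeric(2 * n); lo <- numeric(2 * n)
    up[j] <- 1; up[n + j] <- -(model$ub[j] - w_upper[j])
    lo[j] <- 1; lo[n + j] <- -(model$lb[j] - w_lower[j])
    rows[[2 * j]] <- matrix(up, 1)
    rows[[2 * j + 1]] <- matrix(lo, 1)
    sense <- c(sense, "<=", ">=")
    rhs <- c(rhs, w_upper[j], w_lower[j])
  }
  A <- do.call(rbind, rows)
  obj <- c(rep(0, n), rep(1, n))
  res <- solve_milp(obj, A, sense, rhs,
                    c(lb, rep(0, n)), c(model$ub, rep(1, n)),
                    int_idx = (n + 1L):(2L * n))
  if (res$status != "optimal") stop("ROOM MILP infeasible")
  v <- stats::setNames(res$x[seq_len(n)], model$rxns)
  y <- round(res$x[(n + 1L):(2L * n)])
  changed <- model$rxns[y == 1]
  # upregulation is judged on flux magnitude: |v| beyond the window around
  # |w| (so a reversible flux growing in the negative direction counts)
  w_abs_upper <- abs(w) * (1 + config$delta) + config$epsilon
  upregulated <- model$rxns[y == 1 & abs(v) > w_abs_upper + 1e-9]
  structure(list(changed = changed, upregulated = upregulated,
                 objective = sum(y), fluxes = v,
                 production = v[[product_exchange]],
                 w_upper = stats::setNames(w_upper, model$rxns),
                 w_lower = stats::setNames(w_lower, model$rxns),
                 config = config),
            class = "room_result")
}

#' Extract the up-regulated reaction set
#'
#' Reactions whose production-state absolute flux exceeds the upper
#' no-change threshold; judging on absolute flux means a reversible
#' reaction growing in magnitude in the negative direction also counts.
#' This set feeds [evolvex_score()] / [run_ga()] as the up-target set.
#'
#' @param result a `room_result`.
#' @param w wild-type reference fluxes (same as passed to
#'   [room_min_change()]).
#' @param config the [room_config()] used.
#' @return character vector of reaction ids.
#' @export
extract_upregulated <- function(result, w = NULL, config = NULL) {
  if (is.null(w) || is.null(config)) return(result$upregulated)
  w <- w[names(result$fluxes)]
  w_abs_upper <- abs(w) * (1 + config$delta) + config$epsilon
  ids <- names(result$fluxes)[abs(result$fluxes) > w_abs_upper + 1e-9]
  intersect(result$changed, ids)
}

#' @export
print.room_result <- function(x, ...) {
  cat("room_result:", x$objective, "flux changes; production",
      format(x$production), "\n")
  cat("  changed:", paste(x$changed, collapse = ", "), "\n")
  cat("  upregulated:", paste(x$upregulated, collapse = ", "), "\n")
  invisible(x)
}
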