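# Constraint-based analyses on top of the LP core: flux balance analysis,
# flux variability analysis, and parsimonious FBA (used as the wild-type
# reference state).

#' Clamp model bounds to a global flux magnitude
#'
#' Replaces infinite bounds by the signed magnitude and clips finite bounds
#' into `[-magnitude, magnitude]`.
#'
#' @param model a `metabolic_network`.
#' @param magnitude positive flux cap.
#' @return the clamped model (a copy).
#' @export
clamp_bounds <- function(model, magnitude) {
  stopifnot(magnitude > 0)
  model$lb <- pmax(model$lb, -magnitude)
  model$ub <- pmin(model$ub, magnitude)
  model
}

steady_state_lp <- function(model, obj, maximize,
                            extra_A = NULL, extra_sense = NULL,
                            extra_rhs = NULL, lb = NULL, ub = NULL) {
  S <- as.matrix(model$S)
  m <- nrow(S)
  A <- S
  sense <- rep("=", m)
  rhs <- rep(0, m)
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    sense <- c(sense, extra_sense)
    rhs <- c(rhs, extra_rhs)
  }
  solve_lp(obj, A, sense, rhs,
           if (is.null(lb)) model$lb else lb,
           if (is.null(ub)) model$ub else ub,
           maximize = maximize)
}

#' Flux balance analysis
#'
#' Optimizes the flux of one reaction (by default the growth reaction)
#' subject to steady state and the model bounds.
#'
#' @param model a `metabolic_network` (typically a view from
#'   [apply_constraints()]).
#' @param objective reaction id to optimize; defaults to the growth
#'   reaction.
#' @param maximize direction, default `TRUE`.
#' @return list with `status`, `objval` and the full flux vector `fluxes`
#'   (named), or `NULL` fluxes when infeasible.
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  if (is.null(objective)) objective <- model$growth_reaction
  j <- match(objective, model$rxns)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  obj <- numeric(length(model$rxns))
  obj[j] <- 1
  res <- steady_state_lp(model, obj, maximize)
  if (res$status == "optimal") {
    list(status = "optimal", objval = res$objval,
         fluxes = stats::setNames(res$x, model$rxns))
  } else {
    list(status = res$status, objval = NA_real_, fluxes = NULL)
  }
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under steady state and bounds,
#' optionally with the growth flux fixed at a fraction of its maximum.
#'
#' @param model a `metabolic_network`.
#' @param reactions reaction ids to scan (default: all).
#' @param fix_growth if not `NULL`, fraction of the maximum growth at which
#'   the growth flux is fixed before scanning.
#' @return data frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = NULL, fix_growth = NULL) {
  if (is.null(reactions)) reactions <- model$rxns
  lb <- model$lb
  ub <- model$ub
  if (!is.null(fix_growth)) {
    g <- fba(model)
    if (g$status != "optimal") stop("model infeasible for growth")
    gi <- match(model$growth_reaction, model$rxns)
    lb[gi] <- ub[gi] <- fix_growth * g$objval
  }
  n <- length(model$rxns)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$rxns)
    if (is.na(j)) stop("unknown reaction: ", reactions[k])
    obj <- numeric(n); obj[j] <- 1
    lo <- steady_state_lp(model, obj, maximize = FALSE, lb = lb, ub = ub)
    hi <- steady_state_lp(model, obj, maximize = TRUE, lb = lb, ub = ub)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal (", lo$status, "/", hi$status,
           ") for ", reactions[k])
    }
    out$min[k] <- lo$objval
    out$max[k] <- hi$objval
  }
  out
}

#' Parsimonious flux distribution at maximum growth
#'
#' Maximizes growth, then minimizes the total absolute flux at that growth,
#' giving a deterministic reference flux state.
#'
#' @param model a `metabolic_network`.
#' @return list with `growth` (the maximum) and `fluxes` (named vector).
#' @export
pfba <- function(model) {
  g <- fba(model)
  if (g$status != "optimal") stop("model infeasible for growth")
  n <- length(model$rxns)
  gi <- match(model$growth_reaction, model$rxns)
  lb <- model$lb; ub <- model$ub
  lb[gi] <- ub[gi] <- g$objval
  # variables: v (n) then t (n) with t >= |v|; minimize sum t
  S <- as.matrix(model$S)
  m <- nrow(S)
  A <- rbind(cbind(S, matrix(0, m, n)),
             cbind(diag(n), -diag(n)),     # v - t <= 0
             cbind(-diag(n), -diag(n)))    # -v - t <= 0
  sense <- c(rep("=", m), rep("<=", 2 * n))
  rhs <- rep(0, m + 2 * n)
  tmax <- pmax(abs(lb), abs(ub))
  res <- solve_lp(c(rep(0, n), rep(1, n)), A, sense, rhs,
                  c(lb, rep(0, n)), c(ub, tmax))
  if (res$status != "optimal") stop("parsimonious step failed: ", res$status)
  list(growth = g$objval,
       fluxes = stats::setNames(res$x[seq_len(n)], model$rxns))
}
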