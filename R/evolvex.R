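# The EvolveX flux-coupling score: a two-stage optimization.
#
# Stage 1 finds the minimum absolute total uptake from the selected chemical
# environment that supports a fixed growth value a.  Stage 2, with total
# uptake pinned to that minimum (the maximal-yield regime), minimizes the
# sum of the up-regulation targets' absolute fluxes minus the sum of the
# down-regulation targets' absolute fluxes.  The optimum is the worst-case
# sum of the targets' flux couplings to growth: the guaranteed flux through
# the up-targets minus the flux the down-targets could still carry.  Units
# are flux per growth, i.e. mmol/gCDW.
#
# Absolute values are linearized exactly: for an up-target u the pair
#   v_u - v_|u| <= 0,  -v_u - v_|u| <= 0
# with v_|u| minimized gives v_|u| = |v_u|; for a down-target d the same
# pair bounds v_|d| from below and a big-M pair with a binary (for
# reversible targets) bounds it from above, pinning v_|d| = |v_d| at any
# feasible point.

#' Scoring configuration
#'
#' @param a fixed growth value the coupling is evaluated at; 10 is the
#'   conventional setting when the chemical environment is fixed and only
#'   knockouts are searched, 1 when environment and knockouts are searched
#'   together.
#' @param bound_magnitude global absolute flux cap applied to unbounded
#'   reactions (1000 with `a = 10`, 20000 with `a = 1` by convention).
#' @param uptake_cap optional ceiling on the absolute total uptake in
#'   mmol/gCDW (75 in restricted searches); stage 1 becomes infeasible when
#'   the minimal uptake exceeds it.
#' @param M big-M constant of the absolute-value linearization; must be at
#'   least twice the bound magnitude.
#' @param uptake_slack relative slack on the stage-2 uptake pin, guarding
#'   against solver-noise infeasibility.
#' @return an object of class `scoring_config`.
#' @export
scoring_config <- function(a = 1, bound_magnitude = 1000, uptake_cap = NULL,
                           M = 2 * bound_magnitude, uptake_slack = 1e-6) {
  stopifnot(a > 0, bound_magnitude > 0, M >= 2 * bound_magnitude)
  if (!is.null(uptake_cap)) stopifnot(uptake_cap > 0)
  structure(list(a = a, bound_magnitude = bound_magnitude,
                 uptake_cap = uptake_cap, M = M,
                 uptake_slack = uptake_slack),
            class = "scoring_config")
}

#' Define up- and down-regulation flux targets
#'
#' @param up reaction ids whose flux should be coupled upward with growth.
#' @param down reaction ids whose flux should be suppressed.
#' @param model optional `metabolic_network` to validate ids against.
#' @return an object of class `target_set`.
#' @export
target_set <- function(up = character(0), down = character(0),
                       model = NULL) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down))) {
    stop("a reaction cannot be both an up- and a down-regulation target")
  }
  if (!is.null(model)) {
    unknown <- setdiff(c(up, down), model$rxns)
    if (length(unknown)) stop("target not in model: ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(up = up, down = down), class = "target_set")
}

#' Read a target set from TSV
#'
#' Columns: `reaction_id`, `direction` (`up` or `down`).
#' @param path TSV file path.
#' @param model optional model for validation.
#' @return a `target_set`.
#' @export
read_targets_tsv <- function(path, model = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("reaction_id", "direction") %in% names(tab)),
            all(tab$direction %in% c("up", "down")))
  target_set(up = tab$reaction_id[tab$direction == "up"],
             down = tab$reaction_id[tab$direction == "down"],
             model = model)
}

prepare_view <- function(view, config) {
  model <- clamp_bounds(view, config$bound_magnitude)
  gi <- match(model$growth_reaction, model$rxns)
  model$lb[gi] <- config$a
  model$ub[gi] <- config$a
  model
}

# row of -1 over the selected environment exchanges (so row %*% v = total
# uptake magnitude, given v_n <= -1 forces those fluxes negative)
uptake_row <- function(model) {
  r <- numeric(length(model$rxns))
  r[match(model$environment, model$rxns)] <- -1
  r
}

#' Stage 1: minimum absolute total uptake at fixed growth
#'
#' Minimizes the summed uptake magnitude over the view's selected
#' environment exchanges with the growth flux fixed to `config$a`.  When a
#' total-uptake cap is configured and the minimum exceeds it, the result is
#' infeasible.
#'
#' @param view a constrained model from [apply_constraints()].
#' @param config a [scoring_config()].
#' @return list with `feasible`, `value` (mmol/gCDW), and per-nutrient
#'   `uptake`.
#' @export
min_total_uptake <- function(view, config = scoring_config()) {
  model <- prepare_view(view, config)
  n <- length(model$rxns)
  urow <- uptake_row(model)
  extra_A <- NULL; extra_sense <- character(0); extra_rhs <- numeric(0)
  if (!is.null(config$uptake_cap)) {
    extra_A <- matrix(urow, 1)
    extra_sense <- "<="
    extra_rhs <- config$uptake_cap
  }
  res <- steady_state_lp(model, urow, maximize = FALSE,
                         extra_A = extra_A, extra_sense = extra_sense,
                         extra_rhs = extra_rhs)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, value = NA_real_, uptake = NULL))
  }
  ui <- match(model$environment, model$rxns)
  list(feasible = TRUE, value = res$objval,
       uptake = stats::setNames(-res$x[ui], model$environment))
}

#' The EvolveX score of a design
#'
#' Evaluates the worst-case sum of the target fluxes' couplings to growth
#' for one constrained model view (a knockout set plus a chemical
#' environment): stage 1 pins the total nutrient uptake to its minimum at
#' fixed growth, stage 2 minimizes the summed absolute up-target flux minus
#' the summed absolute down-target flux.  Higher scores mean stronger
#' coupling; an infeasible view scores `-Inf` so that search routines can
#' rank it last.
#'
#' @param view a constrained model from [apply_constraints()].
#' @param targets a [target_set()].
#' @param config a [scoring_config()].
#' @return an object of class `evolvex_score`: `value` (mmol/gCDW),
#'   `feasible`, `r_uptake_max`, `per_target` (absolute flux of each target
#'   at the optimum), `uptake` (per-nutrient uptake magnitude), and
#'   `problem_class` (`"LP"` or `"MILP"`).
#' @export
evolvex_score <- function(view, targets, config = scoring_config()) {
  stopifnot(inherits(targets, "target_set"))
  unknown <- setdiff(c(targets$up, targets$down), view$rxns)
  if (length(unknown)) stop("target not in model: ",
                            paste(unknown, collapse = ", "))
  stage1 <- min_total_uptake(view, config)
  if (!stage1$feasible) {
    return(new_score(-Inf, FALSE, NA_real_, NULL, NULL, "LP"))
  }
  k <- length(targets$up); l <- length(targets$down)
  if (k + l == 0L) {
    return(new_score(0, TRUE, stage1$value, numeric(0), stage1$uptake,
                     "LP"))
  }

  model <- prepare_view(view, config)
  n <- length(model$rxns)
  up_i <- match(targets$up, model$rxns)
  dn_i <- match(targets$down, model$rxns)
  dn_rev <- model$lb[dn_i] < 0 & model$ub[dn_i] > 0
  nbin <- sum(dn_rev)
  M <- config$M

  # variables: v (n) | v_|u| (k) | v_|d| (l) | d_|d| (nbin)
  nv <- n + k + l + nbin
  vu_ub <- pmax(abs(model$lb[up_i]), abs(model$ub[up_i]))
  vd_ub <- pmax(abs(model$lb[dn_i]), abs(model$ub[dn_i]))
  lb <- c(model$lb, rep(0, k), rep(0, l), rep(0, nbin))
  ub <- c(model$ub, vu_ub, vd_ub, rep(1, nbin))
  obj <- c(rep(0, n), rep(1, k), rep(-1, l), rep(0, nbin))

  S <- as.matrix(model$S)
  m <- nrow(S)
  rows <- list(cbind(S, matrix(0, m, nv - n)))
  sense <- rep("=", m)
  rhs <- rep(0, m)
  add_row <- function(r, s, b) {
    rows[[length(rows) + 1L]] <<- matrix(r, 1)
    sense <<- c(sense, s)
    rhs <<- c(rhs, b)
  }
  if (length(model$environment)) {
    add_row(c(uptake_row(model), rep(0, nv - n)), "<=",
            stage1$value * (1 + config$uptake_slack) +
              config$uptake_slack)
  }
  for (t in seq_len(k)) {
    r <- numeric(nv); r[up_i[t]] <- 1; r[n + t] <- -1
    add_row(r, "<=", 0)
    r <- numeric(nv); r[up_i[t]] <- -1; r[n + t] <- -1
    add_row(r, "<=", 0)
  }
  bpos <- 0L
  for (t in seq_len(l)) {
    vd <- dn_i[t]; ad <- n + k + t
    r <- numeric(nv); r[vd] <- 1; r[ad] <- -1
    add_row(r, "<=", 0)
    r <- numeric(nv); r[vd] <- -1; r[ad] <- -1
    add_row(r, "<=", 0)
    if (dn_rev[t]) {
      bpos <- bpos + 1L
      bd <- n + k + l + bpos
      r <- numeric(nv); r[vd] <- -1; r[bd] <- -M; r[ad] <- 1
      add_row(r, "<=", 0)
      r <- numeric(nv); r[vd] <- 1; r[bd] <- M; r[ad] <- 1
      add_row(r, "<=", M)
    } else if (model$lb[vd] >= 0) {
      # irreversible forward: |v_d| = v_d, binary fixed at 0
      r <- numeric(nv); r[vd] <- -1; r[ad] <- 1
      add_row(r, "<=", 0)
    } else {
      # irreversible backward: |v_d| = -v_d, binary fixed at 1
      r <- numeric(nv); r[vd] <- 1; r[ad] <- 1
      add_row(r, "<=", 0)
    }
  }
  A <- do.call(rbind, rows)
  int_idx <- if (nbin > 0) (n + k + l + 1L):nv else integer(0)
  res <- if (nbin > 0) {
    solve_milp(obj, A, sense, rhs, lb, ub, int_idx)
  } else {
    solve_lp(obj, A, sense, rhs, lb, ub)
  }
  if (res$status != "optimal") {
    return(new_score(-Inf, FALSE, stage1$value, NULL, stage1$uptake,
                     if (nbin > 0) "MILP" else "LP"))
  }
  x <- res$x
  per_target <- stats::setNames(
    c(x[n + seq_len(k)], x[n + k + seq_len(l)]),
    c(targets$up, targets$down))
  # absolute-value exactness at the optimum
  abs_err <- max(abs(per_target - abs(x[c(up_i, dn_i)])), 0)
  if (abs_err > 1e-5) {
    stop("absolute-value linearization violated (", abs_err, ")")
  }
  ui <- match(model$environment, model$rxns)
  new_score(res$objval, TRUE, stage1$value, per_target,
            stats::setNames(-x[ui], model$environment),
            if (nbin > 0) "MILP" else "LP")
}

new_score <- function(value, feasible, r_uptake_max, per_target, uptake,
                      problem_class) {
  structure(list(value = value, feasible = feasible,
                 r_uptake_max = r_uptake_max, per_target = per_target,
                 uptake = uptake, problem_class = problem_class),
            class = "evolvex_score")
}

#' @export
print.evolvex_score <- function(x, ...) {
  if (!x$feasible) {
    cat("evolvex_score: infeasible design\n")
    return(invisible(x))
  }
  cat("evolvex_score:", format(x$value), "mmol/gCDW (",
      x$problem_class, ")\n")
  cat("  minimal total uptake:", format(x$r_uptake_max), "mmol/gCDW\n")
  if (length(x$per_target)) {
    cat("  per-target |flux|:",
        paste(names(x$per_target), format(x$per_target), sep = "=",
              collapse = ", "), "\n")
  }
  if (length(x$uptake)) {
    cat("  uptake:", paste(names(x$uptake), format(x$uptake), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}
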