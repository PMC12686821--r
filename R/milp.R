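# Mixed-integer LP by LP-relaxation branch-and-bound.
#
# Binaries appear in two places in the package: the big-M absolute-value
# device for reversible down-regulation targets in the coupling score, and
# the per-reaction change indicators of the ROOM variant.  Counts are small
# (a handful to a few tens), so depth-first branch-and-bound over the
# bounded simplex is entirely adequate.

MILP_INT_TOL <- 1e-6

#' Solve a mixed-integer linear program
#'
#' Same problem form as [solve_lp()], with the variables indexed by
#' `int_idx` additionally required to take integer values (in practice these
#' are binaries with bounds `[0, 1]`).  Depth-first branch-and-bound on the
#' most fractional variable, warm-started incumbent pruning.
#'
#' @inheritParams solve_lp
#' @param int_idx integer vector of variable indices constrained to be
#'   integral.
#' @return as [solve_lp()]; `status` is `"optimal"` or `"infeasible"`.
#' @export
solve_milp <- function(obj, A, sense, rhs, lb, ub, int_idx,
                       maximize = FALSE, max_nodes = 100000L) {
  if (length(int_idx) == 0L) {
    return(solve_lp(obj, A, sense, rhs, lb, ub, maximize = maximize))
  }
  sgn <- if (maximize) -1 else 1
  obj_min <- sgn * obj

  best <- list(objval = Inf, x = NULL)
  nodes <- list(list(lb = lb, ub = ub))
  n_nodes <- 0L
  while (length(nodes) > 0L) {
    n_nodes <- n_nodes + 1L
    if (n_nodes > max_nodes) stop("branch-and-bound node limit exceeded")
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    rel <- solve_lp(obj_min, A, sense, rhs, node$lb, node$ub)
    if (rel$status != "optimal") next
    if (rel$objval >= best$objval - 1e-9) next
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= MILP_INT_TOL)) {
      x <- rel$x
      x[int_idx] <- round(x[int_idx])
      best <- list(objval = rel$objval, x = x)
      next
    }
    j <- int_idx[which.max(frac)]
    v <- rel$x[j]
    lo <- node; hi <- node
    lo$ub[j] <- floor(v)
    hi$lb[j] <- ceiling(v)
    # explore the branch nearer the relaxation value first (pushed last)
    if (v - floor(v) > 0.5) {
      nodes <- c(nodes, list(lo), list(hi))
    } else {
      nodes <- c(nodes, list(hi), list(lo))
    }
  }
  if (is.null(best$x)) {
    list(status = "infeasible", objval = NA_real_, x = NULL)
  } else {
    list(status = "optimal", objval = sgn * best$objval, x = best$x)
  }
}
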