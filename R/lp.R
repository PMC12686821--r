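# Linear programming core: bounded-variable two-phase primal simplex.
#
# All constraint-based analyses in the package (FBA, FVA, pFBA, the EvolveX
# score stages, ROOM relaxations) reduce to problems of the form
#
#   min c'x   s.t.  A x (<=,=,>=) b,   l <= x <= u
#
# with dense A of modest size (tens to a few hundred variables).  Inequalities
# are converted to equalities with slack variables; phase 1 drives artificial
# variables to zero, phase 2 optimizes c.  Nonbasic variables sit at a finite
# bound; free variables are not supported (every flux is boxed by the model's
# bound magnitude, and slacks have a finite lower bound).

LP_FEAS_TOL <- 1e-9
LP_OPT_TOL <- 1e-9

#' Solve a linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to row constraints
#' `A x (sense) rhs` and box bounds `lb <= x <= ub`, using the package's
#' bounded-variable two-phase simplex.
#'
#' @param obj numeric objective coefficient vector.
#' @param A constraint matrix (dense or `Matrix` sparse), one row per
#'   constraint.
#' @param sense character vector of `"<="`, `"="`, `">="`, one per row.
#' @param rhs numeric right-hand sides.
#' @param lb,ub variable bounds; every variable needs at least one finite
#'   bound.
#' @param maximize if `TRUE` the objective is maximized.
#' @param max_iter simplex iteration cap.
#'
#' @return a list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objval`, and the primal solution `x`.
#' @export
solve_lp <- function(obj, A, sense, rhs, lb, ub, maximize = FALSE,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(sense) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + LP_FEAS_TOL)) {
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  }
  obj <- as.numeric(obj)
  if (maximize) obj <- -obj

  # slacks: <= gets s in [0,Inf) with +1; >= gets s in [0,Inf) with -1
  n_slack <- sum(sense != "=")
  Afull <- cbind(A, matrix(0, m, n_slack))
  c_full <- c(obj, rep(0, n_slack))
  lb_full <- c(lb, rep(0, n_slack))
  ub_full <- c(ub, rep(Inf, n_slack))
  j <- n
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      j <- j + 1L
      Afull[i, j] <- 1
    } else if (sense[i] == ">=") {
      j <- j + 1L
      Afull[i, j] <- -1
    } else if (sense[i] != "=") {
      stop("unknown constraint sense: ", sense[i])
    }
  }
  res <- simplex_bounded(c_full, Afull, as.numeric(rhs), lb_full, ub_full,
                         max_iter = max_iter)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    objval <- sum(obj * x)
    if (maximize) objval <- -objval
    list(status = "optimal", objval = objval, x = x)
  } else {
    list(status = res$status, objval = NA_real_, x = NULL)
  }
}

# Two-phase bounded simplex on  min c'x  s.t. A x = b, l <= x <= u.
# Nonbasic variables rest at a finite bound.  The basis system is re-solved
# densely at every iteration; with m in the tens this is cheap and avoids
# accumulating factorization error.
simplex_bounded <- function(cc, A, b, lb, ub, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)

  # start: nonbasic structurals at the finite bound of smaller magnitude
  x <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      x[j] <- if (abs(lb[j]) <= abs(ub[j])) lb[j] else ub[j]
    } else if (is.finite(lb[j])) {
      x[j] <- lb[j]
    } else if (is.finite(ub[j])) {
      x[j] <- ub[j]
    } else {
      stop("free variables are not supported by the simplex core")
    }
  }
  at_upper <- x == ub  # nonbasic status flag (meaningful for nonbasic only)

  resid <- b - as.vector(A %*% x)
  # artificial column i is +/-e_i so the artificial starts nonnegative
  art_sign <- ifelse(resid >= 0, 1, -1)
  Aall <- cbind(A, diag(art_sign, m))
  n_all <- n + m
  lb_all <- c(lb, rep(0, m))
  ub_all <- c(ub, rep(Inf, m))
  x_all <- c(x, abs(resid))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1L):n_all
  in_basis <- rep(FALSE, n_all)
  in_basis[basis] <- TRUE

  phase1_c <- c(rep(0, n), rep(1, m))

  run_phase <- function(cvec, x_all, basis, in_basis, at_upper, phase,
                        iter_budget) {
    bland <- FALSE
    iter <- 0L
    degen_run <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > iter_budget) {
        return(list(status = "iteration_limit", x = x_all, basis = basis,
                    in_basis = in_basis, at_upper = at_upper))
      }
      B <- Aall[, basis, drop = FALSE]
      nb <- which(!in_basis)
      # (artificials are pinned to [0,0] in phase 2 and can never re-enter:
      # the bound checks below exclude them)
      xb <- tryCatch(solve(B, b - Aall[, nb, drop = FALSE] %*% x_all[nb]),
                     error = function(e) NULL)
      if (is.null(xb)) {
        return(list(status = "singular", x = x_all, basis = basis,
                    in_basis = in_basis, at_upper = at_upper))
      }
      x_all[basis] <- as.vector(xb)
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "singular", x = x_all, basis = basis,
                    in_basis = in_basis, at_upper = at_upper))
      }
      d <- cvec[nb] - as.vector(t(Aall[, nb, drop = FALSE]) %*% y)

      low <- !at_upper[nb]
      # candidates: at lower bound wanting to increase, at upper wanting to
      # decrease
      cand_incr <- low & d < -LP_OPT_TOL & x_all[nb] < ub_all[nb] - LP_FEAS_TOL
      cand_decr <- !low & d > LP_OPT_TOL & x_all[nb] > lb_all[nb] + LP_FEAS_TOL
      cand <- which(cand_incr | cand_decr)
      if (length(cand) == 0L) {
        return(list(status = "optimal", x = x_all, basis = basis,
                    in_basis = in_basis, at_upper = at_upper))
      }
      if (bland) {
        k <- cand[which.min(nb[cand])]
      } else {
        k <- cand[which.max(abs(d[cand]))]
      }
      enter <- nb[k]
      sigma <- if (at_upper[enter]) -1 else 1  # direction of x_enter change

      w <- as.vector(solve(B, Aall[, enter]))
      # basic variables move by -sigma * w * t
      delta <- -sigma * w
      t_max <- Inf
      leave_pos <- 0L  # 0 = entering hits own opposite bound
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (delta[i] > LP_FEAS_TOL) {
          if (is.finite(ub_all[bi])) {
            tt <- (ub_all[bi] - x_all[bi]) / delta[i]
            if (tt < t_max - LP_FEAS_TOL) {
              t_max <- tt; leave_pos <- i; leave_to_upper <- TRUE
            }
          }
        } else if (delta[i] < -LP_FEAS_TOL) {
          if (is.finite(lb_all[bi])) {
            tt <- (lb_all[bi] - x_all[bi]) / delta[i]
            if (tt < t_max - LP_FEAS_TOL) {
              t_max <- tt; leave_pos <- i; leave_to_upper <- FALSE
            }
          }
        }
      }
      span <- ub_all[enter] - lb_all[enter]
      if (is.finite(span) && span < t_max) {
        t_max <- span
        leave_pos <- 0L
      }
      if (!is.finite(t_max)) {
        return(list(status = if (phase == 1L) "singular" else "unbounded",
                    x = x_all, basis = basis, in_basis = in_basis,
                    at_upper = at_upper))
      }
      t_max <- max(t_max, 0)
      degen_run <- if (t_max <= LP_FEAS_TOL) degen_run + 1L else 0L
      if (degen_run > 2L * (m + n)) bland <- TRUE

      x_all[enter] <- x_all[enter] + sigma * t_max
      x_all[basis] <- x_all[basis] + delta * t_max
      if (leave_pos == 0L) {
        # bound flip: entering stays nonbasic at its other bound
        at_upper[enter] <- !at_upper[enter]
      } else {
        leave <- basis[leave_pos]
        in_basis[leave] <- FALSE
        at_upper[leave] <- leave_to_upper
        x_all[leave] <- if (leave_to_upper) ub_all[leave] else lb_all[leave]
        basis[leave_pos] <- enter
        in_basis[enter] <- TRUE
      }
    }
  }

  ph1 <- run_phase(phase1_c, x_all, basis, in_basis, at_upper, 1L, max_iter)
  if (ph1$status == "iteration_limit" || ph1$status == "singular") {
    return(list(status = ph1$status, x = NULL))
  }
  infeas <- sum(ph1$x[(n + 1L):n_all])
  scale <- max(1, max(abs(b)))
  if (infeas > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL))
  }
  # pin artificials to zero for phase 2 (they may remain basic at 0)
  ub_all[(n + 1L):n_all] <- 0
  ph1$x[(n + 1L):n_all] <- 0

  ph2 <- run_phase(c(cc, rep(0, m)), ph1$x, ph1$basis, ph1$in_basis,
                   ph1$at_upper, 2L, max_iter)
  if (ph2$status != "optimal") {
    status <- if (ph2$status == "unbounded") "unbounded" else ph2$status
    return(list(status = status, x = NULL))
  }
  list(status = "optimal", x = ph2$x[seq_len(n)])
}
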