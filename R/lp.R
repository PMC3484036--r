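# Linear-programming core. Flux polytopes {A x = b, lb <= x <= ub} are
# solved with a two-phase bounded-variable primal simplex: nonbasic
# variables rest at a finite bound, phase 1 drives artificial variables out
# of the basis, Dantzig pricing with a Bland anti-cycling fallback. Dense
# algebra is adequate at the model sizes this package targets (tens to a
# few hundred reactions).

LP_TOL <- 1e-9

#' Solve a bounded linear program over an equality polytope
#'
#' Optimizes `obj' x` subject to `Aeq x = beq` and `lb <= x <= ub` (finite
#' bounds; models conventionally cap at +/-1000).
#'
#' @param obj Objective coefficient vector.
#' @param Aeq Equality constraint matrix.
#' @param beq Equality right-hand side.
#' @param lb,ub Finite variable bounds.
#' @param maximize Sense of optimization.
#' @return A list with `status` (`"optimal"` or `"infeasible"`), `x` and
#'   `objective`.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n,
            nrow(Aeq) == length(beq))
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite bounds", call. = FALSE)
  }
  if (any(lb > ub + LP_TOL)) {
    return(list(status = "infeasible", x = rep(0, n), objective = NA_real_))
  }
  # drop all-zero constraint rows
  if (nrow(Aeq)) {
    nz <- apply(abs(Aeq), 1, max) > 0
    if (any(!nz & abs(beq) > 1e-7)) {
      return(list(status = "infeasible", x = rep(0, n), objective = NA_real_))
    }
    Aeq <- Aeq[nz, , drop = FALSE]
    beq <- beq[nz]
  }
  res <- simplex_bounded(if (maximize) -obj else obj, Aeq, beq, lb, ub)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(0, n), objective = NA_real_))
  }
  list(status = "optimal", x = res$x, objective = sum(obj * res$x))
}

# minimize c'x s.t. A x = b, l <= x <= u; all bounds finite
simplex_bounded <- function(cc, A, b, l, u, max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0L) {
    # unconstrained box: each variable at its best bound
    x <- ifelse(cc >= 0, l, u)
    return(list(status = "optimal", x = x))
  }
  # phase 1: artificials cover the residual of the all-at-lower-bound point
  x <- l
  r <- b - as.vector(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lext <- c(l, rep(0, m))
  uext <- c(u, abs(r) + 1) # artificials start at |r|; headroom for pivoting
  xext <- c(x, abs(r))
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_iterate(c1, Aext, lext, uext, xext, basis, artificial = basis,
                         max_iter = max_iter)
  if (ph1$status != "optimal") return(list(status = ph1$status, x = NULL))
  if (sum(c1 * ph1$x) > 1e-7) {
    return(list(status = "infeasible", x = NULL))
  }
  # phase 2: pin artificials to zero, optimize the true objective
  uext <- c(u, rep(0, m))
  lext <- c(l, rep(0, m))
  xext <- ph1$x
  xext[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- simplex_iterate(c2, Aext, lext, uext, xext, ph1$basis,
                         artificial = n + seq_len(m), max_iter = max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status, x = NULL))
  list(status = "optimal", x = ph2$x[seq_len(n)])
}

simplex_iterate <- function(cc, A, l, u, x, basis, artificial = integer(0),
                            max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 50L * (n + m) + 200L
  piv_tol <- 1e-10
  red_tol <- 1e-9
  bland_after <- 10L * (n + m)
  is_basic <- rep(FALSE, n)
  is_basic[basis] <- TRUE
  for (it in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) return(list(status = "singular", x = x, basis = basis))
    y <- as.vector(crossprod(Binv, cc[basis]))
    nonbasic <- which(!is_basic)
    d <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))
    at_lower <- abs(x[nonbasic] - l[nonbasic]) <= abs(x[nonbasic] - u[nonbasic])
    # improving directions: increase vars at lower with d < 0,
    # decrease vars at upper with d > 0; fixed vars (l == u) never move
    movable <- u[nonbasic] - l[nonbasic] > piv_tol
    imp_lo <- at_lower & movable & d < -red_tol
    imp_up <- !at_lower & movable & d > red_tol
    cand <- which(imp_lo | imp_up)
    if (length(cand) == 0L) {
      return(list(status = "optimal", x = x, basis = basis))
    }
    if (it > bland_after) {
      q_i <- cand[which.min(nonbasic[cand])] # Bland: lowest index
    } else {
      q_i <- cand[which.max(abs(d[cand]))]
    }
    q <- nonbasic[q_i]
    dir <- if (at_lower[q_i]) 1 else -1 # direction of x_q
    w <- as.vector(Binv %*% A[, q]) * dir # x_B changes by -w per unit t
    # ratio test
    t_max <- u[q] - l[q]
    leave <- 0L # 0 = bound flip
    leave_to <- NA_real_
    xb <- x[basis]
    for (i in seq_len(m)) {
      if (w[i] > piv_tol) {
        ti <- (xb[i] - l[basis[i]]) / w[i]
        if (ti < t_max - piv_tol) {
          t_max <- max(ti, 0)
          leave <- i
          leave_to <- l[basis[i]]
        }
      } else if (w[i] < -piv_tol) {
        ti <- (u[basis[i]] - xb[i]) / (-w[i])
        if (ti < t_max - piv_tol) {
          t_max <- max(ti, 0)
          leave <- i
          leave_to <- u[basis[i]]
        }
      }
    }
    if (!is.finite(t_max)) return(list(status = "unbounded", x = x, basis = basis))
    # update solution
    x[basis] <- x[basis] - t_max * w
    x[q] <- x[q] + dir * t_max
    if (leave == 0L) {
      # bound flip: q stays nonbasic at its other bound
      next
    }
    p <- basis[leave]
    x[p] <- leave_to # snap to the bound it hit
    basis[leave] <- q
    is_basic[q] <- TRUE
    is_basic[p] <- FALSE
  }
  list(status = "iteration_limit", x = x, basis = basis)
}
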