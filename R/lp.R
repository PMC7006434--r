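# Dense bounded-variable two-phase simplex.
#
# No linear-programming backend is assumed: the networks this package targets
# are small (tens of reactions), so a textbook revised simplex with Bland's
# anti-cycling rule is fast, fully deterministic (fixed variable order, no
# randomized pricing) and easy to audit against the vertex-enumeration oracle
# used in the test suite.

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) \code{c'x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}, using a two-phase primal simplex on the
#' bounded-variable formulation. Bland's smallest-index rule is used for both
#' entering and leaving variables, which guarantees termination and makes the
#' returned basic solution deterministic.
#'
#' @param A constraint matrix (dense, m x n). May have zero rows.
#' @param b right-hand side vector, length m.
#' @param cvec objective coefficients, length n.
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/reduced-cost tolerance.
#' @param max_iter iteration cap (safety only; Bland's rule cannot cycle).
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{objective}, \code{x} (length n), \code{iterations}.
#' @keywords internal
lp_solve <- function(A, b, cvec, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), iterations = 0L))
  if (m == 0L) return(lp_solve_boxonly(cvec, lb, ub, maximize))

  sense <- if (maximize) 1 else -1
  cmax <- sense * cvec

  # initial nonbasic point: finite bound nearest zero, else 0 for free vars
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      x0[j] <- if (abs(lb[j]) <= abs(ub[j])) lb[j] else ub[j]
    } else if (is.finite(lb[j])) x0[j] <- lb[j]
    else if (is.finite(ub[j])) x0[j] <- ub[j]
    else x0[j] <- 0
  }
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  # extended problem: n structural + m artificial variables
  N <- n + m
  Aext <- cbind(A, diag(sgn, nrow = m, ncol = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))

  st <- new.env(parent = emptyenv())
  st$basis <- n + seq_len(m)            # artificials basic
  st$x <- c(x0, abs(r))
  st$status <- integer(N)               # 0 basic, 1 at lb, 2 at ub, 3 free at 0
  for (j in seq_len(n)) {
    st$status[j] <- if (!is.finite(lb[j]) && !is.finite(ub[j])) 3L
    else if (x0[j] == lb[j]) 1L else 2L
  }
  st$status[st$basis] <- 0L
  st$iter <- 0L

  # phase 1: minimize sum of artificials (maximize negative sum)
  c1 <- c(rep(0, n), rep(-1, m))
  res <- simplex_iterate(Aext, c1, lbe, ube, st, tol, max_iter)
  if (res != "optimal")
    stop("simplex phase 1 failed: ", res)   # cannot be unbounded: obj <= 0
  if (sum(st$x[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), iterations = st$iter))

  # phase 2: lock artificials at zero, optimize true objective
  ube[n + seq_len(m)] <- 0
  st$x[n + seq_len(m)][st$status[n + seq_len(m)] != 0L] <- 0
  c2 <- c(cmax, rep(0, m))
  res <- simplex_iterate(Aext, c2, lbe, ube, st, tol, max_iter)
  if (res == "unbounded")
    return(list(status = "unbounded", objective = sense * Inf,
                x = rep(NA_real_, n), iterations = st$iter))
  if (res != "optimal") stop("simplex phase 2 failed: ", res)

  x <- st$x[seq_len(n)]
  list(status = "optimal", objective = sum(cvec * x), x = x,
       iterations = st$iter)
}

# degenerate case: no equality rows, optimum at the favorable bound
lp_solve_boxonly <- function(cvec, lb, ub, maximize) {
  sense <- if (maximize) 1 else -1
  cm <- sense * cvec
  x <- ifelse(cm > 0, ub, ifelse(cm < 0, lb, ifelse(is.finite(lb), lb, pmin(ub, 0))))
  if (any(!is.finite(x) & cm != 0))
    return(list(status = "unbounded", objective = sense * Inf,
                x = rep(NA_real_, length(cvec)), iterations = 0L))
  x[!is.finite(x)] <- 0
  list(status = "optimal", objective = sum(cvec * x), x = x, iterations = 0L)
}

# core pivoting loop; mutates environment `st` (basis, x, status, iter).
# Maximizes cext. Returns "optimal" or "unbounded".
simplex_iterate <- function(Aext, cext, lbe, ube, st, tol, max_iter) {
  m <- nrow(Aext); N <- ncol(Aext)
  ctol <- tol * max(1, max(abs(cext)))
  repeat {
    st$iter <- st$iter + 1L
    if (st$iter > max_iter) stop("simplex iteration limit exceeded")
    B <- Aext[, st$basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cext[st$basis]),
                  error = function(e) stop("singular basis in simplex"))
    # reduced costs for nonbasic variables
    nonb <- which(st$status != 0L)
    d <- cext[nonb] - as.vector(crossprod(Aext[, nonb, drop = FALSE], y))
    stj <- st$status[nonb]
    improving <- (stj == 1L & d > ctol) | (stj == 2L & d < -ctol) |
                 (stj == 3L & abs(d) > ctol)
    if (!any(improving)) return("optimal")
    cand <- nonb[improving]
    k <- which.min(cand)                       # Bland: smallest variable index
    j <- cand[k]
    dj <- d[improving][k]
    dir <- if (st$status[j] == 1L) 1 else if (st$status[j] == 2L) -1 else sign(dj)

    w <- solve(B, Aext[, j])                   # basic response to entering var
    # ratio test: how far can x_j move in direction `dir`?
    t_flip <- if (is.finite(lbe[j]) && is.finite(ube[j])) ube[j] - lbe[j] else Inf
    delta <- -dir * w                          # change in basic vars per unit t
    xb <- st$x[st$basis]
    ti <- rep(Inf, m)
    hit <- integer(m)                          # bound each basic var would hit
    up <- delta > tol
    dn <- delta < -tol
    ti[up] <- (ube[st$basis[up]] - xb[up]) / delta[up]
    hit[up] <- 2L
    ti[dn] <- (lbe[st$basis[dn]] - xb[dn]) / delta[dn]
    hit[dn] <- 1L
    ti[ti < 0] <- 0                            # degenerate: never step backwards
    tmin_basic <- if (m > 0L) min(ti) else Inf
    if (!is.finite(t_flip) && !is.finite(tmin_basic)) return("unbounded")
    if (t_flip <= tmin_basic) {
      leave_pos <- 0L                          # entering var flips bounds
      tmax <- t_flip
    } else {
      blocking <- which(ti <= tmin_basic + tol)
      leave_pos <- blocking[which.min(st$basis[blocking])]   # Bland tie-break
      tmax <- ti[leave_pos]
    }
    leave_bnd <- if (leave_pos > 0L) hit[leave_pos] else 0L

    # apply the step
    st$x[st$basis] <- xb + delta * tmax
    st$x[j] <- st$x[j] + dir * tmax
    if (leave_pos == 0L) {
      # entering variable flipped to its opposite bound; basis unchanged
      st$status[j] <- if (dir > 0) 2L else 1L
      st$x[j] <- if (dir > 0) ube[j] else lbe[j]
    } else {
      old <- st$basis[leave_pos]
      st$x[old] <- if (leave_bnd == 2L) ube[old] else lbe[old]  # exact landing
      st$status[old] <- leave_bnd
      st$basis[leave_pos] <- j
      st$status[j] <- 0L
    }
  }
}
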