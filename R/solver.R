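#' Solve a bounded-variable linear program
#'
#' Optimizes `obj %*% x` subject to `A %*% x == b` and `lb <= x <= ub`.
#' This is the narrow solver interface behind all flux balance analysis in
#' the package: a dense two-phase revised simplex with bounded variables.
#' Phase 1 drives artificial variables to zero (detecting infeasibility);
#' phase 2 optimizes the objective. Bland's rule is engaged after a run of
#' degenerate pivots so the method cannot cycle.
#'
#' The implementation targets the model sizes this package works with
#' (hundreds of reactions at most); each iteration refactorizes the basis,
#' trading speed for numerical robustness.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param b right-hand side (length m); defaults to zeros (steady state).
#' @param lb,ub lower/upper variable bounds (length n); `-Inf`/`Inf` allowed.
#' @param direction `"max"` or `"min"`.
#' @param tol pivot/reduced-cost tolerance.
#' @param max_iter iteration cap; exceeded caps raise a diagnostic error.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` (optimal value, `NA` unless optimal) and `x` (solution
#'   vector, `NA` unless optimal).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 = 1, 0 <= x <= 1
#' solve_lp(c(1, 1), matrix(c(1, 1), 1, 2), b = 1, lb = c(0, 0), ub = c(1, 1))
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, direction = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  if (length(obj) != n) stop("objective length does not match ncol(A)")
  if (is.null(b)) b <- numeric(m)
  if (length(lb) != n || length(ub) != n) stop("bound length does not match ncol(A)")
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  sign <- if (direction == "max") 1 else -1
  cvec <- sign * as.numeric(obj)

  if (m == 0L) {
    # pure bound problem
    x <- ifelse(cvec > 0, ub, ifelse(cvec < 0, lb, ifelse(is.finite(lb), lb, pmin(ub, 0))))
    if (any(!is.finite(x))) {
      return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
    }
    return(list(status = "optimal", objective = sign * sum(cvec * x), x = x))
  }

  # starting point: every structural variable at a finite bound nearest zero
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    l <- lb[j]; u <- ub[j]
    x0[j] <- if (is.finite(l) && is.finite(u)) {
      if (abs(l) <= abs(u)) l else u
    } else if (is.finite(l)) l else if (is.finite(u)) u else 0
  }
  r <- b - as.numeric(A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, m, m))
  lbf <- c(lb, numeric(m))
  ubf <- c(ub, rep(Inf, m))
  nf <- n + m

  basis <- n + seq_len(m)
  # nonbasic state: 1 = at lower bound, 2 = at upper bound, 3 = free at zero
  state <- integer(nf)
  for (j in seq_len(n)) {
    state[j] <- if (is.finite(lb[j]) && x0[j] == lb[j]) 1L
    else if (is.finite(ub[j])) 2L else 3L
  }
  state[basis] <- 0L

  run_simplex <- function(cost, phase, basis, state) {
    degen_run <- 0L
    for (iter in seq_len(max_iter)) {
      Nset <- which(state != 0L)
      xN <- vapply(Nset, function(j) switch(state[j], lbf[j], ubf[j], 0), numeric(1))
      Bmat <- Afull[, basis, drop = FALSE]
      lu <- tryCatch(list(xB = solve(Bmat, b - Afull[, Nset, drop = FALSE] %*% xN),
                          y = solve(t(Bmat), cost[basis])),
                     error = function(e) NULL)
      if (is.null(lu)) stop("singular basis encountered in simplex")
      xB <- as.numeric(lu$xB)
      y <- as.numeric(lu$y)
      d <- cost[Nset] - as.numeric(crossprod(Afull[, Nset, drop = FALSE], y))
      up_ok <- (state[Nset] == 1L | state[Nset] == 3L) & d > tol
      dn_ok <- (state[Nset] == 2L | state[Nset] == 3L) & d < -tol
      cand <- which(up_ok | dn_ok)
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, state = state,
                    xB = xB, Nset = Nset, xN = xN))
      }
      if (degen_run > 3L * nf) {
        pick <- cand[which.min(Nset[cand])]          # Bland
      } else {
        pick <- cand[which.max(abs(d[cand]))]        # Dantzig
      }
      q <- Nset[pick]
      delta <- if (up_ok[pick]) 1 else -1
      w <- as.numeric(solve(Bmat, Afull[, q]))
      dxB <- -w * delta
      # ratio test
      t_own <- if (is.finite(lbf[q]) && is.finite(ubf[q])) ubf[q] - lbf[q] else Inf
      t_best <- t_own
      leave <- 0L  # 0 = bound flip on entering variable
      leave_to <- 0L
      for (i in seq_len(m)) {
        if (dxB[i] < -tol) {
          li <- lbf[basis[i]]
          if (is.finite(li)) {
            ti <- (xB[i] - li) / (-dxB[i])
            if (ti < t_best - 1e-12 ||
                (degen_run > 3L * nf && ti < t_best + 1e-12 &&
                 (leave == 0L || basis[i] < basis[leave]))) {
              t_best <- ti; leave <- i; leave_to <- 1L
            }
          }
        } else if (dxB[i] > tol) {
          ui <- ubf[basis[i]]
          if (is.finite(ui)) {
            ti <- (ui - xB[i]) / dxB[i]
            if (ti < t_best - 1e-12 ||
                (degen_run > 3L * nf && ti < t_best + 1e-12 &&
                 (leave == 0L || basis[i] < basis[leave]))) {
              t_best <- ti; leave <- i; leave_to <- 2L
            }
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded"))
      }
      degen_run <- if (t_best < tol) degen_run + 1L else 0L
      if (leave == 0L) {
        state[q] <- if (state[q] == 1L) 2L else 1L   # bound flip
      } else {
        out <- basis[leave]
        state[out] <- leave_to
        basis[leave] <- q
        state[q] <- 0L
      }
    }
    stop("simplex iteration limit reached (", max_iter, ")")
  }

  # phase 1: minimize sum of artificials (maximize negative sum)
  c1 <- c(numeric(n), rep(-1, m))
  res1 <- run_simplex(c1, 1L, basis, state)
  if (res1$status != "optimal") stop("phase-1 simplex failed: ", res1$status)
  art_idx <- match(n + seq_len(m), res1$basis)
  art_total <- sum(vapply(seq_len(m), function(i) {
    pos <- match(n + i, res1$basis)
    if (!is.na(pos)) res1$xB[pos] else {
      v <- switch(res1$state[n + i], lbf[n + i], ubf[n + i], 0)
      v
    }
  }, numeric(1)))
  if (art_total > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  # pin artificials to zero for phase 2
  ubf[n + seq_len(m)] <- 0
  c2 <- c(cvec, numeric(m))
  res2 <- run_simplex(c2, 2L, res1$basis, res1$state)
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- numeric(nf)
  x[res2$Nset] <- res2$xN
  x[res2$basis] <- res2$xB
  x <- x[seq_len(n)]
  # clip round-off outside bounds
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", objective = sign * sum(cvec * x), x = x)
}
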