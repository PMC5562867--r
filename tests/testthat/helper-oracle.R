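# Independent brute-force LP oracle: enumerate the vertices of
# {v : S v = 0, l <= v <= u} by fixing every choice of n - rank(S)
# variables at a finite bound and solving for the rest. Exponential, but
# exact for the small fixture networks; kept strictly independent of the
# simplex implementation it checks.

oracle_lp_value <- function(obj, S, lb, ub, direction = "max",
                            feas_tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- if (nrow(S)) qr(S)$rank else 0
  k <- n - r
  best <- NA_real_
  better <- if (direction == "max") function(a, b) is.na(b) || a > b
  else function(a, b) is.na(b) || a < b
  consider <- function(x) {
    if (any(x < lb - feas_tol) || any(x > ub + feas_tol)) return()
    val <- sum(obj * x)
    if (better(val, best)) best <<- val
  }
  if (k == 0) {
    qrS <- qr(S)
    x <- qr.coef(qrS, rep(0, nrow(S)))
    x[is.na(x)] <- 0
    if (max(abs(S %*% x)) < feas_tol) consider(x)
  } else {
    combs <- utils::combn(n, k)
    grid <- as.matrix(expand.grid(rep(list(c(1L, 2L)), k)))
    for (ci in seq_len(ncol(combs))) {
      N <- combs[, ci]
      B <- setdiff(seq_len(n), N)
      SB <- S[, B, drop = FALSE]
      qrB <- qr(SB)
      if (qrB$rank < length(B)) next
      for (g in seq_len(nrow(grid))) {
        xN <- ifelse(grid[g, ] == 1L, lb[N], ub[N])
        if (any(!is.finite(xN))) next
        rhs <- -S[, N, drop = FALSE] %*% xN
        xB <- qr.coef(qrB, rhs)
        if (anyNA(xB)) next
        if (max(abs(SB %*% xB - rhs)) > feas_tol) next
        x <- numeric(n)
        x[N] <- xN
        x[B] <- xB
        consider(x)
      }
    }
  }
  best
}

oracle_fba_value <- function(model, reaction_id, direction = "maximize") {
  S <- as.matrix(build_stoichiometric_matrix(model))
  obj <- as.numeric(model$reactions$id == reaction_id)
  oracle_lp_value(obj, S, model$reactions$lower_bound,
                  model$reactions$upper_bound,
                  if (direction == "maximize") "max" else "min")
}
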