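# Two-phase primal simplex for linear programs with bounded variables:
#
#   maximise  c'x   subject to  A x = b,  lb <= x <= ub
#
# Written for the FBA problem shape: a few hundred variables, equality
# constraints only (the steady-state rows), finite bounds. Nonbasic
# variables sit at a bound; Bland's smallest-index rule (entering and
# leaving) guarantees termination under degeneracy, which FBA polytopes
# exhibit heavily. Phase 1 starts from all structural variables at the
# bound closest to zero and drives artificial variables out of the basis.

boundedSimplex <- function(A, b, cc, lb, ub, maximise = TRUE,
                           tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (!maximise) cc <- -cc

  # artificial variables n+1..n+m patch the initial residual
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)   # nonbasic start, nearest to 0
  r <- b - as.numeric(A %*% x)
  Afull <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, abs(r))
  xf <- c(x, abs(r))
  basis <- n + seq_len(m)
  at_upper <- c(abs(lb) > abs(ub), rep(FALSE, m))

  iterate <- function(obj, xf, basis, at_upper, allow) {
    allow <- allow & (ubf > lbf + tol)   # fixed variables never enter
    for (it in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      y <- as.numeric(crossprod(Binv, obj[basis]))        # duals
      nonbasic <- setdiff(which(allow), basis)
      if (length(nonbasic) == 0L)
        return(list(status = "optimal", xf = xf, basis = basis,
                    at_upper = at_upper))
      red <- obj[nonbasic] - as.numeric(y %*% Afull[, nonbasic, drop = FALSE])
      up <- at_upper[nonbasic]
      eligible <- (!up & red > tol) | (up & red < -tol)
      if (!any(eligible))
        return(list(status = "optimal", xf = xf, basis = basis,
                    at_upper = at_upper))
      j <- min(nonbasic[eligible])                        # Bland: entering
      dirsign <- if (at_upper[j]) -1 else 1
      d <- as.numeric(Binv %*% Afull[, j]) * dirsign
      xB <- xf[basis]
      ratios <- rep(Inf, m); to_upper <- logical(m)
      inc <- d > tol; dec <- d < -tol
      ratios[inc] <- (xB[inc] - lbf[basis[inc]]) / d[inc]
      ratios[dec] <- (ubf[basis[dec]] - xB[dec]) / (-d[dec])
      to_upper[dec] <- TRUE
      ratios[ratios < 0] <- 0                             # degeneracy guard
      t_bound <- ubf[j] - lbf[j]                          # bound-flip distance
      t_max <- min(t_bound, ratios)
      if (!is.finite(t_max)) return(list(status = "unbounded"))
      xf[basis] <- xB - d * t_max
      xf[j] <- xf[j] + dirsign * t_max
      cand <- which(ratios <= t_max + tol)
      if (length(cand) == 0L) {
        at_upper[j] <- !at_upper[j]            # bound flip, basis unchanged
      } else {
        leave <- cand[which.min(basis[cand])]  # Bland: leaving
        out <- basis[leave]
        xf[out] <- if (to_upper[leave]) ubf[out] else lbf[out]
        at_upper[out] <- to_upper[leave]
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
    list(status = "iteration_limit")
  }

  # phase 1: minimise the artificial mass
  obj1 <- c(rep(0, n), rep(-1, m))
  res1 <- iterate(obj1, xf, basis, at_upper, allow = rep(TRUE, n + m))
  if (res1$status %in% c("singular", "iteration_limit"))
    return(list(status = res1$status))
  if (res1$status != "optimal" ||
      sum(res1$xf[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible"))
  # pin artificials at zero; they may stay in the basis but cannot move
  ubf[n + seq_len(m)] <- 0
  res1$xf[n + seq_len(m)] <- 0

  obj2 <- c(cc, rep(0, m))
  res2 <- iterate(obj2, res1$xf, res1$basis, res1$at_upper,
                  allow = c(rep(TRUE, n), rep(FALSE, m)))
  if (res2$status != "optimal") return(list(status = res2$status))
  xs <- res2$xf[seq_len(n)]
  val <- sum(cc * xs)
  list(status = "optimal", x = xs, value = if (maximise) val else -val)
}
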