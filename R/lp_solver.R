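# ---- dense two-phase simplex ----------------------------------------------
#
# Self-contained LP solver for the fixture-scale flux models used here
# (tens of rows/columns).  No LP package is assumed.  Bland's rule is used
# for both entering and leaving variables, which guarantees termination on
# degenerate bases at the cost of speed — irrelevant at this scale.

#' Solve a bounded linear program
#'
#' Solves `max (or min) obj' v` subject to `A v = b` and `lb <= v <= ub`
#' with a dense two-phase primal simplex.  All bounds must be finite; flux
#' models use the conventional +/-1000 mmol/gDW/h box.
#'
#' @param obj objective coefficient vector (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m, default zero — steady state).
#' @param lb,ub finite bound vectors (length n).
#' @param maximize logical, default `TRUE`.
#' @param tol pivot/feasibility tolerance (default 1e-9).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and `solution` (length n; `NA` unless optimal).
#' @export
solve_lp <- function(obj, A, b = rep(0, nrow(A)), lb, ub, maximize = TRUE,
                     tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m, all(is.finite(lb)), all(is.finite(ub)),
            all(lb <= ub))
  # shift to x = v - lb, add upper-bound slack rows: [A 0; I I] [x; s] = rhs
  u <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  M <- rbind(cbind(A, matrix(0, m, n)), cbind(diag(n), diag(n)))
  rhs <- c(b2, u)
  neg <- rhs < 0
  M[neg, ] <- -M[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  nr <- m + n; nc <- 2L * n
  cost <- c(if (maximize) -obj else obj, rep(0, n))

  # phase 1: artificial basis
  Tm <- cbind(M, diag(nr), rhs)
  basis <- nc + seq_len(nr)
  p1cost <- c(rep(0, nc), rep(1, nr))
  res <- simplex_iterate(Tm, basis, p1cost, ncols = nc + nr, tol = tol)
  Tm <- res$T; basis <- res$basis
  p1obj <- sum(p1cost[basis] * Tm[, ncol(Tm)])
  if (res$status != "optimal" || p1obj > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  # drive remaining artificials out of the basis (degenerate rows)
  drop_rows <- integer()
  for (r in which(basis > nc)) {
    piv <- which(abs(Tm[r, seq_len(nc)]) > tol)
    if (length(piv)) {
      j <- piv[[1]]
      Tm[r, ] <- Tm[r, ] / Tm[r, j]
      for (ii in setdiff(seq_len(nrow(Tm)), r))
        Tm[ii, ] <- Tm[ii, ] - Tm[ii, j] * Tm[r, ]
      basis[r] <- j
    } else {
      drop_rows <- c(drop_rows, r)  # redundant constraint
    }
  }
  if (length(drop_rows)) {
    Tm <- Tm[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  Tm <- Tm[, c(seq_len(nc), ncol(Tm)), drop = FALSE]

  # phase 2
  res <- simplex_iterate(Tm, basis, cost, ncols = nc, tol = tol)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  x <- rep(0, nc)
  x[res$basis] <- res$T[, ncol(res$T)]
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), solution = v)
}

simplex_iterate <- function(Tm, basis, cost, ncols, tol) {
  nr <- nrow(Tm)
  rhs_col <- ncol(Tm)
  repeat {
    cb <- cost[basis]
    red <- cost[seq_len(ncols)] -
      as.vector(cb %*% Tm[, seq_len(ncols), drop = FALSE])
    enter <- which(red < -max(tol, 1e-11))
    if (length(enter) == 0L) {
      return(list(T = Tm, basis = basis, status = "optimal"))
    }
    j <- min(enter)  # Bland's rule
    col <- Tm[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(T = Tm, basis = basis, status = "unbounded"))
    }
    ratios <- Tm[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    r <- cand[which.min(basis[cand])]  # Bland's rule on leaving variable
    Tm[r, ] <- Tm[r, ] / Tm[r, j]
    for (ii in seq_len(nr)) {
      if (ii != r && abs(Tm[ii, j]) > 0)
        Tm[ii, ] <- Tm[ii, ] - Tm[ii, j] * Tm[r, ]
    }
    basis[r] <- j
  }
}
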