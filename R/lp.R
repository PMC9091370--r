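## Linear-programming layer.
##
## All steady-state problems in the package reduce to LPs over bounded
## non-negative variables (transition fluxes are non-negative once
## reversible reactions are unfolded; concentrations are non-negative by
## nature).  They are solved by a self-contained two-phase dense simplex
## using Bland's anti-cycling rule: deterministic, terminating, and robust
## to the degenerate systems that steady-state nets produce (many balance
## rows with zero right-hand sides).  A presolve substitutes variables with
## equal bounds, shifts positive lower bounds to zero, and drops linearly
## dependent equality rows.

.LP_EPS <- 1e-9    # pivot / feasibility tolerance

# One simplex phase on the tableau Tb = [M | d] with basis `basis` and cost
# vector `cost` (length ncol(M)).  Bland's rule: entering = lowest-index
# negative reduced cost, leaving = lowest-index basic among min-ratio ties.
.simplex_phase <- function(Tb, basis, cost, tol = .LP_EPS) {
  m <- nrow(Tb); n <- ncol(Tb) - 1L
  if (m == 0L) return(list(Tb = Tb, basis = basis, status = "optimal"))
  repeat {
    red <- cost - as.numeric(crossprod(cost[basis], Tb[, 1:n, drop = FALSE]))
    ent <- which(red < -tol)
    if (!length(ent)) return(list(Tb = Tb, basis = basis, status = "optimal"))
    j <- ent[1L]
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
    ratio <- Tb[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]
    piv <- Tb[i, ] / Tb[i, j]
    Tb <- Tb - outer(col, piv)
    Tb[i, ] <- piv
    basis[i] <- j
  }
}

# min cost'y  s.t.  M y = d (d >= 0), y >= 0.  Returns y or a status.
.lp_standard <- function(M, d, cost) {
  m <- nrow(M); n <- ncol(M)
  if (m == 0L) {
    if (any(cost < -.LP_EPS)) return(list(status = "unbounded"))
    return(list(status = "optimal", y = rep(0, n)))
  }
  ## phase 1: drive artificials out
  Tb <- cbind(M, diag(m), d, deparse.level = 0)
  basis <- n + seq_len(m)
  ph1 <- .simplex_phase(Tb, basis, c(rep(0, n), rep(1, m)))
  val1 <- sum(ph1$Tb[ph1$basis > n, n + m + 1L])
  if (val1 > 1e-7) return(list(status = "infeasible"))
  Tb <- ph1$Tb; basis <- ph1$basis
  ## artificials still basic (at zero): pivot them out or drop the row
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    j <- which(abs(Tb[i, 1:n]) > .LP_EPS)
    j <- setdiff(j, basis)
    if (length(j)) {
      j <- j[1L]
      piv <- Tb[i, ] / Tb[i, j]
      Tb <- Tb - outer(Tb[, j], piv)
      Tb[i, ] <- piv
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  ## phase 2 on the real columns only
  Tb <- Tb[, c(seq_len(n), n + m + 1L), drop = FALSE]
  ph2 <- .simplex_phase(Tb, basis, cost)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  y <- rep(0, n)
  y[ph2$basis] <- ph2$Tb[, n + 1L]
  list(status = "optimal", y = y, objective = sum(cost * y))
}

#' Solve a linear program over bounded non-negative variables
#'
#' Optimize `obj %*% x` subject to `A_eq %*% x = b_eq`,
#' `A_le %*% x <= b_le` and `lb <= x <= ub`, with `lb >= 0` finite.
#'
#' @param obj numeric objective coefficients (one per variable).
#' @param A_eq,b_eq equality constraints (may be `NULL`).
#' @param A_le,b_le inequality constraints, `A_le %*% x <= b_le`.
#' @param lb,ub variable bounds; `lb` non-negative and finite, `ub` may be
#'   `Inf`.
#' @param maximize logical; maximize instead of minimize.
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` and `x` (solution vector, `NULL` unless
#'   optimal).
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb < -.LP_EPS) || any(!is.finite(lb)))
    stop("solve_lp requires finite non-negative lower bounds")
  if (any(ub < lb - .LP_EPS))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_le)) { A_le <- matrix(0, 0, n); b_le <- numeric(0) }

  ## presolve 1: substitute variables with (numerically) equal bounds
  fixed <- which(ub - lb <= .LP_EPS)
  free <- setdiff(seq_len(n), fixed)
  xfix <- lb[fixed]
  if (length(fixed)) {
    b_eq <- b_eq - as.numeric(A_eq[, fixed, drop = FALSE] %*% xfix)
    b_le <- b_le - as.numeric(A_le[, fixed, drop = FALSE] %*% xfix)
    A_eq <- A_eq[, free, drop = FALSE]
    A_le <- A_le[, free, drop = FALSE]
  }
  const_obj <- sum(obj[fixed] * xfix)
  obj_f <- obj[free]
  m <- length(free)
  assemble <- function(yf) { x <- numeric(n); x[fixed] <- xfix; x[free] <- yf; x }

  ## drop constraint rows without free variables, checking consistency
  if (nrow(A_eq)) {
    zero <- rowSums(A_eq != 0) == 0
    if (any(abs(b_eq[zero]) > 1e-6))
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    A_eq <- A_eq[!zero, , drop = FALSE]; b_eq <- b_eq[!zero]
  }
  if (nrow(A_le)) {
    zero <- rowSums(A_le != 0) == 0
    if (any(b_le[zero] < -1e-6))
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    A_le <- A_le[!zero, , drop = FALSE]; b_le <- b_le[!zero]
  }
  if (m == 0L)
    return(list(status = "optimal", objective = const_obj,
                x = assemble(numeric(0))))

  ## presolve 2: shift positive lower bounds to zero (y = x - lb)
  shift <- lb[free]
  b_eq <- b_eq - as.numeric(A_eq %*% shift)
  b_le <- b_le - as.numeric(A_le %*% shift)
  ub_y <- ub[free] - shift
  const_obj <- const_obj + sum(obj_f * shift)

  ## presolve 3: drop linearly dependent equality rows
  if (nrow(A_eq) > 1L) {
    qa <- qr(t(A_eq))
    if (qa$rank < nrow(A_eq)) {
      if (qr(t(cbind(A_eq, b_eq)))$rank > qa$rank)
        return(list(status = "infeasible", objective = NA_real_, x = NULL))
      keep <- qa$pivot[seq_len(qa$rank)]
      A_eq <- A_eq[keep, , drop = FALSE]; b_eq <- b_eq[keep]
    }
  }

  ## standard form: slacks for <= rows and finite upper bounds
  fin <- which(is.finite(ub_y))
  n_slack <- nrow(A_le) + length(fin)
  ub_rows <- matrix(0, length(fin), m)
  if (length(fin)) ub_rows[cbind(seq_along(fin), fin)] <- 1
  M <- rbind(A_eq, A_le, ub_rows)
  if (n_slack)
    M <- cbind(M, rbind(matrix(0, nrow(A_eq), n_slack), diag(n_slack)))
  d <- c(b_eq, b_le, ub_y[fin])
  neg <- d < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; d[neg] <- -d[neg] }
  cost <- c(if (maximize) -obj_f else obj_f, rep(0, n_slack))

  res <- .lp_standard(M, d, cost)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, x = NULL))
  y <- res$y[seq_len(m)]
  x <- assemble(y + shift)
  list(status = "optimal",
       objective = sum(obj * x),
       x = x)
}
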