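## Dense bounded-variable primal simplex.
##
## All flux LPs in this package are small (tens to a few hundred variables), so a
## dense two-phase simplex with Bland's anti-cycling rule is both fast enough and
## bit-reproducible across platforms, which matters more here than raw speed:
## degenerate optima are ubiquitous in flux balance analysis and the objective
## value, not the flux vector, is the contract.

## Largest magnitude used in place of an infinite bound. Fluxes in the shipped
## models never exceed 1e3, so 1e7 leaves ample headroom without hurting
## conditioning.
.LP_BIG <- 1e7

#' Solve a bounded linear program
#'
#' Maximises (or minimises) \code{c'x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}, using a two-phase primal simplex with Bland's rule.
#' This is the solver behind every flux analysis in the package; it is exposed
#' so that custom LPs (for instance user-written extraction variants) can reuse
#' it.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or \code{Matrix} sparse.
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n. Non-finite entries are clamped to
#'   +/- 1e7.
#' @param maximize logical; minimise when \code{FALSE}.
#' @param tol pivot tolerance.
#'
#' @return A list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"degenerate"}),
#'   \code{objval} and \code{x}.
#' @export
solveLP <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))
  ub <- pmax(ub, lb)
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  ## Phase I: artificial variable per row, basis = artificials.
  xN <- lb                              # all structural variables at lower bound
  r <- as.numeric(b) - as.numeric(A %*% xN)
  sgn <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(.LP_BIG, m))
  ce1 <- c(rep(0, n), rep(-1, m))
  state <- list(
    basis = n + seq_len(m),
    atUpper = rep(FALSE, n),            # status of nonbasic structural vars
    xB = abs(r)
  )
  res1 <- .simplexIterate(Aext, as.numeric(b), ce1, lbe, ube, state, tol)
  if (res1$status != "optimal")
    return(list(status = res1$status, objval = NA_real_, x = rep(NA_real_, n)))
  if (res1$objval < -1e-7)
    return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, n)))

  ## Phase II: pin artificials to zero, optimise the true objective.
  ube[(n + 1):(n + m)] <- 0
  ce2 <- c(cc, rep(0, m))
  res2 <- .simplexIterate(Aext, as.numeric(b), ce2, lbe, ube, res1$state, tol)
  if (res2$status != "optimal")
    return(list(status = res2$status, objval = NA_real_, x = rep(NA_real_, n)))
  x <- res2$x[seq_len(n)]
  obj <- sum(as.numeric(obj) * x)
  list(status = "optimal", objval = obj, x = x)
}

## One simplex run (shared by both phases). `state` carries the basis, the
## bound status of every nonbasic variable, and the current basic values.
.simplexIterate <- function(A, b, cc, lb, ub, state, tol, maxit = 50000L) {
  m <- nrow(A); nAll <- ncol(A)
  basis <- state$basis
  inBasis <- logical(nAll); inBasis[basis] <- TRUE
  ## atUpper tracks nonbasic variables only; basic entries are ignored.
  atUpper <- logical(nAll)
  atUpper[seq_along(state$atUpper)] <- state$atUpper
  xB <- state$xB

  nonbasicValue <- function() {
    v <- ifelse(atUpper, ub, lb)
    v[inBasis] <- 0
    v
  }

  for (it in seq_len(maxit)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cc[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "degenerate"))
    nb <- which(!inBasis)
    d <- cc[nb] - as.numeric(crossprod(A[, nb, drop = FALSE], y))
    eligible <- (!atUpper[nb] & d > tol) | (atUpper[nb] & d < -tol)
    if (!any(eligible)) {
      x <- nonbasicValue()
      x[basis] <- xB
      return(list(status = "optimal",
                  objval = sum(cc * x),
                  x = x,
                  state = list(basis = basis, atUpper = atUpper, xB = xB)))
    }
    e <- nb[eligible][which.min(nb[eligible])]     # Bland: smallest index
    sigma <- if (atUpper[e]) -1 else 1
    w <- tryCatch(solve(B, A[, e]), error = function(e2) NULL)
    if (is.null(w)) return(list(status = "degenerate"))

    ## Ratio test: entering variable moves sigma * t off its bound. The step is
    ## limited by the entering variable's own opposite bound (tFlip) and by the
    ## first basic variable to hit one of its bounds.
    delta <- sigma * w
    tFlip <- ub[e] - lb[e]
    ti <- rep(Inf, m)
    toUpper <- logical(m)
    dec <- delta > tol        # basic value decreases -> hits lower bound
    inc <- delta < -tol       # basic value increases -> hits upper bound
    ti[dec] <- (xB[dec] - lb[basis[dec]]) / delta[dec]
    ti[inc] <- (ub[basis[inc]] - xB[inc]) / (-delta[inc])
    toUpper[inc] <- TRUE
    ti[ti < 0] <- 0           # degenerate steps clamp to zero
    tRow <- suppressWarnings(min(ti))
    tStep <- min(tFlip, tRow)
    if (!is.finite(tStep)) return(list(status = "unbounded"))

    if (tRow <= tFlip) {
      ## Pivot. Bland: among rows achieving the minimum ratio, evict the basic
      ## variable with the smallest index.
      cand <- which(ti <= tStep + tol)
      leave <- cand[which.min(basis[cand])]
      enteringValue <- (if (atUpper[e]) ub[e] else lb[e]) + sigma * tStep
      xB <- xB - delta * tStep
      lv <- basis[leave]
      inBasis[lv] <- FALSE
      atUpper[lv] <- toUpper[leave]
      basis[leave] <- e
      inBasis[e] <- TRUE
      xB[leave] <- enteringValue
    } else {
      ## Bound flip: entering variable crosses to its other bound, basis kept.
      xB <- xB - delta * tStep
      atUpper[e] <- !atUpper[e]
    }
  }
  list(status = "degenerate")
}
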