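## Uniform random sampling of the steady-state flux polytope with an
## artificial-centering hit-and-run chain.
##
## Warmup points are the optimal flux vectors of a full (objective-free) FVA,
## orthogonally projected onto the null space of S so that every subsequent
## point -- chords only ever move along differences of in-space points --
## satisfies S v = 0 to machine precision. Reactions whose FVA range is
## degenerate are held at their forced value and excluded from the walk.

#' Sample steady-state flux distributions
#'
#' Draws \code{n} flux vectors from the polytope \eqn{\{v : S v = 0,
#' lb \le v \le ub\}} with an artificial-centering hit-and-run chain:
#' directions point from the running centre towards randomly chosen warmup
#' points, the step is uniform on the feasible chord, and every
#' \code{thinning}-th state after \code{warmup} steps is recorded.
#' Fully reproducible for a given seed.
#'
#' @param model a feasible \linkS4class{MetabolicModel}.
#' @param n number of samples, default 10000.
#' @param seed RNG seed.
#' @param warmup number of discarded initial steps, default 1000.
#' @param thinning steps between recorded samples, default 100.
#' @return A \linkS4class{FluxSampleSet}.
#' @export
sampleFluxes <- function(model, n = 10000, seed = 1L, warmup = 1000L,
                         thinning = 100L) {
  stopifnot(n >= 1, warmup >= 0, thinning >= 1)
  lp <- .lpData(model)
  nr <- length(lp$ids)
  fv <- .fvaCore(model, fraction = NULL, keepSolutions = TRUE)
  rng <- fluxRanges(fv$range)
  fixed <- (rng[, "max"] - rng[, "min"]) < 1e-9
  if (all(fixed))
    warning("flux polytope has zero volume; all reactions are fixed")

  ## orthonormal basis of null(S); projector keeps chords exactly in-space
  sv <- svd(lp$S, nu = 0, nv = nr)
  rank <- sum(sv$d > max(dim(lp$S)) * max(sv$d, 0) * 1e-12)
  if (rank >= nr) stop("model has no steady-state degrees of freedom")
  N <- sv$v[, seq(rank + 1, nr), drop = FALSE]
  project <- function(M) M %*% N %*% t(N)

  W <- project(fv$solutions)
  colnames(W) <- lp$ids
  center <- colMeans(W)
  x <- center
  fixedVal <- (rng[, "min"] + rng[, "max"]) / 2
  lb <- lp$lb; ub <- lp$ub
  free <- which(!fixed)

  set.seed(seed)
  nW <- nrow(W)
  total <- warmup + n * thinning
  out <- matrix(NA_real_, n, nr, dimnames = list(NULL, lp$ids))
  got <- 0L
  nPts <- nW
  for (step in seq_len(total)) {
    d <- W[sample.int(nW, 1L), ] - center
    d[fixed] <- 0
    nd <- sqrt(sum(d * d))
    if (nd > 1e-12) {
      d <- d / nd
      df <- d[free]
      lo <- (lb[free] - x[free])
      hi <- (ub[free] - x[free])
      pos <- df > 1e-11
      neg <- df < -1e-11
      tmax <- suppressWarnings(min(hi[pos] / df[pos], lo[neg] / df[neg]))
      tmin <- suppressWarnings(max(lo[pos] / df[pos], hi[neg] / df[neg]))
      if (is.finite(tmax) && is.finite(tmin) && tmax > tmin) {
        x <- x + stats::runif(1, tmin, tmax) * d
      }
    }
    nPts <- nPts + 1L
    center <- center + (x - center) / nPts
    ## periodic re-projection kills the slow random-walk drift out of the
    ## null space that the centering updates would otherwise amplify
    if (step %% 200L == 0L) {
      x <- as.numeric(N %*% crossprod(N, x))
      center <- as.numeric(N %*% crossprod(N, center))
    }
    if (step > warmup && (step - warmup) %% thinning == 0L) {
      got <- got + 1L
      xi <- as.numeric(N %*% crossprod(N, x))
      xi[fixed] <- fixedVal[fixed]
      names(xi) <- lp$ids
      out[got, ] <- xi
      if (got == n) break
    }
  }
  new("FluxSampleSet", samples = out, reactionIndex = lp$ids,
      seed = as.integer(seed), algorithm = "achr",
      warmup = as.integer(warmup), thinning = as.integer(thinning),
      modelHash = modelHash(model))
}

#' Check sample validity against a model
#'
#' Recomputes, independently of the sampler, the steady-state residual and
#' bound violations of every sample.
#'
#' @param sampleSet a \linkS4class{FluxSampleSet}.
#' @param model the sampled \linkS4class{MetabolicModel}.
#' @return List with \code{maxResidual} (max |S v| over all samples) and
#'   \code{maxBoundViolation}.
#' @export
validateSamples <- function(sampleSet, model) {
  if (sampleSet@modelHash != modelHash(model))
    stop("sample set was drawn from a different model (hash mismatch)")
  X <- sampleSet@samples
  S <- as.matrix(model@stoichiometry)
  resid <- max(abs(S %*% t(X)))
  lb <- model@reactions$lower_bound
  ub <- model@reactions$upper_bound
  viol <- max(0, max(t(X) - ub), max(lb - t(X)))
  list(maxResidual = resid, maxBoundViolation = viol)
}

#' Summarise sampled flux distributions
#'
#' Per-reaction mean, sd and quartiles, plus a kernel-density estimate on a
#' fixed 512-point grid (normalised to integrate to 1). Constant (fixed)
#' reactions are flagged as degenerate and get no density.
#'
#' @param sampleSet a \linkS4class{FluxSampleSet}.
#' @param reactionIds reactions to summarise (default all).
#' @return List with \code{stats} (data.frame: reaction_id, mean, sd, q25,
#'   median, q75, degenerate) and \code{densities} (named list of
#'   data.frames with columns x, y).
#' @export
summarizeDistribution <- function(sampleSet, reactionIds = NULL) {
  ids <- if (is.null(reactionIds)) sampleSet@reactionIndex else reactionIds
  unknown <- setdiff(ids, sampleSet@reactionIndex)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  X <- sampleSet@samples[, ids, drop = FALSE]
  stats <- data.frame(
    reaction_id = ids,
    mean = colMeans(X),
    sd = apply(X, 2, stats::sd),
    q25 = apply(X, 2, stats::quantile, 0.25),
    median = apply(X, 2, stats::median),
    q75 = apply(X, 2, stats::quantile, 0.75),
    row.names = NULL
  )
  stats$degenerate <- stats$sd < 1e-9
  densities <- stats::setNames(lapply(seq_along(ids), function(k) {
    if (stats$degenerate[k]) return(NULL)
    d <- stats::density(X[, k], n = 512)
    data.frame(x = d$x, y = d$y)
  }), ids)
  list(stats = stats, densities = densities)
}
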