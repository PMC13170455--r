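## Flux-consistency testing and fastcore context-specific extraction.
##
## A reaction is flux-consistent when some steady-state flux vector gives it
## |v| >= epsilon. fastcore extracts a compact consistent sub-network that
## must contain a designated core set; the implementation follows the
## published LP7/LP10 scheme (activation LP for a reaction set, then
## L1-penalised support minimisation over the non-core), with deterministic
## behaviour: candidate sets are always processed in lexicographic reaction-id
## order.

.SUPP_FRACTION <- 0.99   # support threshold |v| >= 0.99 * epsilon

## LP7: find a flux vector maximising the number of reactions in J that reach
## flux >= epsilon. Variables [v, z_J]; constraints S v = 0 and v_j >= z_j
## with z_j in [0, epsilon].
.lp7 <- function(S, lb, ub, J, epsilon) {
  m <- nrow(S); n <- ncol(S); k <- length(J)
  if (k == 0) return(numeric(n))
  A <- matrix(0, m + k, n + 2 * k)
  A[seq_len(m), seq_len(n)] <- S
  for (q in seq_len(k)) {
    A[m + q, J[q]] <- 1          # v_j - z_j - s_j = 0, s_j >= 0
    A[m + q, n + q] <- -1
    A[m + q, n + k + q] <- -1
  }
  obj <- c(numeric(n), rep(1, k), numeric(k))
  lbx <- c(lb, rep(0, k), rep(0, k))
  ubx <- c(ub, rep(epsilon, k), rep(.LP_BIG, k))
  res <- solveLP(obj, A, rep(0, m + k), lbx, ubx, maximize = TRUE)
  if (res$status != "optimal") stop("LP7 is ", res$status)
  res$x[seq_len(n)]
}

## LP10: minimise the L1 norm of fluxes over the penalty set P subject to
## v_k >= activation for every k in K. Variables [v, t_P] with |v_p| <= t_p.
## The activation level is epsilon scaled up by 1e4 (capped by the bounds) so
## that support reactions with small stoichiometric coefficients still carry
## flux above the support-detection threshold.
.lp10 <- function(S, lb, ub, K, P, epsilon) {
  m <- nrow(S); n <- ncol(S); np <- length(P)
  lb2 <- lb
  act <- 1e4 * epsilon
  lb2[K] <- pmax(lb2[K], pmin(act, ub[K]))
  if (np == 0) {
    res <- solveLP(numeric(n), S, rep(0, m), lb2, ub, maximize = FALSE)
    if (res$status != "optimal") stop("LP10 is ", res$status)
    return(res$x)
  }
  A <- matrix(0, m + 2 * np, n + 3 * np)
  A[seq_len(m), seq_len(n)] <- S
  for (q in seq_len(np)) {
    p <- P[q]
    A[m + q, p] <- 1                   #  v_p - t_p + s1 = 0
    A[m + q, n + q] <- -1
    A[m + q, n + np + q] <- 1
    A[m + np + q, p] <- -1             # -v_p - t_p + s2 = 0
    A[m + np + q, n + q] <- -1
    A[m + np + q, n + 2 * np + q] <- 1
  }
  obj <- c(numeric(n), rep(1, np), numeric(2 * np))
  lbx <- c(lb2, rep(0, np), rep(0, 2 * np))
  ubx <- c(ub, rep(.LP_BIG, 3 * np))
  res <- solveLP(obj, A, rep(0, nrow(A)), lbx, ubx, maximize = FALSE)
  if (res$status != "optimal") stop("LP10 is ", res$status)
  res$x[seq_len(n)]
}

#' Find blocked reactions
#'
#' A reaction is blocked when its maximal attainable |flux| under the current
#' bounds is below \code{epsilon} in both directions.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param epsilon minimum activation flux, default 1e-4 mmol/gDW/h.
#' @return Character vector of blocked reaction ids.
#' @export
findBlockedReactions <- function(model, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  lp <- .lpData(model)
  n <- length(lp$ids)
  b0 <- rep(0, nrow(lp$S))
  feas <- solveLP(numeric(n), lp$S, b0, lp$lb, lp$ub)
  if (feas$status != "optimal")
    stop("model is ", feas$status, " under current bounds")
  unresolved <- rep(TRUE, n)
  ## one LP7 sweep certifies most active reactions cheaply
  v <- .lp7(lp$S, lp$lb, lp$ub, seq_len(n), epsilon)
  unresolved[abs(v) >= .SUPP_FRACTION * epsilon] <- FALSE
  for (j in which(unresolved)) {
    obj <- numeric(n); obj[j] <- 1
    vmax <- solveLP(obj, lp$S, b0, lp$lb, lp$ub, maximize = TRUE)$objval
    if (!is.na(vmax) && vmax >= epsilon) { unresolved[j] <- FALSE; next }
    vmin <- solveLP(obj, lp$S, b0, lp$lb, lp$ub, maximize = FALSE)$objval
    if (!is.na(vmin) && vmin <= -epsilon) unresolved[j] <- FALSE
  }
  lp$ids[unresolved]
}

## Sub-model with only the given reactions; metabolites orphaned by the
## removal are dropped. Original bounds, GPRs and orientations are kept.
.subModel <- function(model, keepIds) {
  keepIds <- intersect(model@reactions$id, keepIds)
  if (length(keepIds) == 0) {
    ## everything pruned: an empty (reaction-free) model is a legal result
    return(new("MetabolicModel",
               metabolites = model@metabolites[0, , drop = FALSE],
               reactions = model@reactions[0, , drop = FALSE],
               stoichiometry = Matrix::sparseMatrix(integer(), integer(),
                                                    x = numeric(),
                                                    dims = c(0, 0)),
               genes = model@genes, objective = character()))
  }
  jx <- match(keepIds, model@reactions$id)
  S <- model@stoichiometry[, jx, drop = FALSE]
  keepMet <- Matrix::rowSums(S != 0) > 0
  met <- model@metabolites[keepMet, , drop = FALSE]
  rxn <- model@reactions[jx, , drop = FALSE]
  rxns <- lapply(seq_len(nrow(rxn)), function(q) {
    idx <- which(S[, q] != 0)
    list(id = rxn$id[q], name = rxn$name[q],
         stoichiometry = stats::setNames(S[idx, q], model@metabolites$id[idx]),
         lower_bound = rxn$lower_bound[q], upper_bound = rxn$upper_bound[q],
         gpr = rxn$gpr[q], subsystem = rxn$subsystem[q])
  })
  objective <- if (model@objective %in% keepIds) model@objective else keepIds[1]
  MetabolicModel(met, rxns, objective = objective, genes = model@genes)
}

#' Largest flux-consistent sub-model
#'
#' Removes every blocked reaction (and the metabolites orphaned by the
#' removal); the result is the largest sub-model in which every reaction can
#' carry |flux| >= epsilon. Internal thermodynamically infeasible loops are
#' deliberately not pruned -- consistency here is defined purely by
#' \eqn{S v = 0} and the bounds -- but stoichiometric 2-cycles are reported
#' via \code{\link{findTwoCycles}} as candidates for manual curation.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param epsilon minimum activation flux, default 1e-4 mmol/gDW/h.
#' @return A consistent \linkS4class{MetabolicModel}.
#' @export
fastcc <- function(model, epsilon = 1e-4) {
  blocked <- findBlockedReactions(model, epsilon)
  cyc <- findTwoCycles(model)
  if (nrow(cyc))
    message("fastcc: ", nrow(cyc), " stoichiometric 2-cycle(s) present (",
            paste(paste(cyc$reaction1, cyc$reaction2, sep = "/"),
                  collapse = ", "), ")")
  if (length(blocked) == 0) return(model)
  .subModel(model, setdiff(model@reactions$id, blocked))
}

#' Stoichiometric 2-cycles
#'
#' Reports reaction pairs whose columns are exact opposites (or equals with
#' opposing allowed directions), i.e. candidate futile cycles that can carry
#' unbounded circular flux without any net conversion.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return data.frame with columns \code{reaction1}, \code{reaction2}.
#' @export
findTwoCycles <- function(model) {
  S <- as.matrix(model@stoichiometry)
  rxn <- model@reactions
  n <- ncol(S)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(S[, i] == -S[, j])) {
      ## forward/forward loop
      if (rxn$upper_bound[i] > 0 && rxn$upper_bound[j] > 0)
        out[[length(out) + 1]] <- c(rxn$id[i], rxn$id[j])
    } else if (all(S[, i] == S[, j])) {
      ## parallel duplicates runnable against each other
      if ((rxn$upper_bound[i] > 0 && rxn$lower_bound[j] < 0) ||
          (rxn$lower_bound[i] < 0 && rxn$upper_bound[j] > 0))
        out[[length(out) + 1]] <- c(rxn$id[i], rxn$id[j])
    }
  }
  if (length(out) == 0)
    return(data.frame(reaction1 = character(), reaction2 = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("reaction1", "reaction2")
  df
}

#' fastcore context-specific sub-network extraction
#'
#' Extracts a compact flux-consistent sub-model of \code{model} that contains
#' every reaction of the core set. The input model must itself be
#' flux-consistent (run \code{\link{fastcc}} first) and every core reaction
#' unblocked. The non-core complement is approximately minimal (the
#' algorithm's contract; exact on small networks).
#'
#' @param core a \linkS4class{CoreSet}.
#' @param model a flux-consistent \linkS4class{MetabolicModel}.
#' @return A \linkS4class{MetabolicModel} containing the core.
#' @export
fastcore <- function(core, model) {
  epsilon <- core@epsilon
  ids <- model@reactions$id
  missing <- setdiff(core@reactionIds, ids)
  if (length(missing))
    stop("core reaction(s) not in model: ", paste(missing, collapse = ", "))
  ## lexicographic ordering makes the extraction reproducible
  ord <- order(ids)
  S <- as.matrix(model@stoichiometry)[, ord, drop = FALSE]
  lb <- model@reactions$lower_bound[ord]
  ub <- model@reactions$upper_bound[ord]
  ids <- ids[ord]
  n <- length(ids)
  C <- which(ids %in% core@reactionIds)
  irr <- which(lb >= 0)

  flip <- function(jset) {
    for (j in jset) {
      S[, j] <<- -S[, j]
      tmp <- lb[j]; lb[j] <<- -ub[j]; ub[j] <<- -tmp
    }
  }
  supp <- function(v) which(abs(v) >= .SUPP_FRACTION * epsilon)

  findSparseMode <- function(J, P, singleton) {
    if (length(J) == 0) return(integer())
    probe <- if (singleton) J[1] else J
    v <- .lp7(S, lb, ub, probe, epsilon)
    K <- intersect(probe, supp(v))
    if (length(K) == 0) return(integer())
    v <- .lp10(S, lb, ub, K, P, epsilon)
    supp(v)
  }

  flipped <- FALSE
  singleton <- FALSE
  J <- intersect(C, irr)
  P <- setdiff(seq_len(n), C)
  A <- findSparseMode(J, P, singleton)
  if (length(setdiff(J, A)))
    stop("inconsistent irreversible core reaction(s): ",
         paste(ids[setdiff(J, A)], collapse = ", "))
  J <- setdiff(C, A)
  it <- 0L
  while (length(J) > 0) {
    it <- it + 1L
    if (it > 10L * n) stop("fastcore failed to converge")
    P <- setdiff(P, A)
    Anew <- findSparseMode(J, P, singleton)
    A <- union(A, Anew)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      JiRev <- setdiff(if (singleton) J[1] else J, irr)
      if (flipped || length(JiRev) == 0) {
        if (singleton)
          stop("core reaction blocked in input model: ", ids[J[1]])
        flipped <- FALSE
        singleton <- TRUE
      } else {
        flip(JiRev)
        flipped <- TRUE
      }
    }
  }
  .subModel(model, ids[sort(A)])
}

#' Read a core set from a newline-delimited reaction-id file
#' @param path file path.
#' @param epsilon minimum activation flux.
#' @return A \linkS4class{CoreSet}.
#' @export
readCoreSet <- function(path, epsilon = 1e-4) {
  ids <- readLines(path)
  CoreSet(ids[nzchar(trimws(ids))], epsilon = epsilon)
}

#' Extraction report comparing a parent model and its extracted sub-model
#' @param model parent \linkS4class{MetabolicModel}.
#' @param sub extracted sub-model.
#' @return data.frame with columns \code{reaction_id}, \code{kept}.
#' @export
extractionReport <- function(model, sub) {
  data.frame(reaction_id = model@reactions$id,
             kept = model@reactions$id %in% sub@reactions$id)
}
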