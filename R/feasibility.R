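# Steady-state flux feasibility probes.
#
# Every viability question in this package reduces to: does a flux vector v
# exist with S v = 0 (after augmenting S with sink/demand columns), within
# bounds, and with some coordinate pushed away from zero? That is a convex
# feasibility problem; it is decided by minimising 1/2 ||v||^2 subject to the
# constraints with quadprog's dual active-set method, which either returns a
# feasible point or reports the constraint system inconsistent.

# Decide feasibility of { S v = 0, lb <= v <= ub }.
# Bound constraints with |bound| >= big are dropped (treated as infinite).
steady_state_feasible <- function(S, lb, ub, big = 1e7) {
  n <- ncol(S)
  if (n == 0L) return(TRUE)  # no reactions: 0 = 0 trivially holds
  # fixed variables (lb == ub) are substituted out to keep the QP well-posed
  fixed <- which(ub - lb < 1e-12)
  rhs <- rep(0, nrow(S))
  if (length(fixed)) {
    rhs <- rhs - S[, fixed, drop = FALSE] %*% lb[fixed]
    keep <- setdiff(seq_len(n), fixed)
    if (!length(keep)) {
      return(all(abs(rhs) < 1e-9))
    }
    S <- S[, keep, drop = FALSE]
    lb <- lb[keep]; ub <- ub[keep]
    n <- length(keep)
  }
  i_lb <- which(lb > -big)
  i_ub <- which(ub < big)
  Amat <- cbind(t(S),
                diag(n)[, i_lb, drop = FALSE],
                -diag(n)[, i_ub, drop = FALSE])
  bvec <- c(as.numeric(rhs), lb[i_lb], -ub[i_ub])
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n),
                       Amat = Amat, bvec = bvec, meq = nrow(S)),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(res))) return(FALSE)
    stop("feasibility solve failed: ", conditionMessage(res))
  }
  TRUE
}

#' Test whether a metabolite is producible at steady state
#'
#' A metabolite is producible when some steady-state flux distribution over
#' the active reactions, within their bounds, can deliver it to a demand sink
#' at flux at least \code{eps}. The question is decided by linear feasibility
#' of the augmented stoichiometric system.
#'
#' @param network a \code{metabolic_network}.
#' @param metabolite a declared metabolite id.
#' @param active integer or logical index of active reactions (default: all).
#' @param eps minimal demand flux counted as production (default \code{1e-6}).
#' @return logical scalar.
#' @export
producible <- function(network, metabolite, active = NULL, eps = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  m <- match(metabolite, network$metabolites)
  if (is.na(m)) stop("undeclared metabolite: ", metabolite)
  idx <- resolve_active(network, active)
  S <- network$S[, idx, drop = FALSE]
  demand <- numeric(nrow(S)); demand[m] <- -1
  ok <- tryCatch(
    steady_state_feasible(cbind(S, demand),
                          lb = c(network$lb[idx], eps),
                          ub = c(network$ub[idx], 1e6)),
    error = function(e) stop("producibility check failed for metabolite '",
                             metabolite, "': ", conditionMessage(e))
  )
  ok
}

resolve_active <- function(network, active) {
  if (is.null(active)) return(seq_along(network$rxn_ids))
  if (is.logical(active)) return(which(active))
  if (is.character(active)) {
    idx <- match(active, network$rxn_ids)
    if (anyNA(idx)) stop("unknown reaction ids in 'active'")
    return(idx)
  }
  as.integer(active)
}

#' Identify blocked reactions
#'
#' A reaction is blocked when it cannot carry flux of magnitude \code{eps} in
#' any steady-state distribution of the active network. Each direction is a
#' separate feasibility probe (v_j >= eps; v_j <= -eps when the lower bound
#' allows it).
#'
#' @inheritParams producible
#' @return logical vector along \code{active} (TRUE = blocked).
#' @export
blocked_reactions <- function(network, active = NULL, eps = 1e-6) {
  idx <- resolve_active(network, active)
  S <- network$S[, idx, drop = FALSE]
  lb <- network$lb[idx]
  ub <- network$ub[idx]
  n <- length(idx)
  blocked <- logical(n)
  for (j in seq_len(n)) {
    fwd <- FALSE
    if (ub[j] >= eps) {
      lb2 <- lb; lb2[j] <- max(lb[j], eps)
      fwd <- steady_state_feasible(S, lb2, ub)
    }
    bwd <- FALSE
    if (!fwd && lb[j] <= -eps) {
      ub2 <- ub; ub2[j] <- min(ub[j], -eps)
      bwd <- steady_state_feasible(S, lb, ub2)
    }
    blocked[j] <- !(fwd || bwd)
  }
  blocked
}
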