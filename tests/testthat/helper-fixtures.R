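# Shared fixtures and independent oracles.

# Linear chain A -> B -> C -> D with one gene per internal reaction,
# spontaneous import of A and export of D (and optionally of C).
chain_network <- function(export_c = FALSE) {
  reactions <- list(
    list(id = "EX_A", stoich = c(A = 1), rev = FALSE, lb = 0, ub = 10,
         gpr = NULL),
    list(id = "R1", stoich = c(A = -1, B = 1), rev = FALSE, lb = 0, ub = 10,
         gpr = "g1"),
    list(id = "R2", stoich = c(B = -1, C = 1), rev = FALSE, lb = 0, ub = 10,
         gpr = "g2"),
    list(id = "R3", stoich = c(C = -1, D = 1), rev = FALSE, lb = 0, ub = 10,
         gpr = "g3"),
    list(id = "EX_D", stoich = c(D = -1), rev = FALSE, lb = 0, ub = 10,
         gpr = NULL)
  )
  exchanges <- c("EX_A", "EX_D")
  if (export_c) {
    reactions[[length(reactions) + 1L]] <- list(
      id = "EX_C", stoich = c(C = -1), rev = FALSE, lb = 0, ub = 10,
      gpr = NULL)
    exchanges <- c(exchanges, "EX_C")
  }
  metabolic_network(c("A", "B", "C", "D"), reactions,
                    biomass = "D", exchanges = exchanges)
}

# Four-component toy: each biomass component on its own one-step route, so
# fitness is exactly the fraction of surviving routes.
four_route_network <- function() {
  mets <- c("N", "B1", "B2", "B3", "B4")
  reactions <- list(
    list(id = "EX_N", stoich = c(N = 1), rev = FALSE, lb = 0, ub = 10,
         gpr = NULL)
  )
  exchanges <- "EX_N"
  for (j in 1:4) {
    b <- paste0("B", j)
    reactions[[length(reactions) + 1L]] <- list(
      id = paste0("R", j), stoich = stats::setNames(c(-1, 1), c("N", b)),
      rev = FALSE, lb = 0, ub = 10, gpr = paste0("g", j))
    reactions[[length(reactions) + 1L]] <- list(
      id = paste0("EX_", b), stoich = stats::setNames(-1, b), rev = FALSE,
      lb = 0, ub = 10, gpr = NULL)
    exchanges <- c(exchanges, paste0("EX_", b))
  }
  metabolic_network(mets, reactions, biomass = paste0("B", 1:4),
                    exchanges = exchanges)
}

# Independent producibility oracle for 1:1 single-substrate toy networks
# (every reaction converts at most one substrate into products): a metabolite
# is producible iff it is forward-reachable from the imports through
# GPR-active reactions. Valid for the helper/generator topologies, where no
# reaction has stoichiometric couplings that flux balance could violate.
reachable_mets <- function(network, removed = character()) {
  present <- setdiff(network$genes, removed)
  active <- vapply(network$gpr_trees, evaluate_gpr, logical(1),
                   present = present)
  P <- character(0)
  repeat {
    grew <- FALSE
    for (j in which(active)) {
      st <- network$S[, j]
      subs <- rownames(network$S)[st < 0]
      prods <- rownames(network$S)[st > 0]
      if (network$ub[j] <= 0 || !length(prods)) next
      if (all(subs %in% P) && !all(prods %in% P)) {
        P <- union(P, prods)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  P
}

fitness_oracle <- function(network, removed = character()) {
  mean(network$biomass %in% reachable_mets(network, removed))
}

# Random monotone step curve on [0, 1] starting at y = 1.
random_step_curve <- function(seed, n_knots = NULL) {
  set.seed(seed)
  if (is.null(n_knots)) n_knots <- sample(4:12, 1)
  x <- c(1, sort(stats::runif(n_knots - 2), decreasing = TRUE), 0)
  y <- c(1, sort(stats::runif(n_knots - 1, 0, 1), decreasing = TRUE))
  depcurve:::knots_to_curve(x, y)
}

# Quadrature oracle: integrate a function of the curves on a partition 10x
# finer than the union of their breakpoints (midpoint rule; exact for step
# functions since every refined interval lies inside one constant piece).
refined_quadrature <- function(curves, fn, refine = 10L) {
  breaks <- sort(unique(unlist(lapply(curves, `[[`, "breaks"))))
  fine <- unique(unlist(lapply(seq_len(length(breaks) - 1L), function(j) {
    seq(breaks[j], breaks[j + 1L], length.out = refine + 1L)
  })))
  fine <- sort(unique(fine))
  mids <- (fine[-1] + fine[-length(fine)]) / 2
  w <- diff(fine)
  vals <- lapply(curves, eval_curve, x = mids)
  sum(w * fn(vals))
}
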