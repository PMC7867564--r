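#' Biomass-fraction fitness scorer
#'
#' The default fitness of a sub-model: the fraction of the network's biomass
#' components that remain producible over the active reactions. It is 1 for
#' the comprehensive network (viable by construction) and 0 for a totally
#' degraded model in which no biomass component can be made. Alternative
#' scorers with the same signature can be passed to [extract_submodel()].
#'
#' @param network a \code{metabolic_network}.
#' @param active integer index of active reactions.
#' @param eps minimal production flux (see [producible()]).
#' @return numeric in \[0, 1\].
#' @export
biomass_fraction_fitness <- function(network, active, eps = 1e-6) {
  mean(vapply(network$biomass, function(m) {
    producible(network, m, active = active, eps = eps)
  }, logical(1)))
}

#' Extract the sub-model induced by removing a gene set
#'
#' Reactions whose GPR rule evaluates to FALSE on the remaining genes are
#' deactivated; the surviving network is then pruned of blocked reactions
#' (those unable to carry flux in any feasible steady state) until a fixed
#' point. Pruning can silence reactions whose genes were never removed, which
#' is how removal effects propagate through the network. Because a blocked
#' reaction carries zero flux in every feasible state, dropping it leaves the
#' flux space unchanged: the fixed point is unique and independent of the
#' order in which reactions are examined.
#'
#' @param network a \code{metabolic_network}.
#' @param removed character vector of removed gene ids (subset of
#'   \code{network$genes}).
#' @param prune prune blocked reactions (default TRUE). Fitness is identical
#'   with or without pruning; pruning matters for \code{present_genes}.
#' @param eps minimal flux magnitude (see [producible()]).
#' @param scorer fitness function, see [biomass_fraction_fitness()].
#' @return an object of class \code{submodel}: fields \code{removed}, \code{i}
#'   (number of removed genes), \code{active} (reaction ids),
#'   \code{present_genes}, \code{fitness}, \code{fitness_star}.
#' @export
extract_submodel <- function(network, removed = character(),
                             prune = TRUE, eps = 1e-6,
                             scorer = biomass_fraction_fitness) {
  stopifnot(inherits(network, "metabolic_network"))
  removed <- as.character(removed)
  if (!all(removed %in% network$genes)) {
    stop("removed genes not in network: ",
         paste(setdiff(removed, network$genes), collapse = ", "))
  }
  present <- setdiff(network$genes, removed)
  active <- vapply(network$gpr_trees, evaluate_gpr, logical(1),
                   present = present)
  if (prune) active <- prune_blocked(network, active, eps = eps)
  finish_submodel(network, removed, active, eps = eps, scorer = scorer)
}

prune_blocked <- function(network, active, eps = 1e-6) {
  repeat {
    idx <- which(active)
    if (!length(idx)) break
    bl <- blocked_reactions(network, active = idx, eps = eps)
    if (!any(bl)) break
    active[idx[bl]] <- FALSE
  }
  active
}

finish_submodel <- function(network, removed, active, eps, scorer,
                            fitness = NULL) {
  idx <- which(active)
  if (is.null(fitness)) fitness <- scorer(network, idx, eps = eps)
  i <- length(removed)
  k <- length(network$genes)
  present_genes <- setdiff(unique(unlist(network$rxn_gene_list[idx])), removed)
  structure(list(
    removed = removed,
    i = i,
    k = k,
    active = network$rxn_ids[idx],
    present_genes = present_genes,
    fitness = fitness,
    fitness_star = (1 - i / k) * fitness
  ), class = "submodel")
}

#' Fitness of a sub-model
#'
#' @param x a \code{submodel} from [extract_submodel()].
#' @return the fitness score in \[0, 1\]: 1 means viability equal to the
#'   comprehensive network, 0 a totally degraded model.
#' @export
fitness <- function(x) {
  stopifnot(inherits(x, "submodel"))
  x$fitness
}

#' @rdname fitness
#' @export
fitness_star <- function(x) {
  stopifnot(inherits(x, "submodel"))
  x$fitness_star
}

#' @export
print.submodel <- function(x, ...) {
  cat("<submodel> i=", x$i, "/", x$k, " removed, ",
      length(x$active), " active reactions, ",
      length(x$present_genes), " present genes, fitness=",
      format(x$fitness, digits = 4), ", fitness*=",
      format(x$fitness_star, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Build the sub-model series along an expression-based gene ranking
#'
#' Genes are removed cumulatively in ranking order (lowest-expressed first);
#' a sub-model is extracted at i = 0, step, 2 step, ..., k removed genes (the
#' terminal i = k model is always included). Along the series the GPR-active
#' reaction set can only shrink, so extraction is incremental: steps at which
#' no GPR flips reuse the previous pruned model and fitness.
#'
#' @param network a \code{metabolic_network}.
#' @param ranking character vector: a permutation of \code{network$genes} in
#'   removal order, e.g. from [rank_genes()].
#' @param step number of genes removed between consecutive sub-models.
#' @inheritParams extract_submodel
#' @return object of class \code{submodel_series}: list with \code{ranking},
#'   \code{step} and \code{models} (list of \code{submodel}).
#' @export
build_series <- function(network, ranking, step = 1L, eps = 1e-6,
                         scorer = biomass_fraction_fitness) {
  stopifnot(inherits(network, "metabolic_network"))
  if (step < 1L) stop("step must be >= 1")
  ranking <- as.character(ranking)
  if (!setequal(ranking, network$genes) ||
      length(ranking) != length(network$genes)) {
    stop("ranking must be a permutation of the network genes")
  }
  k <- length(network$genes)
  iseq <- unique(c(seq(0L, k, by = step), k))

  models <- vector("list", length(iseq))
  prev_gpr_active <- NULL
  prev_pruned <- NULL
  prev_fitness <- NULL
  for (s in seq_along(iseq)) {
    i <- iseq[s]
    removed <- ranking[seq_len(i)]
    present <- if (i == k) character(0) else ranking[(i + 1L):k]
    gpr_active <- vapply(network$gpr_trees, evaluate_gpr, logical(1),
                         present = present)
    if (!is.null(prev_gpr_active) && identical(gpr_active, prev_gpr_active)) {
      # no GPR flipped: same reactions, same flux space, same fitness
      models[[s]] <- finish_submodel(network, removed, prev_pruned,
                                     eps = eps, scorer = scorer,
                                     fitness = prev_fitness)
    } else {
      # warm start: anything pruned before stays blocked in a smaller network
      start <- if (is.null(prev_pruned)) gpr_active else (prev_pruned & gpr_active)
      pruned <- prune_blocked(network, start, eps = eps)
      models[[s]] <- finish_submodel(network, removed, pruned,
                                     eps = eps, scorer = scorer)
      prev_pruned <- pruned
      prev_fitness <- models[[s]]$fitness
      prev_gpr_active <- gpr_active
    }
  }
  structure(list(ranking = ranking, step = as.integer(step),
                 i = iseq, models = models),
            class = "submodel_series")
}

#' @export
print.submodel_series <- function(x, ...) {
  cat("<submodel_series> ", length(x$models), " sub-models, step ", x$step,
      ", k = ", length(x$ranking), "\n", sep = "")
  invisible(x)
}
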