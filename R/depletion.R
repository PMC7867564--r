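#' Read a GMT gene-set collection
#'
#' Thin wrapper around \code{fgsea::gmtPathways} (standard tab-separated GMT:
#' name, description, member genes).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a named list of gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional vector of descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict and filter gene sets against a metabolic network
#'
#' Each set is restricted to genes present in the network, then filtered to
#' the size window \code{[min_size, max_size]} (defaults 3 and 50, both
#' inclusive). When a genome \code{universe} is supplied, an over-representation
#' pre-filter is applied: a one-sided hypergeometric test of the set's
#' network-gene overlap against the genome, keeping sets with
#' p < \code{enrich_p}. This mirrors the usual practice of pre-selecting gene
#' sets enriched in the network's gene complement before depletion analysis
#' (the original selection used a topGO enrichment; the hypergeometric test
#' here is a plain over-representation stand-in).
#'
#' @param collection named list of character vectors (e.g. from [read_gmt()]),
#'   or a GMT file path.
#' @param network a \code{metabolic_network}.
#' @param min_size,max_size inclusive bounds on the network-restricted size.
#' @param universe optional character vector of all genome genes (must contain
#'   the network genes).
#' @param enrich_p keep sets with hypergeometric p below this (default 0.1).
#' @return named list of \code{gene_set} objects (fields \code{name},
#'   \code{members}: the network-restricted members, \code{full_size}).
#'   Empty (with a warning) if nothing survives.
#' @export
prepare_gene_sets <- function(collection, network, min_size = 3L,
                              max_size = 50L, universe = NULL,
                              enrich_p = 0.1) {
  if (is.character(collection) && length(collection) == 1L) {
    collection <- read_gmt(collection)
  }
  stopifnot(inherits(network, "metabolic_network"))
  out <- list()
  for (nm in names(collection)) {
    full <- unique(as.character(collection[[nm]]))
    members <- intersect(full, network$genes)
    if (length(members) < min_size || length(members) > max_size) next
    if (!is.null(universe)) {
      in_uni <- intersect(full, universe)
      q <- length(intersect(in_uni, network$genes))
      m <- length(intersect(network$genes, universe))
      n <- length(universe) - m
      p <- stats::phyper(q - 1L, m, n, length(in_uni), lower.tail = FALSE)
      if (p >= enrich_p) next
    }
    out[[nm]] <- structure(list(name = nm, members = members,
                                full_size = length(full)),
                           class = "gene_set")
  }
  if (!length(out)) warning("no gene sets survive the size/enrichment filters")
  out
}

#' Rank genes for removal by expression
#'
#' Genes are removed lowest-expressed first; ties are broken by lexicographic
#' gene id so the ranking is deterministic. Network genes missing from the
#' expression vector are imputed at 0 (removed first) with a warning.
#'
#' @param values named non-negative numeric vector (one expression column).
#' @param genes optional character vector (e.g. \code{network$genes}); the
#'   ranking is restricted/extended to exactly these genes.
#' @return character vector of gene ids in removal order.
#' @export
rank_genes <- function(values, genes = NULL) {
  if (is.null(names(values))) stop("expression values must be named by gene")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(values))
    if (length(missing)) {
      warning(length(missing), " network gene(s) missing from expression; ",
              "imputed at 0 (removed first): ",
              paste(utils::head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ...")
      values <- c(values, stats::setNames(rep(0, length(missing)), missing))
    }
    values <- values[genes]
  }
  names(values)[order(values, names(values), method = "radix")]
}

# ---- depletion curves ------------------------------------------------------
#
# A depletion curve is a step function of x = fitness* with one knot per
# sub-model: y = fraction of the gene set still present. Curves are stored in
# a canonical piecewise-constant form: breakpoints 0 = b_1 < ... < b_n = 1 and
# values v_1..v_n, where v_1 is the point value at x = 0 and v_j (j > 1) is
# the constant value on the left-open interval (b_{j-1}, b_j]. At a knot the
# curve takes the already-dropped value (the knot's own y). All integrals are
# computed exactly on this partition, so they are invariant under any grid
# refinement.

new_step_curve <- function(breaks, vals, id = NULL, knots = NULL) {
  stopifnot(length(vals) == length(breaks),
            breaks[1] == 0, breaks[length(breaks)] == 1,
            !is.unsorted(breaks, strictly = TRUE))
  structure(list(id = id, breaks = breaks, vals = vals, knots = knots),
            class = "depletion_curve")
}

knots_to_curve <- function(x, y, id = NULL) {
  # x: fitness* per sub-model in series order (non-increasing), x[1] = 1
  stopifnot(length(x) == length(y))
  breaks <- sort(unique(c(0, 1, x)))
  eval_at <- function(q) y[sum(x >= q)]            # last knot with x >= q
  vals <- c(y[length(y)],                          # point value at x = 0
            vapply(breaks[-1], eval_at, numeric(1)))
  new_step_curve(breaks, vals, id = id,
                 knots = data.frame(x = x, y = y))
}

#' Construct a depletion curve directly from knots
#'
#' Mostly useful for simulation and testing: builds the canonical step-curve
#' representation from sub-model knots without a network.
#'
#' @param x knot positions (fitness* per sub-model, non-increasing, first
#'   element 1).
#' @param y knot values (fraction of the gene set remaining).
#' @param id optional label.
#' @return a \code{depletion_curve}.
#' @export
step_curve <- function(x, y, id = NULL) {
  if (x[1] != 1) stop("first knot must sit at x = 1")
  if (is.unsorted(rev(x))) stop("knot positions must be non-increasing")
  knots_to_curve(x, y, id = id)
}

#' Evaluate a depletion curve
#'
#' @param curve a \code{depletion_curve}.
#' @param x numeric vector of fitness* positions in \[0, 1\].
#' @return numeric vector of curve values.
#' @export
eval_curve <- function(curve, x) {
  stopifnot(inherits(curve, "depletion_curve"))
  if (any(x < 0 | x > 1)) stop("curve is defined on [0, 1]")
  idx <- findInterval(x, curve$breaks, left.open = TRUE) + 1L
  curve$vals[idx]
}

#' Depletion curve values on a uniform grid
#'
#' @param curve a \code{depletion_curve}.
#' @param n grid size (default 1001 points over \[0, 1\]).
#' @return data.frame with columns \code{x}, \code{y}.
#' @export
curve_grid <- function(curve, n = 1001L) {
  x <- seq(0, 1, length.out = n)
  data.frame(x = x, y = eval_curve(curve, x))
}

#' Depletion curve of a gene set along a sub-model series
#'
#' One knot per sub-model: x = fitness*, y = fraction of the gene set's
#' members among the sub-model's present genes. Present genes shrink along
#' the series, so the curve is non-increasing in removal order.
#'
#' @param series a \code{submodel_series} from [build_series()].
#' @param gene_set a \code{gene_set} (from [prepare_gene_sets()]) or a
#'   character vector of member genes; must be non-empty.
#' @param id optional curve label (e.g. the sample id).
#' @return a \code{depletion_curve}.
#' @export
depletion_curve <- function(series, gene_set, id = NULL) {
  stopifnot(inherits(series, "submodel_series"))
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else
    as.character(gene_set)
  if (!length(members)) stop("gene set is empty")
  y <- vapply(series$models, function(m) {
    length(intersect(m$present_genes, members)) / length(members)
  }, numeric(1))
  x <- vapply(series$models, function(m) m$fitness_star, numeric(1))
  knots_to_curve(x, y, id = id)
}

#' @export
print.depletion_curve <- function(x, ...) {
  cat("<depletion_curve>", if (!is.null(x$id)) paste0("'", x$id, "'"),
      length(x$breaks) - 1L, "segments, y(1) =", x$vals[length(x$vals)],
      ", y(0) =", x$vals[1], "\n")
  invisible(x)
}

#' @export
plot.depletion_curve <- function(x, ..., xlab = "fitness*",
                                 ylab = "fraction of gene set remaining") {
  g <- curve_grid(x)
  plot(g$x, g$y, type = "s", xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

# Re-express curves on the union of their breakpoints.
# Returns list(breaks, V): V has one row per curve, columns follow breaks
# (col 1 = point value at 0; col j>1 = value on (b_{j-1}, b_j]).
align_curves <- function(curves) {
  breaks <- sort(unique(unlist(lapply(curves, `[[`, "breaks"))))
  V <- do.call(rbind, lapply(curves, eval_curve, x = breaks))
  list(breaks = breaks, V = V)
}

#' Average depletion curves (condition curve)
#'
#' The depletion curve of a condition is the pointwise mean of the depletion
#' curves of its replicates, itself a step function on the union of the
#' replicate breakpoints.
#'
#' @param curves list of \code{depletion_curve}.
#' @param id optional label for the averaged curve.
#' @return a \code{depletion_curve}.
#' @export
average_curve <- function(curves, id = NULL) {
  stopifnot(length(curves) >= 1L)
  al <- align_curves(curves)
  new_step_curve(al$breaks, colMeans(al$V), id = id)
}

#' Area statistics between two depletion curves
#'
#' \code{abs_area} is the integral over \[0, 1\] of the absolute difference
#' between the curves; \code{auc_delta} returns both areas under the curves
#' and their signed difference \code{delta = auc_u - auc_v}, which equals the
#' signed integral of the difference. Both are computed exactly on the union
#' of the two step functions' breakpoints, so they are stable under any grid
#' refinement. Always \code{abs(delta) <= abs_area <= 1}.
#'
#' @param curve_u,curve_v \code{depletion_curve} objects.
#' @return \code{abs_area}: numeric scalar; \code{auc_delta}: named numeric
#'   vector \code{c(auc_u, auc_v, delta)}.
#' @export
abs_area <- function(curve_u, curve_v) {
  al <- align_curves(list(curve_u, curve_v))
  w <- diff(al$breaks)
  sum(w * abs(al$V[1, -1] - al$V[2, -1]))
}

#' @rdname abs_area
#' @export
auc_delta <- function(curve_u, curve_v) {
  al <- align_curves(list(curve_u, curve_v))
  w <- diff(al$breaks)
  auc_u <- sum(w * al$V[1, -1])
  auc_v <- sum(w * al$V[2, -1])
  c(auc_u = auc_u, auc_v = auc_v, delta = auc_u - auc_v)
}
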