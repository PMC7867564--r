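# Permutation machinery for depletion-curve discrepancy.
#
# The test statistic for a gene set across conditions is A* = max over
# condition pairs of the absolute area between the condition-averaged
# depletion curves. Resampling permutes the sample -> condition labels while
# preserving the number of replicates per condition; sub-model series and
# replicate curves are computed once and only relabelled, so a permutation
# costs a handful of vector operations on the aligned curve matrix.

# Aligned representation for fast resampling: V (samples x breakpoint values,
# col 1 = point value at 0) and interval widths w matching cols 2..n.
curve_matrix <- function(curves) {
  al <- align_curves(curves)
  list(V = al$V[, -1, drop = FALSE], w = diff(al$breaks),
       ids = vapply(seq_along(curves), function(i) {
         id <- curves[[i]]$id
         if (is.null(id)) paste0("sample", i) else as.character(id)
       }, character(1)))
}

# condition-mean rows of V for a label vector; rows ordered by `conds`
cond_means <- function(V, labels, conds) {
  M <- rowsum(V, group = factor(labels, levels = conds), reorder = TRUE)
  M / as.vector(table(factor(labels, levels = conds)))
}

pair_areas <- function(CM, w, pairs_idx) {
  vapply(seq_len(ncol(pairs_idx)), function(p) {
    sum(w * abs(CM[pairs_idx[1, p], ] - CM[pairs_idx[2, p], ]))
  }, numeric(1))
}

#' Gene-set discrepancy statistic across conditions
#'
#' The maximum absolute area between condition-averaged depletion curves over
#' all unordered condition pairs.
#'
#' @param condition_curves named list of \code{depletion_curve}, one per
#'   condition (at least two).
#' @return numeric scalar A*.
#' @export
discrepancy_stat <- function(condition_curves) {
  stopifnot(length(condition_curves) >= 2L)
  pairs <- utils::combn(length(condition_curves), 2L)
  max(vapply(seq_len(ncol(pairs)), function(p) {
    abs_area(condition_curves[[pairs[1, p]]], condition_curves[[pairs[2, p]]])
  }, numeric(1)))
}

# All distinct assignments of `labels` to positions (multiset permutations),
# as a matrix with one column per assignment. Used for exhaustive enumeration.
enumerate_relabelings <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(lab) {
    if (length(lab) <= 1L) return(matrix(lab, nrow = length(lab)))
    out <- NULL
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      sub <- recurse(rest)
      out <- cbind(out, rbind(rep(u, ncol(sub)), sub))
    }
    out
  }
  recurse(labels)
}

n_relabelings <- function(labels) {
  tb <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tb + 1)))
}

#' Permutation test for gene-set discrepancy across conditions
#'
#' Tests whether the depletion behaviour of a gene set in at least one
#' condition differs from the others. The statistic is A* (see
#' [discrepancy_stat()]); the null is generated by permuting replicate labels
#' between conditions while keeping each condition's replicate count, and the
#' p-value uses the add-one estimator
#' \code{p = (#\{null >= observed\} + 1) / (N + 1)} (ties count as
#' exceedances). When the number of distinct relabelings is at most
#' \code{exhaustive_cap}, the full enumeration is used instead and
#' \code{p = #\{E >= E_obs\} / #relabelings} over all relabelings (the
#' identity included).
#'
#' @param sample_curves list of per-replicate \code{depletion_curve}.
#' @param condition_of character vector: condition of each curve (same order);
#'   every condition needs at least one replicate, at least two overall for a
#'   non-degenerate test.
#' @param N number of resamples (default 99).
#' @param seed optional integer seed (recorded in the result).
#' @param exhaustive_cap enumerate exhaustively when the number of distinct
#'   relabelings is at most this (default 0 = never).
#' @return object of class \code{discrepancy_result}: fields \code{E_obs},
#'   \code{null} (null statistics), \code{N}, \code{p}, \code{method},
#'   \code{pairs} (per-pair \code{A_bar}, \code{auc} values and \code{delta}),
#'   \code{seed}.
#' @export
permutation_pvalue <- function(sample_curves, condition_of, N = 99L,
                               seed = NULL, exhaustive_cap = 0L) {
  stopifnot(length(sample_curves) == length(condition_of))
  condition_of <- as.character(condition_of)
  conds <- sort(unique(condition_of))
  if (length(conds) < 2L) stop("need at least two conditions")
  if (any(table(condition_of) < 1L)) stop("every condition needs a replicate")
  if (N < 1L) stop("N must be >= 1")

  cm <- curve_matrix(sample_curves)
  pairs_idx <- utils::combn(length(conds), 2L)
  CM <- cond_means(cm$V, condition_of, conds)
  obs_areas <- pair_areas(CM, cm$w, pairs_idx)
  E_obs <- max(obs_areas)

  # per-pair signed statistics of the observed labelling
  aucs <- as.vector(CM %*% cm$w)
  pairs <- data.frame(
    U = conds[pairs_idx[1, ]], V = conds[pairs_idx[2, ]],
    A_bar = obs_areas,
    auc_U = aucs[pairs_idx[1, ]], auc_V = aucs[pairs_idx[2, ]],
    delta = aucs[pairs_idx[1, ]] - aucs[pairs_idx[2, ]]
  )

  tol <- 1e-12
  if (exhaustive_cap > 0 && n_relabelings(condition_of) <= exhaustive_cap) {
    relab <- enumerate_relabelings(condition_of)
    E_all <- apply(relab, 2L, function(lab) {
      max(pair_areas(cond_means(cm$V, lab, conds), cm$w, pairs_idx))
    })
    p <- mean(E_all >= E_obs - tol)
    null <- E_all
    method <- "exhaustive"
    N_used <- ncol(relab)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(N), function(b) {
      lab <- sample(condition_of)
      max(pair_areas(cond_means(cm$V, lab, conds), cm$w, pairs_idx))
    }, numeric(1))
    p <- (sum(null >= E_obs - tol) + 1) / (N + 1)
    method <- "sampled"
    N_used <- N
  }

  structure(list(E_obs = E_obs, null = null, N = N_used, p = p,
                 method = method, pairs = pairs, conditions = conds,
                 seed = seed),
            class = "discrepancy_result")
}

#' @export
print.discrepancy_result <- function(x, ...) {
  cat("<discrepancy_result> A* =", format(x$E_obs, digits = 4),
      " p =", format(x$p, digits = 4),
      paste0("(", x$method, ", N = ", x$N, ")\n"))
  invisible(x)
}

#' Post-hoc pairwise permutation tests
#'
#' For each unordered pair of conditions, the same permutation scheme is run
#' restricted to the pair's replicates with the pair's absolute area as the
#' statistic; the signed AUC difference \code{delta = auc_U - auc_V} is
#' reported alongside to show the direction of the contrast.
#'
#' @inheritParams permutation_pvalue
#' @return data.frame with one row per pair: \code{U}, \code{V}, \code{A_bar},
#'   \code{auc_U}, \code{auc_V}, \code{delta}, \code{p}, \code{method}.
#' @export
pairwise_tests <- function(sample_curves, condition_of, N = 99L, seed = NULL,
                           exhaustive_cap = 0L) {
  condition_of <- as.character(condition_of)
  conds <- sort(unique(condition_of))
  if (length(conds) < 2L) stop("need at least two conditions")
  pairs_idx <- utils::combn(length(conds), 2L)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(ncol(pairs_idx)), function(p) {
    u <- conds[pairs_idx[1, p]]; v <- conds[pairs_idx[2, p]]
    sel <- condition_of %in% c(u, v)
    res <- permutation_pvalue(sample_curves[sel], condition_of[sel], N = N,
                              seed = NULL, exhaustive_cap = exhaustive_cap)
    data.frame(U = u, V = v, A_bar = res$E_obs,
               auc_U = res$pairs$auc_U, auc_V = res$pairs$auc_V,
               delta = res$pairs$delta, p = res$p, method = res$method)
  })
  do.call(rbind, rows)
}

#' Gene-set discrepancy analysis over an expression design
#'
#' End-to-end driver: per-sample expression rankings, sub-model series,
#' per-gene-set depletion curves, the A* permutation test across conditions
#' and the post-hoc pairwise tests. Series are computed once per sample and
#' shared by all gene sets; permutations only relabel the cached curves.
#'
#' @param network a \code{metabolic_network}.
#' @param expression non-negative matrix, genes in rows (rownames), samples in
#'   columns (colnames).
#' @param design data.frame with columns \code{sample}, \code{condition};
#'   at least two replicates per condition.
#' @param gene_sets list from [prepare_gene_sets()] (or named list of
#'   character vectors).
#' @param step removal step for [build_series()] (default 1).
#' @param N resamples per test (default 99).
#' @param seed integer seed for the permutation stream.
#' @param eps minimal flux (see [producible()]).
#' @param exhaustive_cap see [permutation_pvalue()].
#' @param pairwise also run the post-hoc pairwise tests (default TRUE).
#' @return object of class \code{discrepancy_analysis}: \code{summary}
#'   (data.frame: gene_set, n_genes, A_star, p, best pair), \code{results}
#'   (per-set \code{discrepancy_result}), \code{pairwise} (per-set pairwise
#'   data.frames), \code{series}, \code{curves}, \code{design}.
#' @export
gs_discrepancy <- function(network, expression, design, gene_sets,
                           step = 1L, N = 99L, seed = 1L, eps = 1e-6,
                           exhaustive_cap = 0L, pairwise = TRUE) {
  stopifnot(inherits(network, "metabolic_network"),
            all(c("sample", "condition") %in% names(design)))
  samples <- as.character(design$sample)
  if (!all(samples %in% colnames(expression))) {
    stop("design samples missing from expression matrix")
  }
  if (any(table(design$condition) < 2L)) {
    stop("need at least two replicates per condition for permutation testing")
  }
  condition_of <- as.character(design$condition)

  series <- lapply(samples, function(s) {
    ranking <- rank_genes(expression[, s], genes = network$genes)
    build_series(network, ranking, step = step, eps = eps)
  })
  names(series) <- samples

  if (!inherits(gene_sets[[1]], "gene_set")) {
    gene_sets <- lapply(stats::setNames(names(gene_sets), names(gene_sets)),
                        function(nm) structure(list(name = nm,
                                                    members = gene_sets[[nm]],
                                                    full_size = length(gene_sets[[nm]])),
                                               class = "gene_set"))
  }

  set.seed(seed)
  results <- list(); pw <- list(); curves_all <- list()
  for (nm in names(gene_sets)) {
    gs <- gene_sets[[nm]]
    curves <- lapply(samples, function(s) depletion_curve(series[[s]], gs, id = s))
    res <- permutation_pvalue(curves, condition_of, N = N, seed = NULL,
                              exhaustive_cap = exhaustive_cap)
    results[[nm]] <- res
    curves_all[[nm]] <- curves
    if (pairwise) {
      pw[[nm]] <- pairwise_tests(curves, condition_of, N = N, seed = NULL,
                                 exhaustive_cap = exhaustive_cap)
    }
  }

  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    best <- which.max(r$pairs$A_bar)
    data.frame(gene_set = nm,
               n_genes = length(gene_sets[[nm]]$members),
               A_star = r$E_obs, p = r$p,
               best_U = r$pairs$U[best], best_V = r$pairs$V[best])
  }))

  structure(list(summary = summary, results = results, pairwise = pw,
                 series = series, curves = curves_all, design = design,
                 seed = seed, N = N),
            class = "discrepancy_analysis")
}

#' @export
print.discrepancy_analysis <- function(x, ...) {
  cat("<discrepancy_analysis>", nrow(x$summary), "gene sets,",
      length(unique(x$design$condition)), "conditions, N =", x$N, "\n")
  print(utils::head(x$summary[order(x$summary$p), ], 10L))
  invisible(x)
}

#' Signed discrepancy matrix for heatmap export
#'
#' Entry (gene set, contrast U_vs_V) = sign(delta_\{U,V\}) * A-bar_\{U,V\}:
#' the pairwise area statistic signed by the direction of the AUC difference.
#' Row/column dendrogram orders (Euclidean distance, average linkage) are
#' attached for heatmap display, as in the usual clustered sign(delta)E view.
#'
#' @param analysis a \code{discrepancy_analysis} from [gs_discrepancy()].
#' @param file optional TSV path to write the matrix to.
#' @return numeric matrix (gene sets x contrasts) with attributes
#'   \code{row_order} and \code{col_order} (dendrogram leaf orders).
#' @export
export_signed_matrix <- function(analysis, file = NULL) {
  stopifnot(inherits(analysis, "discrepancy_analysis"))
  sets <- names(analysis$results)
  p0 <- analysis$results[[1]]$pairs
  contrasts <- paste0(p0$U, "_vs_", p0$V)
  M <- matrix(unlist(lapply(sets, function(nm) {
    pr <- analysis$results[[nm]]$pairs
    sign(pr$delta) * pr$A_bar
  })), nrow = length(sets), ncol = length(contrasts), byrow = TRUE,
  dimnames = list(sets, contrasts))
  row_order <- if (nrow(M) > 2L) {
    stats::hclust(stats::dist(M), method = "average")$order
  } else seq_len(nrow(M))
  col_order <- if (ncol(M) > 2L) {
    stats::hclust(stats::dist(t(M)), method = "average")$order
  } else seq_len(ncol(M))
  attr(M, "row_order") <- row_order
  attr(M, "col_order") <- col_order
  if (!is.null(file)) {
    df <- data.frame(gene_set = rownames(M), M, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  M
}

#' Write the per-set results table as TSV
#'
#' One row per gene set: A*, p, then per-pair A-bar / p / delta columns.
#'
#' @param analysis a \code{discrepancy_analysis}.
#' @param file output TSV path.
#' @export
write_results_tsv <- function(analysis, file) {
  stopifnot(inherits(analysis, "discrepancy_analysis"))
  rows <- lapply(names(analysis$results), function(nm) {
    r <- analysis$results[[nm]]
    row <- data.frame(gene_set = nm, n_pairs = nrow(r$pairs),
                      A_star = r$E_obs, p = r$p)
    pw <- analysis$pairwise[[nm]]
    if (!is.null(pw)) {
      for (j in seq_len(nrow(pw))) {
        tag <- paste0(pw$U[j], "_vs_", pw$V[j])
        row[[paste0(tag, ".A_bar")]] <- pw$A_bar[j]
        row[[paste0(tag, ".p")]] <- pw$p[j]
        row[[paste0(tag, ".delta")]] <- pw$delta[j]
      }
    }
    row
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
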