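# Causal-gene nomination from depletion-curve descents.
#
# With a unit removal step every drop of a gene set's depletion curve is
# attributable to exactly one removed gene (possibly a gene outside the set
# whose loss propagates through the network and prunes set members). Each
# descent is characterised geometrically in the unit square: its angle
# atan(dy/dx) measures impact, its fitness* position measures how degraded the
# sub-network already was.

#' Attribute depletion-curve descents to removed genes
#'
#' Requires a unit removal step so each descent maps to one gene. For every
#' step at which the curve drops, the removed gene is credited with the drop
#' \code{dy} (including propagation losses), the fitness* decrement \code{dx},
#' the descent position (the fitness* of the sub-model after the removal) and
#' the descent angle.
#'
#' @param series a \code{submodel_series} built with \code{step = 1}.
#' @param gene_set a \code{gene_set} or character vector of members.
#' @param id optional sample id carried into the output.
#' @return data.frame: \code{gene}, \code{dy}, \code{dx}, \code{position},
#'   \code{angle} (degrees), plus \code{sample} when \code{id} is given.
#'   Zero rows for a flat curve.
#' @export
attribute_descents <- function(series, gene_set, id = NULL) {
  stopifnot(inherits(series, "submodel_series"))
  if (series$step != 1L) {
    stop("descent attribution requires a series built at unit step ",
         "(step = 1); re-run build_series() with step = 1")
  }
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else
    as.character(gene_set)
  if (!length(members)) stop("gene set is empty")
  y <- vapply(series$models, function(m) {
    length(intersect(m$present_genes, members)) / length(members)
  }, numeric(1))
  x <- vapply(series$models, function(m) m$fitness_star, numeric(1))
  j <- which(diff(y) < 0) + 1L           # models where a drop is observed
  # model j has i[j] removed genes; the gene removed entering it is
  # ranking[i[j]] (unit step)
  out <- data.frame(
    gene = series$ranking[series$i[j]],
    dy = y[j - 1L] - y[j],
    dx = x[j - 1L] - x[j],
    position = x[j],
    stringsAsFactors = FALSE
  )
  out$angle <- descent_angle(out$dy, out$dx)
  if (!is.null(id)) out$sample <- rep(id, nrow(out))
  out
}

#' Descent angle in degrees
#'
#' \code{atan(dy / dx)} on the unit-square curve geometry (both axes span
#' \[0, 1\], so the 45-degree threshold is scale-free). A vertical drop
#' (\code{dx = 0}) is 90 degrees.
#'
#' @param dy,dx non-negative drop in curve value and in fitness*.
#' @return numeric vector of angles in \[0, 90\].
#' @export
descent_angle <- function(dy, dx) {
  ifelse(dx <= 0, ifelse(dy > 0, 90, 0), atan2(dy, dx) * 180 / pi)
}

#' Summarise descents per gene across a replicate design
#'
#' Aggregates per-sample descent records into per-condition means of descent
#' position (fitness*) and angle, dispersion ratios across condition means,
#' and the filter verdicts of [filter_causal()].
#'
#' @param descents data.frame as returned by [attribute_descents()] over all
#'   samples (must carry a \code{sample} column).
#' @param design data.frame with columns \code{sample}, \code{condition}.
#' @param thresholds list with elements \code{position} (default 0.1),
#'   \code{angle} (default 45, degrees), \code{rsd} (default 0.2).
#' @param rsd_mode \code{"mean_over_sd"} (dispersion ratio as printed in the
#'   originating method: mean(x)/sd(x)) or \code{"sd_over_mean"} (the
#'   conventional relative standard deviation). Recorded in the output.
#' @return data.frame, one row per gene with at least one descent: columns
#'   \code{gene}, \code{n_samples}, \code{rsd_position}, \code{rsd_angle},
#'   \code{pass_majority}, \code{pass_rsd}, \code{passes}; the per-condition
#'   summary is attached as attribute \code{"per_condition"}.
#' @export
causal_gene_metrics <- function(descents, design,
                                thresholds = list(position = 0.1, angle = 45,
                                                  rsd = 0.2),
                                rsd_mode = c("mean_over_sd", "sd_over_mean")) {
  rsd_mode <- match.arg(rsd_mode)
  stopifnot(all(c("sample", "condition") %in% names(design)))
  if (nrow(descents) == 0L) {
    out <- data.frame(gene = character(), n_samples = integer(),
                      rsd_position = numeric(), rsd_angle = numeric(),
                      pass_majority = logical(), pass_rsd = logical(),
                      passes = logical())
    attr(out, "per_condition") <- NULL
    attr(out, "rsd_mode") <- rsd_mode
    return(out)
  }
  descents$condition <- design$condition[match(descents$sample, design$sample)]
  n_reps <- table(design$condition)

  rsd <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    s <- stats::sd(x)
    m <- mean(x)
    if (rsd_mode == "mean_over_sd") {
      if (s == 0) Inf else m / s
    } else {
      if (m == 0) Inf else s / m
    }
  }

  per_cond <- do.call(rbind, lapply(split(descents,
                                          list(descents$gene, descents$condition),
                                          drop = TRUE), function(d) {
    data.frame(gene = d$gene[1], condition = d$condition[1],
               n_descents = nrow(d),
               n_pass = sum(d$position > thresholds$position &
                            d$angle > thresholds$angle),
               mean_position = mean(d$position),
               mean_angle = mean(d$angle))
  }))
  rownames(per_cond) <- NULL

  out <- do.call(rbind, lapply(split(per_cond, per_cond$gene), function(pc) {
    majority <- any(pc$n_pass > as.vector(n_reps[pc$condition]) / 2)
    rp <- rsd(pc$mean_position)
    ra <- rsd(pc$mean_angle)
    pass_rsd <- isTRUE(rp > thresholds$rsd) && isTRUE(ra > thresholds$rsd)
    data.frame(gene = pc$gene[1],
               n_samples = sum(pc$n_descents),
               rsd_position = rp, rsd_angle = ra,
               pass_majority = majority, pass_rsd = pass_rsd,
               passes = majority && pass_rsd)
  }))
  rownames(out) <- NULL
  out <- out[order(out$gene), , drop = FALSE]
  attr(out, "per_condition") <- per_cond
  attr(out, "rsd_mode") <- rsd_mode
  attr(out, "thresholds") <- thresholds
  out
}

#' Filter causal-gene metrics to passing genes
#'
#' A gene passes when (a) in at least one condition, strictly more than half
#' of that condition's replicates show a descent with fitness* position above
#' the position threshold and angle above the angle threshold, and (b) both
#' dispersion ratios across per-condition means exceed the RSD threshold.
#'
#' @param metrics output of [causal_gene_metrics()].
#' @return character vector of passing gene ids.
#' @export
filter_causal <- function(metrics) {
  metrics$gene[metrics$passes]
}

#' End-to-end causal-gene identification
#'
#' Builds unit-step series per sample, attributes descents of the gene set's
#' depletion curve, and summarises/filters per-gene metrics.
#'
#' @inheritParams gs_discrepancy
#' @param gene_set a \code{gene_set} or character vector of members.
#' @param series optional pre-built named list of unit-step
#'   \code{submodel_series} (one per design sample) to reuse.
#' @param thresholds,rsd_mode see [causal_gene_metrics()].
#' @return the metrics data.frame of [causal_gene_metrics()], with the
#'   per-sample descents attached as attribute \code{"descents"}.
#' @export
find_causal_genes <- function(network, expression, design, gene_set,
                              series = NULL, eps = 1e-6,
                              thresholds = list(position = 0.1, angle = 45,
                                                rsd = 0.2),
                              rsd_mode = c("mean_over_sd", "sd_over_mean")) {
  samples <- as.character(design$sample)
  if (is.null(series)) {
    series <- lapply(samples, function(s) {
      ranking <- rank_genes(expression[, s], genes = network$genes)
      build_series(network, ranking, step = 1L, eps = eps)
    })
    names(series) <- samples
  }
  descents <- do.call(rbind, lapply(samples, function(s) {
    attribute_descents(series[[s]], gene_set, id = s)
  }))
  metrics <- causal_gene_metrics(descents, design, thresholds = thresholds,
                                 rsd_mode = rsd_mode)
  attr(metrics, "descents") <- descents
  metrics
}

#' Write the causal-gene report as TSV
#'
#' @param metrics output of [causal_gene_metrics()] / [find_causal_genes()].
#' @param file output path.
#' @export
write_causal_tsv <- function(metrics, file) {
  utils::write.table(metrics, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
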