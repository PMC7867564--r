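# Synthetic fixtures with planted ground truth.
#
# Three generators cover the pipeline end to end: a viable toy GSMN with
# branched topology and mixed AND/OR GPRs, replicate expression designs in
# which a chosen gene set is rank-displaced in one condition, and strand-split
# ChIP tag piles over planted enriched regions on Poisson background. All
# generation is a pure function of (spec, seed); truth tables are returned
# alongside every fixture.

#' Synthetic-data specification
#'
#' Bundles the generator parameters with their defaults. Defaults emulate a
#' replicated multi-condition expression study on a desk-scale network:
#' 4 conditions x 6 replicates, log-normal expression noise, a planted gene
#' set down-shifted in one target condition; ChIP defaults plant broad
#' (multi-kb) enriched domains on a 1 Mb genome with 2 conditions x 2
#' replicates, a 200 bp fragment length and Poisson background.
#'
#' @param seed integer seed; generation is a pure function of the spec.
#' @param network list: \code{n_biomass} (4), \code{chain_length} (3),
#'   \code{n_filler} (2).
#' @param design list: \code{conditions} (4), \code{replicates} (6),
#'   \code{target_condition} (1), \code{n_planted} (5), \code{effect} (6;
#'   log2 down-shift of planted genes in the target condition, 0 = null),
#'   \code{noise_sd} (0.2; replicate log-normal sd), \code{base_meanlog}
#'   (log(100)), \code{base_sdlog} (1).
#' @param chip list: \code{genome} (named sizes, c(chr1 = 1e6)),
#'   \code{fragment_length} (200), \code{n_regions} (8), \code{region_width}
#'   (4500), \code{narrow_width} (1400; one boundary-straddling narrow
#'   region), \code{enrichment_fold} (10), \code{depth} (2e5),
#'   \code{conditions} (2), \code{replicates} (2).
#' @return object of class \code{synth_spec}.
#' @export
synth_spec <- function(seed = 1L, network = list(), design = list(),
                       chip = list()) {
  net_def <- list(n_biomass = 4L, chain_length = 3L, n_filler = 2L)
  des_def <- list(conditions = 4L, replicates = 6L, target_condition = 1L,
                  n_planted = 5L, effect = 6, noise_sd = 0.2,
                  base_meanlog = log(100), base_sdlog = 1)
  chip_def <- list(genome = c(chr1 = 1e6), fragment_length = 200L,
                   n_regions = 8L, region_width = 4500L, narrow_width = 1400L,
                   enrichment_fold = 10, depth = 2e5, conditions = 2L,
                   replicates = 2L)
  structure(list(seed = as.integer(seed),
                 network = utils::modifyList(net_def, network),
                 design = utils::modifyList(des_def, design),
                 chip = utils::modifyList(chip_def, chip)),
            class = "synth_spec")
}

#' Generate a viable toy metabolic network
#'
#' Topology: a nutrient is imported by a spontaneous exchange and converted to
#' a hub metabolite by an isozyme pair (OR rule); from the hub, one linear
#' chain per biomass component, with GPR patterns cycling through single
#' genes, two-gene complexes (AND) and isozyme pairs (OR); spontaneous export
#' for every biomass component; plus dead-end filler branches whose genes do
#' not affect viability. The comprehensive network has fitness exactly 1, and
#' removing a chain gene blocks everything downstream of it (propagation).
#'
#' @param spec a \code{synth_spec}.
#' @return a \code{metabolic_network}.
#' @export
make_network <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- spec$network
  set.seed(spec$seed)
  nb <- p$n_biomass
  cl <- p$chain_length

  mets <- c("N", "H")
  reactions <- list(
    list(id = "EX_N", stoich = c(N = 1), rev = FALSE, lb = 0, ub = 1000,
         gpr = NULL),
    list(id = "R_hub", stoich = c(N = -1, H = 1), rev = FALSE, lb = 0,
         ub = 1000, gpr = "gHub1 or gHub2")
  )
  exchanges <- "EX_N"
  biomass <- character(nb)
  gcount <- 0L
  new_gene <- function() {
    gcount <<- gcount + 1L
    sprintf("g%02d", gcount)
  }
  # GPR pattern of each chain step. Redundancy dominates, as in genome-scale
  # models where sub-models stay viable until deep into a removal ranking:
  # most steps are isozyme pairs (OR) or an enzyme complex (AND) backed by a
  # parallel isozyme reaction; a small minority are fragile single-gene steps,
  # which is what lets removals propagate early for some rankings.
  patterns <- sample(c("single", "and_backup", "or"), nb * cl, replace = TRUE,
                     prob = c(0.1, 0.2, 0.7))
  step <- 0L
  for (j in seq_len(nb)) {
    prev <- "H"
    for (l in seq_len(cl)) {
      step <- step + 1L
      met <- if (l == cl) sprintf("B%d", j) else sprintf("I%d_%d", j, l)
      mets <- c(mets, met)
      gpr <- switch(patterns[step],
        single = new_gene(),
        and_backup = paste(new_gene(), "and", new_gene()),
        or = paste(new_gene(), "or", new_gene())
      )
      reactions[[length(reactions) + 1L]] <- list(
        id = sprintf("R%d_%d", j, l),
        stoich = stats::setNames(c(-1, 1), c(prev, met)),
        rev = FALSE, lb = 0, ub = 1000, gpr = gpr)
      if (patterns[step] == "and_backup") {
        # parallel single-gene isozyme reaction rescues the complex step
        reactions[[length(reactions) + 1L]] <- list(
          id = sprintf("R%d_%db", j, l),
          stoich = stats::setNames(c(-1, 1), c(prev, met)),
          rev = FALSE, lb = 0, ub = 1000, gpr = new_gene())
      }
      prev <- met
    }
    biomass[j] <- sprintf("B%d", j)
    ex <- sprintf("EX_B%d", j)
    reactions[[length(reactions) + 1L]] <- list(
      id = ex, stoich = stats::setNames(-1, sprintf("B%d", j)),
      rev = FALSE, lb = 0, ub = 1000, gpr = NULL)
    exchanges <- c(exchanges, ex)
  }
  # dead-end filler branches: visible gene content, no effect on viability
  for (f in seq_len(p$n_filler)) {
    met <- sprintf("F%d", f)
    mets <- c(mets, met)
    reactions[[length(reactions) + 1L]] <- list(
      id = sprintf("R_F%d", f), stoich = c(H = -1, stats::setNames(1, met)),
      rev = FALSE, lb = 0, ub = 1000, gpr = new_gene())
    ex <- sprintf("EX_F%d", f)
    reactions[[length(reactions) + 1L]] <- list(
      id = ex, stoich = stats::setNames(-1, met), rev = FALSE, lb = 0,
      ub = 1000, gpr = NULL)
    exchanges <- c(exchanges, ex)
  }
  net <- metabolic_network(mets, reactions, biomass, exchanges)
  stopifnot(extract_submodel(net, character(0), prune = FALSE)$fitness == 1)
  net
}

#' Generate a replicate expression design with a planted gene-set effect
#'
#' Baseline per-gene levels are log-normal; replicates add log-normal noise.
#' In the target condition the planted genes are down-shifted by
#' \code{2^effect}, so they rank early for removal there and the planted set
#' depletes at high fitness* in that condition only. \code{effect = 0} yields
#' an exchangeable null across all conditions.
#'
#' @param spec a \code{synth_spec}.
#' @param network the network the expression is for (genes taken from it).
#' @param planted_genes optional explicit planted member genes; default: a
#'   seeded sample of \code{spec$design$n_planted} network genes.
#' @return list: \code{expression} (genes x samples matrix), \code{design}
#'   (data.frame sample/condition), \code{truth} (list with
#'   \code{target_condition}, \code{planted_genes}, \code{effect}).
#' @export
make_expression <- function(spec = synth_spec(), network,
                            planted_genes = NULL) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(network, "metabolic_network"))
  d <- spec$design
  set.seed(spec$seed + 1L)
  genes <- network$genes
  k <- length(genes)
  conds <- sprintf("cond%d", seq_len(d$conditions))
  target <- conds[d$target_condition]
  if (is.null(planted_genes)) {
    planted_genes <- sort(sample(genes, min(d$n_planted, k)))
  }
  samples <- as.vector(t(outer(conds, seq_len(d$replicates),
                               function(c, r) paste0(c, "_r", r))))
  design <- data.frame(sample = samples,
                       condition = rep(conds, each = d$replicates))
  base <- exp(stats::rnorm(k, d$base_meanlog, d$base_sdlog))
  names(base) <- genes
  expr <- matrix(0, k, length(samples), dimnames = list(genes, samples))
  for (s in seq_along(samples)) {
    mu <- base
    if (design$condition[s] == target && d$effect != 0) {
      mu[planted_genes] <- mu[planted_genes] * 2^(-d$effect)
    }
    expr[, s] <- mu * exp(stats::rnorm(k, 0, d$noise_sd))
  }
  list(expression = expr, design = design,
       truth = list(target_condition = target,
                    planted_genes = planted_genes, effect = d$effect))
}

#' Generate random gene-set collections
#'
#' Seeded random subsets of the supplied genes, e.g. as a null collection for
#' permutation-calibration experiments.
#'
#' @param genes character vector to draw from.
#' @param n number of sets.
#' @param size integer range \code{c(min, max)} of set sizes.
#' @param seed integer seed.
#' @param prefix set-name prefix.
#' @return named list of character vectors.
#' @export
make_gene_sets <- function(genes, n = 200L, size = c(3L, 8L), seed = 1L,
                           prefix = "SET") {
  set.seed(seed)
  sets <- lapply(seq_len(n), function(i) {
    sort(sample(genes, sample(size[1]:size[2], 1L)))
  })
  names(sets) <- sprintf("%s%04d", prefix, seq_len(n))
  sets
}

#' Generate ChIP and INPUT tag tracks with planted enriched regions
#'
#' INPUT tracks are uniform Poisson tags. ChIP tracks are the same uniform
#' background plus, in each truth region, extra fragments whose centres are
#' uniform in the region: plus-strand 5' ends sit half a fragment upstream of
#' the centre and minus-strand 5' ends half a fragment downstream, so the
#' strand cross-correlation peaks at the fragment length. The expected extra
#' coverage is (fold - 1) times background, giving fold-times enrichment.
#' Truth regions are evenly spaced; one deliberately narrow region is centred
#' on a phase-0 bin boundary (multiple of 500) to exercise the half-bin phase.
#'
#' @param spec a \code{synth_spec}.
#' @return list: \code{chip}, \code{input} (named lists of
#'   \code{tag_track}), \code{condition_of} (named vector), \code{truth}
#'   (\code{GRanges} of planted regions), \code{fragment_length}.
#' @export
make_chip <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- spec$chip
  set.seed(spec$seed + 2L)
  stopifnot(length(p$genome) >= 1L)
  chrom <- names(p$genome)[1]
  L <- as.integer(p$genome[1])
  fl <- as.integer(p$fragment_length)

  # planted regions: evenly spaced wide domains + one narrow one centred on a
  # multiple of the 500-nt bin width
  n_wide <- p$n_regions - 1L
  grid <- seq(0.1, 0.9, length.out = n_wide + 1L)
  grid <- grid[-which.min(abs(grid - 0.5))]   # keep the midpoint clear
  centers <- round(grid * L) + sample(-200:200, n_wide, replace = TRUE)
  starts <- pmax(centers - round(p$region_width / 2), 0L)
  ends <- pmin(starts + p$region_width, L)
  narrow_center <- 500L * round(0.5 * L / 500)   # exactly on a bin boundary
  starts <- c(starts, narrow_center - round(p$narrow_width / 2))
  ends <- c(ends, narrow_center + round(p$narrow_width / 2))
  ord <- order(starts)
  truth <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts[ord] + 1L, end = ends[ord])))

  conds <- sprintf("cond%d", seq_len(p$conditions))
  condition_of <- character(0)
  chip <- list(); input <- list()
  bg_rate <- p$depth / L
  for (cn in conds) {
    for (r in seq_len(p$replicates)) {
      id <- paste0(cn, "_r", r)
      # INPUT: uniform Poisson
      n_in <- stats::rpois(1L, p$depth)
      input[[id]] <- tag_track(
        data.frame(chrom = chrom,
                   pos = sample.int(L, n_in, replace = TRUE) - 1L,
                   strand = sample(c("+", "-"), n_in, replace = TRUE)),
        chrom_sizes = p$genome[1], id = id, role = "INPUT")
      # ChIP: background + planted fragments
      n_bg <- stats::rpois(1L, p$depth)
      bg <- data.frame(chrom = chrom,
                       pos = sample.int(L, n_bg, replace = TRUE) - 1L,
                       strand = sample(c("+", "-"), n_bg, replace = TRUE))
      sig <- NULL
      if (p$enrichment_fold > 1) {
        st <- BiocGenerics::start(truth) - 1L
        wd <- BiocGenerics::width(truth)
        n_extra <- stats::rpois(length(wd), (p$enrichment_fold - 1) * bg_rate * wd)
        # fragment centres pile on nucleosome-scale sites (~200 bp spacing,
        # 20 bp jitter) within each region, as chromatin-mark fragments do;
        # this also gives the strand cross-correlation its apex
        ctr <- unlist(lapply(seq_along(wd), function(i) {
          sites <- seq(st[i], st[i] + wd[i] - 1L, by = 200L)
          round(sample(sites, n_extra[i], replace = TRUE) +
                  stats::rnorm(n_extra[i], 0, 20))
        }))
        ctr <- pmin(pmax(ctr, 0L), L - 1L)
        strand <- sample(c("+", "-"), length(ctr), replace = TRUE)
        pos <- ifelse(strand == "+", ctr - round(fl / 2), ctr + round(fl / 2))
        pos <- pmin(pmax(pos, 0L), L - 1L)
        sig <- data.frame(chrom = chrom, pos = pos, strand = strand)
      }
      chip[[id]] <- tag_track(rbind(bg, sig), chrom_sizes = p$genome[1],
                              id = id, role = "ChIP")
      condition_of[id] <- cn
    }
  }
  list(chip = chip, input = input, condition_of = condition_of,
       truth = truth, fragment_length = fl)
}

#' Fixture with a single planted high-impact causal gene
#'
#' A hand-shaped 12-gene network and a deterministic-rank expression design
#' (2 conditions x 3 replicates, tiny noise) in which exactly one gene,
#' \code{gCause}, causes an early descent of the gene set
#' \{gM1, gM2, gM3\} through network propagation: \code{gCause} is not a set
#' member, but its removal blocks the only route to the set member gM1's
#' reaction. The set's remaining members are removed so late that their
#' descents sit below the fitness* position threshold.
#'
#' @param seed integer seed (noise only; the structure is fixed).
#' @param noise_sd replicate log-normal noise (default 0.01; small enough to
#'   keep rankings deterministic).
#' @return list: \code{network}, \code{expression}, \code{design},
#'   \code{gene_set} (character members), \code{truth} (list with
#'   \code{causal_gene})
#' @export
make_causal_fixture <- function(seed = 1L, noise_sd = 0.01) {
  mets <- c("N", "Q", "P", "B1", "B2", "B3", "B4", "F1", "F2", "F3")
  rxn <- function(id, from, to, gpr) {
    list(id = id, stoich = stats::setNames(c(-1, 1), c(from, to)),
         rev = FALSE, lb = 0, ub = 1000, gpr = gpr)
  }
  ex_in <- list(id = "EX_N", stoich = c(N = 1), rev = FALSE, lb = 0,
                ub = 1000, gpr = NULL)
  ex_out <- function(met) list(id = paste0("EX_", met),
                               stoich = stats::setNames(-1, met),
                               rev = FALSE, lb = 0, ub = 1000, gpr = NULL)
  reactions <- list(
    ex_in,
    rxn("RA", "N", "Q", "gA"),
    rxn("RC", "Q", "P", "gCause"),
    rxn("RM1", "P", "B1", "gM1"),
    rxn("RM2", "N", "B2", "gM2"),
    rxn("RM3", "N", "B3", "gM3"),
    rxn("RB4", "N", "B4", "gB4"),
    rxn("RF1", "N", "F1", "gF1"),
    rxn("RF2", "N", "F2", "gF2"),
    rxn("RF3", "N", "F3", "gF3 or gF4"),
    ex_out("B1"), ex_out("B2"), ex_out("B3"), ex_out("B4"),
    ex_out("F1"), ex_out("F2"), ex_out("F3")
  )
  net <- metabolic_network(mets, reactions, biomass = c("B1", "B2", "B3", "B4"),
                           exchanges = c("EX_N", paste0("EX_", c("B1", "B2",
                                                                 "B3", "B4",
                                                                 "F1", "F2",
                                                                 "F3"))))
  # removal order (low expression first): fillers, then the causal gene at
  # rank 4 (descent position well above 0.1), remaining structure genes, and
  # the set members last (descents below the position threshold)
  order_removed <- c("gF1", "gF2", "gF3", "gCause", "gF4", "gA",
                     "gB4", "gM2", "gM3", "gM1")
  stopifnot(setequal(order_removed, net$genes))
  base <- stats::setNames(10 * 2^seq_along(order_removed), order_removed)

  conds <- c("condA", "condB")
  samples <- as.vector(t(outer(conds, 1:3, paste0)))
  design <- data.frame(sample = samples, condition = rep(conds, each = 3))
  set.seed(seed)
  expr <- vapply(samples, function(s) {
    base[net$genes] * exp(stats::rnorm(length(base), 0, noise_sd))
  }, numeric(length(base)))
  rownames(expr) <- net$genes

  list(network = net, expression = expr, design = design,
       gene_set = c("gM1", "gM2", "gM3"),
       truth = list(causal_gene = "gCause"))
}

#' Write an expression fixture to disk (TSV dialects)
#'
#' @param fixture output of [make_expression()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (expression.tsv, design.tsv,
#'   truth.tsv).
#' @export
write_expression_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(fixture$expression),
                                fixture$expression, check.names = FALSE),
                     ep, sep = "\t", quote = FALSE, row.names = FALSE)
  dp <- file.path(dir, "design.tsv")
  utils::write.table(fixture$design, dp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(key = c("target_condition", "effect", "planted_genes"),
               value = c(fixture$truth$target_condition,
                         fixture$truth$effect,
                         paste(fixture$truth$planted_genes, collapse = ","))),
    tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ep, dp, tp))
}

#' Read an expression matrix and design table from TSV
#'
#' Expression: genes in rows (first column \code{gene}), samples in columns.
#' Design: columns \code{sample}, \code{condition}.
#'
#' @param expression_tsv,design_tsv file paths.
#' @return list with \code{expression} matrix and \code{design} data.frame.
#' @export
read_expression_tsv <- function(expression_tsv, design_tsv) {
  ed <- utils::read.delim(expression_tsv, check.names = FALSE)
  expr <- as.matrix(ed[, -1, drop = FALSE])
  rownames(expr) <- ed[[1]]
  design <- utils::read.delim(design_tsv)
  list(expression = expr, design = design)
}
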