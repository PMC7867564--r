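#' Construct a genome-scale metabolic network
#'
#' A metabolic network couples a stoichiometric model (metabolites, reactions
#' with flux bounds) to gene content through GPR boolean rules. Exchange
#' reactions are the boundary of the system: they are the only reactions whose
#' stoichiometry is intentionally unbalanced (mass enters or leaves through
#' them). The comprehensive network is expected to be viable, i.e. every
#' biomass component producible at steady state (fitness 1); this is the
#' reference against which gene-removal sub-models are scored.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions list of reactions; each a list with elements \code{id},
#'   \code{stoich} (named numeric: metabolite -> coefficient, negative =
#'   consumed), \code{rev} (logical), \code{lb}, \code{ub} (flux bounds),
#'   \code{gpr} (rule string, empty/NULL = spontaneous).
#' @param biomass character vector of metabolite ids required for growth;
#'   must be non-empty.
#' @param exchanges character vector of reaction ids allowed nonzero boundary
#'   flux.
#' @return an object of class \code{metabolic_network}.
#' @seealso [read_network_json()], [extract_submodel()], [fitness()]
#' @export
metabolic_network <- function(metabolites, reactions, biomass,
                              exchanges = character()) {
  metabolites <- as.character(metabolites)
  if (anyDuplicated(metabolites)) stop("duplicated metabolite ids")
  if (length(biomass) == 0L) stop("biomass_components must be non-empty")
  if (!all(biomass %in% metabolites)) {
    stop("biomass components not declared as metabolites: ",
         paste(setdiff(biomass, metabolites), collapse = ", "))
  }
  rxn_ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rxn_ids)) stop("duplicated reaction ids")
  if (!all(exchanges %in% rxn_ids)) {
    stop("exchange ids not declared as reactions: ",
         paste(setdiff(exchanges, rxn_ids), collapse = ", "))
  }

  n_m <- length(metabolites)
  n_r <- length(reactions)
  S <- matrix(0, n_m, n_r, dimnames = list(metabolites, rxn_ids))
  lb <- numeric(n_r)
  ub <- numeric(n_r)
  gpr_trees <- vector("list", n_r)

  for (j in seq_len(n_r)) {
    r <- reactions[[j]]
    st <- r$stoich
    if (is.null(names(st)) || !all(names(st) %in% metabolites)) {
      stop("reaction '", r$id, "' references undeclared metabolites: ",
           paste(setdiff(names(st), metabolites), collapse = ", "))
    }
    S[names(st), j] <- as.numeric(st)
    rev_j <- isTRUE(r$rev)
    lb[j] <- as.numeric(r$lb)
    ub[j] <- as.numeric(r$ub)
    if (lb[j] > ub[j]) stop("reaction '", r$id, "': lb > ub")
    if (!rev_j && lb[j] < 0) {
      stop("reaction '", r$id, "': irreversible but lb < 0")
    }
    tree <- if (is.list(r$gpr)) r$gpr else parse_gpr(r$gpr)
    gpr_trees[j] <- list(tree)
    reactions[[j]]$gpr_tree <- tree
    reactions[[j]]$gpr <- deparse_gpr(gpr_trees[[j]])
  }

  genes <- sort(unique(unlist(lapply(gpr_trees, gpr_genes))))
  if (length(genes) < 1L) stop("network must reference at least one gene")

  structure(list(
    metabolites = metabolites,
    reactions = reactions,
    rxn_ids = rxn_ids,
    biomass = as.character(biomass),
    exchanges = as.character(exchanges),
    genes = genes,
    S = S,
    lb = lb,
    ub = ub,
    gpr_trees = gpr_trees,
    rxn_gene_list = lapply(gpr_trees, gpr_genes)
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$metabolites), " metabolites, ",
      length(x$rxn_ids), " reactions (", length(x$exchanges), " exchanges), ",
      length(x$genes), " genes, ", length(x$biomass),
      " biomass components\n", sep = "")
  invisible(x)
}

#' Read / write a metabolic network in the package's JSON dialect
#'
#' Schema: \code{\{metabolites:[...], reactions:[\{id, stoich:\{met:coef\},
#' rev, lb, ub, gpr:"(gA and gB) or gC"\}], biomass:[...], exchanges:[...]\}}.
#'
#' @param path file path.
#' @return [read_network_json()] returns a \code{metabolic_network};
#'   [write_network_json()] returns \code{path} invisibly.
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (k in c("metabolites", "reactions", "biomass")) {
    if (is.null(doc[[k]])) stop("network JSON missing field '", k, "'")
  }
  reactions <- lapply(doc$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         rev = isTRUE(r$rev),
         lb = r$lb, ub = r$ub,
         gpr = if (is.null(r$gpr)) NULL else r$gpr)
  })
  metabolic_network(
    metabolites = unlist(doc$metabolites),
    reactions = reactions,
    biomass = unlist(doc$biomass),
    exchanges = if (is.null(doc$exchanges)) character() else unlist(doc$exchanges)
  )
}

#' @rdname read_network_json
#' @param network a \code{metabolic_network}.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  doc <- list(
    metabolites = network$metabolites,
    reactions = lapply(network$reactions, function(r) {
      list(id = r$id, stoich = as.list(r$stoich), rev = isTRUE(r$rev),
           lb = r$lb, ub = r$ub, gpr = r$gpr)
    }),
    biomass = network$biomass,
    exchanges = network$exchanges
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
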