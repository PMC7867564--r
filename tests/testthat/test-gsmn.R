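test_that("network construction validates structure", {
  expect_error(metabolic_network(
    "A", list(list(id = "R1", stoich = c(Z = 1), rev = FALSE, lb = 0, ub = 1,
                   gpr = "g1")), biomass = "A"),
    "undeclared metabolites")
  expect_error(metabolic_network(
    "A", list(list(id = "R1", stoich = c(A = 1), rev = FALSE, lb = -1, ub = 1,
                   gpr = "g1")), biomass = "A"),
    "irreversible but lb < 0")
  expect_error(metabolic_network(
    "A", list(list(id = "R1", stoich = c(A = 1), rev = FALSE, lb = 0, ub = 1,
                   gpr = "g1")), biomass = character(0)),
    "non-empty")
})

test_that("network JSON round-trips", {
  net <- chain_network(export_c = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  net2 <- read_network_json(path)
  expect_identical(net2$metabolites, net$metabolites)
  expect_identical(net2$rxn_ids, net$rxn_ids)
  expect_identical(net2$genes, net$genes)
  expect_identical(net2$S, net$S)
  expect_identical(net2$biomass, net$biomass)
  expect_identical(net2$exchanges, net$exchanges)
})

test_that("producibility: comprehensive true, closed exchanges false, broken chain false", {
  net <- chain_network()
  expect_true(producible(net, "D"))
  expect_true(producible(net, "B"))
  # close the import: nothing non-source is producible
  closed <- net
  closed$ub[match("EX_A", net$rxn_ids)] <- 0
  expect_false(producible(closed, "D"))
  # sole gene of a middle reaction removed: downstream metabolite dead
  sm <- extract_submodel(net, "g2", prune = FALSE)
  active <- match(sm$active, net$rxn_ids)
  expect_false(producible(net, "D", active = active))
  expect_true(producible(net, "B", active = active))
  expect_error(producible(net, "nope"), "undeclared")
})

test_that("pruning removes blocked downstream reactions and propagates gene loss", {
  net <- chain_network()
  sm <- extract_submodel(net, "g2")
  # R2 inactivated by GPR; R3 blocked (no substrate source) and pruned
  expect_false("R2" %in% sm$active)
  expect_false("R3" %in% sm$active)
  expect_false("g3" %in% sm$present_genes)
  expect_false("g2" %in% sm$present_genes)
  # R1 also blocked: B has no consumer and no export
  expect_false("R1" %in% sm$active)
  # with an export for C, R1/R2 survive a g3 removal
  net2 <- chain_network(export_c = TRUE)
  sm2 <- extract_submodel(net2, "g3")
  expect_true(all(c("R1", "R2") %in% sm2$active))
  expect_false("R3" %in% sm2$active)
})

test_that("extraction contracts: empty and full removal, idempotence", {
  net <- make_network(synth_spec(seed = 3))
  sm0 <- extract_submodel(net, character(0))
  expect_identical(sort(sm0$active), sort(net$rxn_ids))
  expect_identical(sm0$i, 0L)
  expect_identical(fitness(sm0), 1)
  expect_identical(fitness_star(sm0), 1)

  sm_all <- extract_submodel(net, net$genes)
  expect_identical(fitness(sm_all), 0)
  expect_identical(fitness_star(sm_all), 0)
  expect_length(sm_all$present_genes, 0)
  # only the spontaneous skeleton can survive GPR deactivation
  spont <- net$rxn_ids[vapply(net$gpr_trees, is.null, logical(1))]
  expect_true(all(sm_all$active %in% spont))

  sm_rep <- extract_submodel(net, sm0$removed)
  expect_identical(sm_rep$active, sm0$active)
})

test_that("fitness equals the producible fraction of biomass components", {
  net <- four_route_network()
  expect_identical(fitness(extract_submodel(net, character(0))), 1)
  expect_identical(fitness(extract_submodel(net, "g1")), 0.75)
  expect_identical(fitness(extract_submodel(net, c("g1", "g3"))), 0.5)
  expect_identical(fitness(extract_submodel(net, paste0("g", 1:4))), 0)
})

test_that("knockout fitness matches the reachability oracle exhaustively", {
  net <- make_network(synth_spec(seed = 11, network = list(
    n_biomass = 2L, chain_length = 2L, n_filler = 1L)))
  k <- length(net$genes)
  expect_lte(k, 12L)
  for (size in 0:k) {
    sets <- utils::combn(net$genes, size, simplify = FALSE)
    for (rem in sets) {
      f <- fitness(extract_submodel(net, rem, prune = FALSE))
      expect_identical(f, fitness_oracle(net, rem),
                       info = paste("removed:", paste(rem, collapse = ",")))
    }
  }
})

test_that("fitness is monotone non-increasing under superset removal", {
  net <- make_network(synth_spec(seed = 19, network = list(
    n_biomass = 2L, chain_length = 2L, n_filler = 0L)))
  set.seed(42)
  for (rep in 1:30) {
    small <- sample(net$genes, sample(0:(length(net$genes) - 1), 1))
    extra <- sample(setdiff(net$genes, small), 1)
    f1 <- fitness(extract_submodel(net, small, prune = FALSE))
    f2 <- fitness(extract_submodel(net, c(small, extra), prune = FALSE))
    expect_lte(f2, f1)
  }
})

test_that("pruning fixed point is independent of reaction order", {
  base <- make_network(synth_spec(seed = 7, network = list(
    n_biomass = 3L, chain_length = 2L, n_filler = 1L)))
  set.seed(1)
  removed <- sample(base$genes, 4)
  ref <- extract_submodel(base, removed)
  for (rep in 1:5) {
    perm <- sample(seq_along(base$reactions))
    net_p <- metabolic_network(base$metabolites,
                               lapply(base$reactions[perm], function(r) {
                                 r[c("id", "stoich", "rev", "lb", "ub", "gpr")]
                               }),
                               biomass = base$biomass,
                               exchanges = base$exchanges)
    sm <- extract_submodel(net_p, removed)
    expect_setequal(sm$active, ref$active)
    expect_setequal(sm$present_genes, ref$present_genes)
    expect_equal(sm$fitness, ref$fitness)
  }
})

test_that("series: fitness* identity, boundary values, coarse step", {
  net <- make_network(synth_spec(seed = 5))
  k <- length(net$genes)
  ranking <- sort(net$genes)
  ser <- build_series(net, ranking, step = 1L)
  expect_length(ser$models, k + 1L)
  fs <- vapply(ser$models, fitness, numeric(1))
  fss <- vapply(ser$models, fitness_star, numeric(1))
  expect_equal(fss, (1 - ser$i / k) * fs)
  expect_identical(fss[1], 1)
  expect_identical(fss[k + 1L], 0)
  expect_true(all(diff(fs) <= 1e-12))

  ser2 <- build_series(net, ranking, step = k)
  expect_length(ser2$models, 2L)
  expect_identical(ser2$i, c(0L, k))

  # incremental extraction agrees with from-scratch extraction
  for (j in c(2, 5, k %/% 2, k)) {
    direct <- extract_submodel(net, ranking[seq_len(j)])
    expect_setequal(ser$models[[j + 1L]]$active, direct$active)
    expect_equal(ser$models[[j + 1L]]$fitness, direct$fitness)
  }
})
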